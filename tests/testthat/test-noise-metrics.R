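# Coefficient-of-variation noise statistics and their permutation tests.

test_that("feature CV matches hand computations and is scale invariant", {
  expect_equal(feature_cv(c(1, 2, 3)), 0.5)           # sd 1, mean 2
  expect_equal(feature_cv(rep(4.2, 6)), 0)
  x <- rexp(20) + 0.1
  expect_equal(feature_cv(137.5 * x), feature_cv(x), tolerance = 1e-12)
  expect_error(feature_cv(c(-3, 1)), "positive")
  expect_error(feature_cv(2), "at least 2")
})

test_that("metabolic noise is the median of per-feature CVs", {
  # three features engineered to CVs 0.1, 0.5, 0.9 across four hens:
  # (1, 1, 1, 1 + k) has mean 1 + k/4 and sd k/2, so cv solves
  # k/2 = cv * (1 + k/4)
  mk <- function(cv) {
    k <- cv / (0.5 - cv / 4)
    c(1, 1, 1, 1 + k)
  }
  x <- rbind(F1 = mk(0.1), F2 = mk(0.5), F3 = mk(0.9)) * 100
  colnames(x) <- paste0("H", 1:4, "_t21")
  tab <- toy_table(x, setNames(rep("control", 4), paste0("H", 1:4)))
  ns <- metabolic_noise(tab, "control", 21)
  expect_equal(sort(ns$cv), c(0.1, 0.5, 0.9), tolerance = 1e-12)
  expect_equal(attr(ns, "median_cv"), 0.5, tolerance = 1e-12)
  expect_equal(attr(ns, "n_samples"), 4L)
})

test_that("metabolic noise is exactly invariant to per-feature rescaling", {
  cohort <- small_cohort()
  tab <- cohort$metabolites
  scaled <- tab
  withr::with_seed(8, {
    scaled$intensities <- tab$intensities *
      10^runif(nrow(tab$intensities), -3, 3)
  })
  n1 <- metabolic_noise(tab, "control", 21)
  n2 <- metabolic_noise(scaled, "control", 21)
  expect_equal(n1$cv, n2$cv, tolerance = 1e-12)
  expect_equal(attr(n1, "median_cv"), attr(n2, "median_cv"),
               tolerance = 1e-12)
})

test_that("identical groups give a permutation p of 1", {
  x <- matrix(exp(rnorm(40, 6, 0.4)), 4, 10)
  rownames(x) <- paste0("F", 1:4)
  hens <- c(paste0("C", 1:5), paste0("M", 1:5))
  colnames(x) <- paste0(hens, "_t21")
  x[, 6:10] <- x[, 1:5]  # molted columns duplicate control columns
  tab <- toy_table(x, setNames(rep(c("control", "molted"), each = 5), hens))
  traj <- noise_trajectory(tab, n_perm = 100, seed = 1)
  expect_equal(attr(traj, "comparisons")$p_value, 1)
})

test_that("planted CV schedules show up in the noise trajectory", {
  cohort <- default_cohort()
  traj <- noise_trajectory(cohort$metabolites, n_perm = 50, seed = 2)
  tt <- as_tibble(traj)
  ctrl <- tt$median_cv[tt$group == "control"][order(tt$age_months[tt$group == "control"])]
  expect_true(all(diff(ctrl) > 0))  # cv_age_slope > 0
  molted <- tt[tt$group == "molted", ]
  expect_lt(molted$median_cv[molted$age_months == 27],
            molted$median_cv[molted$age_months == 21])
})

test_that("larger injected dispersion raises the median CV", {
  meds <- vapply(c(0.15, 0.3, 0.45), function(cv) {
    m <- sapply(1:3, function(s) {
      cohort <- simulate_cohort(small_config(seed = 100 + s, cv_base = cv))
      attr(metabolic_noise(cohort$metabolites, "control", 21), "median_cv")
    })
    mean(m)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("reproduction noise follows the two-point hand computation", {
  eff <- tibble::tibble(hen_id = c("A", "B"), group = "control",
                        month = 24L, efficiency = c(0.5, 1.0))
  rn <- reproduction_noise_trajectory(eff)
  expect_equal(rn$cv, sd(c(0.5, 1)) / 0.75, tolerance = 1e-12)
  same <- tibble::tibble(hen_id = c("A", "B", "C"), group = "control",
                         month = 24L, efficiency = rep(0.7, 3))
  expect_equal(reproduction_noise_trajectory(same)$cv, 0)
  lone <- tibble::tibble(hen_id = "A", group = "control", month = 24L,
                         efficiency = 0.5)
  expect_error(reproduction_noise_trajectory(lone), "Fewer than 2")
  dead <- tibble::tibble(hen_id = c("A", "B"), group = "control",
                         month = 24L, efficiency = c(0, 0))
  expect_error(reproduction_noise_trajectory(dead), "All-zero")
})

test_that("reproduction slope test wires hen matrices into the engine", {
  withr::with_seed(41, {
    months <- 24:30
    mk <- function(ids, slope) {
      tidyr::crossing(hen_id = ids, month = months) |>
        dplyr::mutate(
          group = ifelse(substr(hen_id, 1, 1) == "C", "control", "molted"),
          efficiency = pmin(pmax(
            0.8 - 0.02 * (month - 24) +
              slope * (month - 24) * (match(hen_id, ids) - mean(seq_along(ids))) / 10 +
              rnorm(dplyr::n(), 0, 0.01), 0.01), 1)
        )
    }
    ctrl <- mk(sprintf("C%02d", 1:20), 0.015)   # spread grows: CV rises
    molt <- mk(sprintf("M%02d", 1:20), -0.002)  # spread shrinks slightly
  })
  eff <- dplyr::bind_rows(ctrl, molt)
  res <- reproduction_slope_test(eff, unique(ctrl$hen_id),
                                 unique(molt$hen_id), window = 24:30,
                                 n_perm = 500, seed = 6)
  expect_lte(res$p_value, 0.01)
  expect_error(
    reproduction_slope_test(dplyr::filter(eff, month > 25),
                            unique(ctrl$hen_id), unique(molt$hen_id),
                            window = 24:30, n_perm = 10),
    "missing months"
  )
  flat <- dplyr::mutate(eff, efficiency = 0.7)
  res_flat <- reproduction_slope_test(flat, unique(ctrl$hen_id),
                                      unique(molt$hen_id), window = 24:30,
                                      n_perm = 100, seed = 1)
  expect_equal(res_flat$p_value, 1)
})

test_that("cytokine normalization fixes the baseline at one", {
  cohort <- default_cohort()
  cp <- cytokine_panel_comparison(cohort$cytokines, n_perm = 50, seed = 3)
  base <- dplyr::filter(as_tibble(cp), age_months == 21)
  expect_true(all(abs(base$normalized - 1) < 1e-12))
  meds <- attr(cp, "medians")
  expect_true(all(abs(meds$median_normalized[meds$age_months == 21] - 1) < 1e-12))
})

test_that("a uniform 1.5x cytokine elevation is detected by permutation", {
  withr::with_seed(19, {
    chans <- paste0("ch", 1:9)
    hens <- tibble::tibble(
      hen_id = c(paste0("C", 1:4), paste0("M", 1:4)),
      group = rep(c("control", "molted"), each = 4)
    )
    panel <- tidyr::crossing(hens, age_months = c(21L, 27L), channel = chans) |>
      dplyr::mutate(value = exp(rnorm(dplyr::n(), 4, 0.1)) *
                      ifelse(group == "molted" & age_months == 27, 1.5, 1))
  })
  cp <- cytokine_panel_comparison(panel, n_perm = 1000, seed = 8)
  comp <- attr(cp, "comparisons")
  expect_lte(comp$p_value[comp$age_months == 27], 0.05)
  # identical groups: p = 1
  panel_same <- panel |>
    dplyr::mutate(value = rep(value[group == "control"], 2))
  cp2 <- cytokine_panel_comparison(panel_same, n_perm = 200, seed = 9)
  expect_equal(attr(cp2, "comparisons")$p_value, 1)
})
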
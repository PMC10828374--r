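# The two feature screens and their consistency-filtered intersection.

test_that("constant and non-monotone features are never aging biomarkers", {
  tab <- planted_table(seed = 1, n_feat = 30, n_signal = 6)
  # overwrite one feature with a constant and one with a valley profile
  tab$intensities["F020", ] <- 50
  ages <- tab$samples$age_months
  tab$intensities["F021", ] <- exp(log(c(`21` = 1, `27` = 3, `33` = 2)[as.character(ages)]) * 3 +
                                     rnorm(ncol(tab$intensities), 0, 0.01) + 5)
  sel <- select_aging_biomarkers(tab)
  expect_false("F020" %in% sel$feature_id)
  expect_false("F021" %in% sel$feature_id)  # medians 1, 3, 2: not monotone
  # the planted monotone features dominate the selection
  expect_gte(sum(sel$feature_id %in% sprintf("F%03d", 1:6)), 5)
  expect_true(all(sel$direction %in% c("increasing", "decreasing")))
})

test_that("OR pooling equals the union of the per-pair BH rejection sets", {
  tab <- planted_table(seed = 2, n_feat = 40, n_signal = 12, shift = 0.8)
  sel <- select_aging_biomarkers(tab, q_cutoff = 0.1)
  x <- tab$intensities
  s <- tab$samples
  union_ids <- character(0)
  for (pr in list(c(21, 27), c(21, 33), c(27, 33))) {
    p <- vapply(seq_len(nrow(x)), function(f) {
      suppressWarnings(wilcox.test(x[f, s$age_months == pr[1]],
                                   x[f, s$age_months == pr[2]],
                                   exact = FALSE)$p.value)
    }, numeric(1))
    q <- p.adjust(p, "BH")
    union_ids <- union(union_ids, rownames(x)[q <= 0.1])
  }
  expect_setequal(attr(sel, "pre_monotonic"), union_ids)
})

test_that("monotonicity filter agrees with brute-force median comparison", {
  tab <- planted_table(seed = 3, n_feat = 40, n_signal = 12, shift = 0.8)
  sel <- select_aging_biomarkers(tab)
  x <- tab$intensities
  s <- tab$samples
  for (fid in attr(sel, "pre_monotonic")) {
    med <- vapply(c(21, 27, 33), function(a) {
      median(x[fid, s$age_months == a])
    }, numeric(1))
    mono <- (med[1] < med[2] && med[2] < med[3]) ||
      (med[1] > med[2] && med[2] > med[3])
    expect_equal(fid %in% sel$feature_id, mono, label = fid)
  }
})

test_that("z-scoring cannot change the monotonicity verdict", {
  tab <- planted_table(seed = 4, n_feat = 25, n_signal = 8)
  x <- tab$intensities
  s <- tab$samples
  meds <- function(m) {
    t(vapply(seq_len(nrow(m)), function(f) {
      vapply(c(21, 27, 33), function(a) median(m[f, s$age_months == a]),
             numeric(1))
    }, numeric(3)))
  }
  raw <- meds(x)
  z <- meds((x - rowMeans(x)) / apply(x, 1, sd))
  mono <- function(m) {
    (m[, 1] < m[, 2] & m[, 2] < m[, 3]) | (m[, 1] > m[, 2] & m[, 2] > m[, 3])
  }
  expect_identical(mono(raw), mono(z))
})

test_that("selection requires all three reference timepoints", {
  tab <- planted_table(seed = 5, n_feat = 10, n_signal = 2,
                       ages = c(21, 27))
  expect_error(select_aging_biomarkers(tab), "three reference ages|missing")
  tiny <- planted_table(seed = 6, n_feat = 10, n_signal = 2, n_per_age = 2)
  expect_error(select_aging_biomarkers(tiny), "at least 3 samples")
})

test_that("a feature tracking efficiency exactly is a laying biomarker", {
  withr::with_seed(12, {
    n <- 24
    hens <- sprintf("H%02d", 1:n)
    eff <- tibble::tibble(hen_id = hens, month = 21L,
                          efficiency = runif(n, 0.2, 1))
    x <- rbind(
      F1 = eff$efficiency,              # identical to the phenotype
      matrix(exp(rnorm(5 * n, 8, 0.4)), 5,
             dimnames = list(sprintf("N%d", 1:5)))
    )
    colnames(x) <- paste0(hens, "_t21")
    tab <- toy_table(x, setNames(rep("control", n), hens))
    sel <- select_laying_biomarkers(tab, eff)
    expect_true("F1" %in% sel$feature_id)
    expect_equal(sel$rho[sel$feature_id == "F1"], 1)
    expect_equal(sel$sign[sel$feature_id == "F1"], 1L)
  })
})

test_that("laying screen errors on unmatched efficiencies", {
  cohort <- small_cohort()
  eff <- monthly_efficiency(cohort$laying)
  expect_error(
    select_laying_biomarkers(cohort$metabolites,
                             dplyr::filter(eff, month != 21)),
    "No efficiency"
  )
})

test_that("planted laying features are recovered from the full cohort", {
  cohort <- default_cohort()
  eff <- monthly_efficiency(cohort$laying)
  sel <- select_laying_biomarkers(cohort$metabolites, eff)
  perf <- selection_performance(sel, cohort$truth$laying_features, 693)
  expect_gte(perf$sensitivity, 0.8)
  # signs follow the planted coupling for the true positives
  joined <- dplyr::inner_join(as_tibble(sel)[, c("feature_id", "sign")],
                              cohort$truth$laying_features, by = "feature_id")
  expect_gte(mean(joined$sign.x == joined$sign.y), 0.95)
})

test_that("common markers apply the sign and molt-intermediate filters", {
  empty_a <- structure(tibble::tibble(feature_id = "A", chemical_group = "x",
                                      direction = "increasing"),
                       kind = "aging", params = list(ages = c(21, 27, 33)),
                       class = c("biomarker_set", class(tibble::tibble())))
  empty_l <- structure(tibble::tibble(feature_id = "B", rho = 0.5, sign = 1L),
                       kind = "laying", params = list(),
                       class = c("biomarker_set", class(tibble::tibble())))
  expect_equal(nrow(common_markers(empty_a, empty_l)), 0)

  # a feature aging upward with a positive efficiency correlation breaks
  # the "higher efficiency looks younger" rule
  lay_bad <- structure(tibble::tibble(feature_id = "A", rho = 0.5, sign = 1L),
                       kind = "laying", params = list(),
                       class = c("biomarker_set", class(tibble::tibble())))
  out <- common_markers(empty_a, lay_bad, require_molt_intermediate = FALSE)
  expect_equal(nrow(out), 0)

  cohort <- default_cohort()
  eff <- monthly_efficiency(cohort$laying)
  aging <- select_aging_biomarkers(cohort$metabolites)
  laying <- select_laying_biomarkers(cohort$metabolites, eff)
  common <- common_markers(aging, laying, cohort$metabolites)
  # planted dual-role features carry opposite signs by construction, so
  # recovered intersection members pass the sign filter
  planted_both <- intersect(cohort$truth$aging_features$feature_id,
                            cohort$truth$laying_features$feature_id)
  sign_only <- common_markers(aging, laying,
                              require_molt_intermediate = FALSE)
  recovered <- intersect(planted_both, intersect(aging$feature_id,
                                                 laying$feature_id))
  expect_gte(mean(recovered %in% sign_only$feature_id), 0.9)
  expect_true(all(common$feature_id %in% sign_only$feature_id))
})

test_that("selection is deterministic and serializes cleanly", {
  cohort <- small_cohort()
  s1 <- select_aging_biomarkers(cohort$metabolites, ages = c(21, 25, 27))
  s2 <- select_aging_biomarkers(cohort$metabolites, ages = c(21, 25, 27))
  expect_identical(as_tibble(s1), as_tibble(s2))
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "set.json")
  write_biomarker_set(s1, jp)
  parsed <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(parsed$kind, "aging")
  expect_equal(nrow(parsed$records), nrow(s1))
})
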
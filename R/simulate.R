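# Cohort simulator: plants the longitudinal structure the downstream
# statistics are designed to detect -- age-monotone metabolite trends,
# fecundity-coupled features, age-increasing control CV, molt-attenuated
# aging with reduced CV, declining laying efficiency with post-molt
# recovery, and sterility-coupled mortality -- and records all of it in a
# queryable ground-truth object.

MOLT_START_MONTH <- 22L  # molt spans months 22-23; steady state from 24
MOLT_END_MONTH <- 23L

CYTOKINE_CHANNELS <- c("IFNg", "IL-6", "IL-10", "IL-12p40", "IL-16",
                       "IL-21", "Netrin", "Pentraxin", "Rantes")

#' Calendar for a laying study
#'
#' Months are indexed by hen age; all hens share a hatching date, so a
#' single calendar serves the whole flock. Month lengths alternate 31/30
#' days (within the 28-31 day contract; no leap handling is attempted).
#'
#' @param from_month,to_month First and last age-month covered.
#' @return Tibble with `month`, `n_days`, `first_day`, `last_day`; day 1 is
#'   the first day of `from_month`.
#' @export
laying_calendar <- function(from_month = 21L, to_month = 33L) {
  months <- seq(from_month, to_month)
  n_days <- ifelse(months %% 2 == 1, 31L, 30L)
  last <- cumsum(n_days)
  tibble(month = months, n_days = n_days,
         first_day = last - n_days + 1L, last_day = last)
}

month_of_day <- function(day, calendar) {
  calendar$month[findInterval(day, calendar$first_day)]
}

# Latent fecundity of one hen at integer months. Logistic decline with a
# hen-level intercept; molted hens drop to zero across the molt window and
# restart from a tighter, higher intercept with an attenuated decline.
latent_fecundity <- function(months, intercept, post_intercept, group,
                             decline_rate, attenuation, collapse_month) {
  f <- plogis(intercept - decline_rate * (months - 21))
  if (group == "molted") {
    mid <- months >= MOLT_START_MONTH & months <= MOLT_END_MONTH
    post <- months > MOLT_END_MONTH
    f[mid] <- 0
    f[post] <- plogis(post_intercept -
                        decline_rate * attenuation *
                        (months[post] - (MOLT_END_MONTH + 1)))
  }
  if (!is.na(collapse_month)) f[months >= collapse_month] <- 0
  f
}

#' Simulate a longitudinal molting cohort
#'
#' Generates a control and a molted arm followed from 21 to the last
#' sampling age: daily egg-laying logs with sterility-coupled mortality, a
#' feature-by-sample metabolite intensity table for the 12-hen metabolomics
#' subsets at each sampling age, a 9-channel cytokine panel, and a
#' `sim_truth` object recording every planted signal.
#'
#' Metabolite intensities are log-normal with per-feature scales spanning
#' four orders of magnitude. Planted aging features shift their group
#' median log-intensity by `aging_effect_size` baseline SDs per 12 months
#' in controls and by `molt_attenuation` times that rate in molted hens
#' after the molt; fecundity-coupled features shift with each hen's latent
#' fecundity; multiplicative noise follows the configured CV schedule.
#' Control metabolomics subsets are drawn at random per timepoint; the
#' molted subset excludes the top 10 percent of layers at month 21 and is
#' then tracked longitudinally, as in the study design the simulator
#' emulates.
#'
#' @param config A [sim_config()].
#' @return A `hen_cohort` list with elements `metabolites`
#'   (a [metabolite_table()]), `laying` (long tibble `hen_id`, `group`,
#'   `day`, `month`, `egg`, with `calendar` and `deaths` attributes),
#'   `cytokines` (tibble `hen_id`, `group`, `age_months`, `channel`,
#'   `value`), `truth` (a `sim_truth`), and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 1, n_features = 40,
#'                                      n_hens_per_group = 8))
#' glance(cohort$metabolites)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_rng_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  ages <- as.integer(config$ages)
  last_month <- max(ages)
  calendar <- laying_calendar(21L, last_month)
  n <- config$n_hens_per_group
  hens <- tibble(
    hen_id = c(sprintf("C%02d", seq_len(n)), sprintf("M%02d", seq_len(n))),
    group = rep(c("control", "molted"), each = n)
  )

  decline_rate <- config$efficiency_decline_per_month / 0.105
  hens$intercept <- rnorm(nrow(hens), qlogis(0.82), 0.5)
  # Hen quality persists through the molt: the post-molt intercept keeps
  # half of the hen's pre-molt deviation (tighter spread = the reset that
  # lowers post-molt heterogeneity).
  hens$post_intercept <- qlogis(config$molt_recovery_efficiency) +
    0.5 * (hens$intercept - qlogis(0.82)) + rnorm(nrow(hens), 0, 0.2)

  # Reproductive collapse (-> sterility -> elevated mortality): monthly
  # hazard rising with age; attenuated post-molt in treated hens.
  months <- seq(21L, last_month)
  hens$collapse_month <- NA_integer_
  hens$death_month <- NA_integer_
  base_hazard <- 0.016
  hazard_growth <- 0.15
  bg_hazard <- 0.003
  for (i in seq_len(nrow(hens))) {
    for (m in months[months >= MOLT_START_MONTH]) {
      if (!is.na(hens$death_month[i])) break
      h <- base_hazard * exp(hazard_growth * (m - 21))
      if (hens$group[i] == "molted") {
        # the molt resets the reproductive tract: collapse hazard scaled to
        # the treated arm's much lower mortality regime (~13% vs ~34%)
        if (m <= MOLT_END_MONTH) h <- 0
        else h <- h * 0.3
      }
      if (is.na(hens$collapse_month[i]) && runif(1) < h) {
        hens$collapse_month[i] <- m
        if (runif(1) < config$sterility_mortality_coupling) {
          dm <- m + sample(1:3, 1)
          # deaths falling past the study window are censored (hen ends the
          # study sterile but alive), keeping death strictly after onset
          if (dm <= last_month) hens$death_month[i] <- dm
        }
      }
      if (is.na(hens$death_month[i]) && runif(1) < bg_hazard) {
        hens$death_month[i] <- m
      }
    }
  }

  # Latent fecundity per hen-month, then daily Bernoulli egg events.
  fec <- tidyr::crossing(hens[, c("hen_id", "group")], month = months) |>
    left_join(hens, by = c("hen_id", "group")) |>
    mutate(fecundity = purrr::pmap_dbl(
      list(.data$month, .data$intercept, .data$post_intercept, .data$group,
           .data$collapse_month),
      function(m, a, a2, g, cm) {
        latent_fecundity(m, a, a2, g, decline_rate,
                         config$molt_attenuation, cm)
      }
    )) |>
    select("hen_id", "group", "month", "fecundity")

  day_grid <- calendar |>
    rowwise() |>
    reframe(month = .data$month, day = seq(.data$first_day, .data$last_day))
  hens$death_day <- NA_integer_
  for (i in seq_len(nrow(hens))) {
    dm <- hens$death_month[i]
    if (is.na(dm)) next
    row <- calendar[calendar$month == dm, ]
    dd <- row$first_day + sample.int(row$n_days, 1) - 1L
    cm <- hens$collapse_month[i]
    if (!is.na(cm)) {
      cstart <- calendar$first_day[calendar$month == cm]
      dd <- max(dd, cstart + 21L)  # death follows >= 3 weeks of sterility
    }
    hens$death_day[i] <- min(dd, max(calendar$last_day))
  }

  laying <- tidyr::crossing(hens[, c("hen_id", "group")], day_grid) |>
    left_join(hens[, c("hen_id", "death_day")], by = "hen_id") |>
    filter(is.na(.data$death_day) | .data$day <= .data$death_day) |>
    left_join(fec, by = c("hen_id", "group", "month")) |>
    mutate(egg = rbinom(n(), 1L, .data$fecundity)) |>
    select("hen_id", "group", "day", "month", "egg") |>
    arrange(.data$hen_id, .data$day)
  attr(laying, "calendar") <- calendar
  attr(laying, "deaths") <- hens |>
    filter(!is.na(.data$death_day)) |>
    select("hen_id", "group", "death_day", "death_month")

  # --- metabolomics subsets -------------------------------------------------
  # 12 hens per group/timepoint at the study's cohort size; smaller cohorts
  # scale down so the top-fraction exclusion still leaves a pool
  n_sub <- min(12L, max(2L, floor(0.8 * n)))
  molted_ages <- ages[ages < MOLT_START_MONTH | ages > MOLT_END_MONTH]
  survivors_m <- hens |>
    filter(.data$group == "molted",
           is.na(.data$death_month) | .data$death_month > last_month)
  molted_subset <- select_metabolomics_subset(
    laying, group = "molted", n = n_sub, exclude_top_fraction = 0.1,
    seed = NULL, month = 21L, eligible = survivors_m$hen_id
  )
  sample_rows <- list()
  for (a in ages) {
    alive_c <- hens |>
      filter(.data$group == "control",
             is.na(.data$death_month) | .data$death_month > a)
    ctrl <- select_metabolomics_subset(
      laying, group = "control", n = n_sub, exclude_top_fraction = 0,
      seed = NULL, month = 21L, eligible = alive_c$hen_id
    )
    sample_rows[[length(sample_rows) + 1L]] <-
      tibble(hen_id = ctrl, group = "control", age_months = a)
    if (a %in% molted_ages) {
      sample_rows[[length(sample_rows) + 1L]] <-
        tibble(hen_id = molted_subset, group = "molted", age_months = a)
    }
  }
  samples <- bind_rows(sample_rows) |>
    mutate(sampling_month = .data$age_months,
           sample_id = paste0(.data$hen_id, "_t", .data$age_months)) |>
    select("sample_id", "hen_id", "group", "age_months", "sampling_month")

  # --- planted feature structure -------------------------------------------
  nf <- config$n_features
  feature_ids <- sprintf("F%04d", seq_len(nf))
  chem_groups <- sample(c("TG", "PC", "PE", "Cer", "FA", "AA", "organic_acid",
                          "nucleotide", "sugar", "other"),
                        nf, replace = TRUE,
                        prob = c(.18, .12, .08, .06, .12, .16, .1, .06, .06, .06))
  n_aging <- round(config$frac_aging_features * nf)
  n_laying <- round(config$frac_laying_features * nf)
  aging_idx <- sample.int(nf, n_aging)
  laying_idx <- sample.int(nf, n_laying)
  direction <- integer(nf)
  direction[aging_idx] <- sample(c(-1L, 1L), n_aging, replace = TRUE)
  lay_sign <- integer(nf)
  lay_sign[laying_idx] <- sample(c(-1L, 1L), n_laying, replace = TRUE)
  # Features planted as both aging and fecundity-coupled get opposite signs
  # (a feature rising with age falls with fecundity), so that higher
  # efficiency always "looks younger" -- the consistency the common-marker
  # filter screens for.
  both <- intersect(aging_idx, laying_idx)
  lay_sign[both] <- -direction[both]

  log_base <- runif(nf, log(1e3), log(1e7))
  sigma_base <- sqrt(log(1 + config$cv_base^2))

  # Metabolic age progress (months of metabolic aging since month 21).
  progress <- ifelse(
    samples$group == "control", samples$age_months - 21,
    ifelse(samples$age_months <= MOLT_END_MONTH, 0,
           config$molt_attenuation * (samples$age_months - 21))
  )
  cv_cell <- ifelse(
    samples$group == "control",
    config$cv_base + config$cv_age_slope * (samples$age_months - 21),
    ifelse(samples$age_months < MOLT_START_MONTH, config$cv_base,
           pmax(config$cv_base - config$cv_molt_reduction, 0.02))
  )
  sigma_cell <- sqrt(log(1 + cv_cell^2))
  fec_at_sampling <- samples |>
    left_join(fec, by = c("hen_id", "group", "sampling_month" = "month")) |>
    pull("fecundity")
  # Fecundity-coupled features track the hen's deviation from the
  # group-typical fecundity trajectory (0.1 of deviation = one
  # laying_effect_size x SD shift): hen-level reproductive state, not the
  # shared age decline, which belongs to the planted aging features alone.
  typical_fec <- vapply(seq_len(nrow(samples)), function(i) {
    latent_fecundity(samples$sampling_month[i], qlogis(0.82),
                     qlogis(config$molt_recovery_efficiency),
                     samples$group[i], decline_rate,
                     config$molt_attenuation, NA_integer_)
  }, numeric(1))
  # saturating response: a collapsed hen's deviation is large (-0.3 and
  # beyond), but its metabolic correlates plateau rather than scale
  # linearly; tanh caps the planted shift at one laying_effect_size SD
  # while preserving the ordering the rank-based screen sees
  fec_resid <- 0.1 * tanh((fec_at_sampling - typical_fec) / 0.1)

  ns <- nrow(samples)
  log_int <- matrix(log_base, nf, ns) +
    outer(direction * config$aging_effect_size * sigma_base, progress / 12) +
    outer(lay_sign * config$laying_effect_size * sigma_base,
          fec_resid / 0.1) +
    matrix(rnorm(nf * ns), nf, ns) * rep(sigma_cell, each = nf)
  intensities <- exp(log_int)
  if (config$dropout_rate > 0) {
    # Below-detection events imputed at half the feature minimum, the usual
    # limit-of-detection convention; keeps the table complete and positive.
    drop <- matrix(runif(nf * ns) < config$dropout_rate, nf, ns)
    lod <- apply(intensities, 1, min) / 2
    intensities[drop] <- rep(lod, times = ns)[drop]
  }
  metabolites <- metabolite_table(
    intensities,
    tibble(feature_id = feature_ids, chemical_group = chem_groups),
    samples
  )

  # --- cytokine panel (9 channels, 4 hens/group/timepoint) ------------------
  cyto_ages <- intersect(ages, c(21L, ages[ages > MOLT_END_MONTH]))
  cyto_base <- exp(runif(length(CYTOKINE_CHANNELS), log(50), log(5000)))
  cyto_hens <- bind_rows(
    tibble(hen_id = head(samples$hen_id[samples$group == "control" &
                                          samples$age_months == 21], 4),
           group = "control"),
    tibble(hen_id = head(molted_subset, 4), group = "molted")
  )
  cytokines <- tidyr::crossing(cyto_hens, age_months = cyto_ages,
                               channel = CYTOKINE_CHANNELS) |>
    mutate(
      decay = ifelse(.data$group == "control", 0.04, 0.04 * 0.3),
      value = cyto_base[match(.data$channel, CYTOKINE_CHANNELS)] *
        exp(-.data$decay * (.data$age_months - 21) + rnorm(n(), 0, 0.2))
    ) |>
    select("hen_id", "group", "age_months", "channel", "value")

  truth <- structure(list(
    aging_features = tibble(feature_id = feature_ids[sort(aging_idx)],
                            direction = direction[sort(aging_idx)]),
    laying_features = tibble(feature_id = feature_ids[sort(laying_idx)],
                             sign = lay_sign[sort(laying_idx)]),
    hens = hens |>
      mutate(sterility_onset_month = .data$collapse_month) |>
      select("hen_id", "group", "intercept", "post_intercept",
             "sterility_onset_month", "death_month", "death_day"),
    fecundity = fec,
    molted_subset = molted_subset,
    params = list(molt_attenuation = config$molt_attenuation,
                  aging_effect_size = config$aging_effect_size,
                  laying_effect_size = config$laying_effect_size)
  ), class = "sim_truth")

  structure(list(metabolites = metabolites, laying = laying,
                 cytokines = cytokines, truth = truth, config = config),
            class = "hen_cohort")
}

#' @export
print.hen_cohort <- function(x, ...) {
  cat("<hen_cohort> seed", x$config$seed, "\n")
  print(x$metabolites)
  d <- attr(x$laying, "deaths")
  cat("deaths:", sum(d$group == "control"), "control,",
      sum(d$group == "molted"), "molted\n")
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", nrow(x$aging_features), "aging features,",
      nrow(x$laying_features), "fecundity-coupled features\n")
  invisible(x)
}

#' Select the metabolomics subset of a group
#'
#' Mirrors the study's hen-selection rule: for the treated group, hens with
#' month-21 laying efficiency strictly above the
#' `1 - exclude_top_fraction` quantile are removed (the near-100 percent
#' layers the treatment was not aimed at), and `n` hens are then drawn
#' uniformly from the remaining pool; controls use
#' `exclude_top_fraction = 0`, i.e. a pure random draw.
#'
#' @param laying Long laying log (`hen_id`, `group`, `day`, `month`, `egg`).
#' @param group Group to select from.
#' @param n Number of hens to return.
#' @param exclude_top_fraction Fraction of top layers to exclude first.
#' @param seed Optional seed (NULL inherits the caller's RNG state).
#' @param month Month whose efficiency drives the exclusion (default 21).
#' @param eligible Optional hen-id whitelist (e.g. hens alive through the
#'   study, when selection happens after the fact).
#' @return Character vector of `n` hen ids.
#' @export
select_metabolomics_subset <- function(laying, group, n,
                                       exclude_top_fraction = 0,
                                       seed = NULL, month = 21L,
                                       eligible = NULL) {
  stopifnot(is.numeric(n), n >= 1)
  if (exclude_top_fraction < 0 || exclude_top_fraction >= 1) {
    abort("`exclude_top_fraction` must lie in [0, 1).")
  }
  eff <- monthly_efficiency(laying) |>
    filter(.data$month == !!month, .data$group == !!group)
  if (!is.null(eligible)) eff <- filter(eff, .data$hen_id %in% eligible)
  pool <- eff
  if (exclude_top_fraction > 0) {
    cut <- quantile(eff$efficiency, 1 - exclude_top_fraction, names = FALSE)
    pool <- filter(eff, .data$efficiency <= cut)  # ties at the cut are kept
  }
  if (nrow(pool) < n) {
    abort(paste0("Only ", nrow(pool), " hens remain after exclusion; ",
                 n, " requested."))
  }
  with_rng_seed(seed, sort(sample(pool$hen_id, n)))
}

#' Write simulator outputs to plain-text files
#'
#' @param laying Laying log tibble.
#' @param path CSV path; the long-form log (`hen_id`, `day`, `egg`) goes to
#'   `path`, hen-level survival metadata to a `.hens.csv` companion.
#' @return Paths, invisibly.
#' @export
write_laying_log <- function(laying, path) {
  readr::write_csv(laying[, c("hen_id", "day", "egg")], path)
  hens_path <- sub("\\.csv$", ".hens.csv", path)
  deaths <- attr(laying, "deaths")
  hens <- distinct(laying, .data$hen_id, .data$group) |>
    left_join(deaths, by = c("hen_id", "group"))
  readr::write_csv(hens, hens_path)
  invisible(c(path, hens_path))
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(
    list(aging_features = truth$aging_features,
         laying_features = truth$laying_features,
         hens = truth$hens,
         molted_subset = truth$molted_subset,
         params = truth$params),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}
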
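# Shared fixtures: a small fast cohort for structural tests and one cached
# study-sized cohort for tests that need the full design.

# Strong planted signals: at 8 hens/cell the screens need large effects to
# return non-empty sets, which the structural tests require.
small_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_hens_per_group = 10L, n_features = 80L,
             ages = c(21L, 23L, 25L, 27L), aging_effect_size = 6,
             laying_effect_size = 2, ...)
}

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(config)
  }
  .cohort_cache[[key]]
}

default_cohort <- function() cached_cohort("default", sim_config(seed = 1))

small_cohort <- function() cached_cohort("small", small_config())

# Hand-built metabolite table: intensities supplied directly, metadata
# derived from the column naming hen<ID>_t<age>.
toy_table <- function(intensities, group_of_hen, chemical_group = "other") {
  ids <- colnames(intensities)
  hen <- sub("_t\\d+$", "", ids)
  age <- as.integer(sub("^.*_t", "", ids))
  metabolite_table(
    intensities,
    tibble::tibble(
      feature_id = rownames(intensities),
      chemical_group = rep_len(chemical_group, nrow(intensities))
    ),
    tibble::tibble(sample_id = ids, hen_id = hen,
                   group = unname(group_of_hen[hen]),
                   age_months = age, sampling_month = age)
  )
}

# A table with planted monotone-age features, for selection tests:
# features 1..n_signal shift their log-mean by `shift` per age step.
planted_table <- function(seed, n_feat = 40, n_signal = 10, n_per_age = 8,
                          ages = c(21, 27, 33), shift = 2, sd_log = 0.25) {
  withr::with_seed(seed, {
    hens <- sprintf("H%02d", seq_len(n_per_age * length(ages)))
    samp <- tibble::tibble(
      hen_id = hens,
      age_months = rep(ages, each = n_per_age)
    )
    mu <- matrix(rep(runif(n_feat, 6, 14), nrow(samp)), n_feat)
    step <- match(samp$age_months, ages) - 1
    sig <- rbind(
      outer(rep(shift * sd_log, n_signal), step),
      matrix(0, n_feat - n_signal, nrow(samp))
    )
    x <- exp(mu + sig + matrix(rnorm(n_feat * nrow(samp), 0, sd_log), n_feat))
    rownames(x) <- sprintf("F%03d", seq_len(n_feat))
    colnames(x) <- paste0(samp$hen_id, "_t", samp$age_months)
    toy_table(x, setNames(rep("control", length(hens)), hens))
  })
}
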
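#' Simulation configuration for a longitudinal hen cohort
#'
#' Bundles every constant the cohort simulator needs: study design (group
#' sizes, metabolite panel size, blood-sampling ages), planted signal
#' structure (which fractions of features age or track fecundity, and how
#' strongly), the noise model (baseline coefficient of variation, its drift
#' with age in untreated hens, and the post-molt reduction), and the
#' reproduction/mortality model (efficiency decline, post-molt recovery, and
#' the coupling between sterility and death).
#'
#' Effect sizes are standardized: `aging_effect_size` is the shift of a
#' feature's log-intensity group median per 12 months of age, in units of the
#' feature's baseline log-scale standard deviation; `molt_attenuation`
#' multiplies that rate for treated hens after the molt (2/3 emulates a
#' cohort that ages 8 metabolic months per 12 chronological ones).
#' `laying_effect_size` is the analogous standardized shift per unit of
#' latent fecundity for fecundity-tracking features.
#'
#' @param seed Integer seed; every stochastic choice in the simulator is
#'   derived from it.
#' @param n_hens_per_group Hens enrolled per arm (default 32).
#' @param n_features Number of metabolite features (default 693).
#' @param ages Blood-sampling ages in months (default `c(21, 23, 27, 33)`);
#'   the second age is a control-only validation timepoint — treated hens
#'   are molted across it and are not sampled then.
#' @param frac_aging_features Fraction of features with a planted monotone
#'   age trend (default 0.3).
#' @param frac_laying_features Fraction of features coupled to latent
#'   fecundity (default 0.27).
#' @param aging_effect_size Standardized median shift per 12 months
#'   (default 2.5, the regime in which the pairwise screen at 12 hens per
#'   group selects roughly 210 of 693 features — the marker yield the
#'   simulator is meant to emulate).
#' @param molt_attenuation Multiplicative factor on the aging rate of
#'   treated hens after the molt, in (0, 1] (default 2/3).
#' @param laying_effect_size Standardized shift per 0.1 of a hen's
#'   (saturating) fecundity deviation for fecundity-coupled features
#'   (default 2.0, giving planted features a Spearman correlation with
#'   efficiency around 0.5).
#' @param cv_base Baseline per-feature coefficient of variation
#'   (default 0.25).
#' @param cv_age_slope Increase of the control CV per month of age
#'   (default 0.005).
#' @param cv_molt_reduction Additive CV drop in treated hens after the molt
#'   (default 0.05).
#' @param efficiency_decline_per_month Decline of median laying efficiency
#'   per month near the study start (default 0.02).
#' @param molt_recovery_efficiency Median efficiency treated hens recover to
#'   after the molt (default 0.9).
#' @param sterility_mortality_coupling Probability that a sterile hen dies
#'   within three months of sterility onset (default 0.7).
#' @param dropout_rate Fraction of intensity entries set missing
#'   (default 0; the simulator emits complete tables).
#'
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_features
#' @export
sim_config <- function(seed = 1L,
                       n_hens_per_group = 32L,
                       n_features = 693L,
                       ages = c(21L, 23L, 27L, 33L),
                       frac_aging_features = 0.3,
                       frac_laying_features = 0.27,
                       aging_effect_size = 2.5,
                       molt_attenuation = 2 / 3,
                       laying_effect_size = 2.0,
                       cv_base = 0.25,
                       cv_age_slope = 0.005,
                       cv_molt_reduction = 0.05,
                       efficiency_decline_per_month = 0.02,
                       molt_recovery_efficiency = 0.9,
                       sterility_mortality_coupling = 0.7,
                       dropout_rate = 0) {
  cfg <- list(
    seed = seed,
    n_hens_per_group = n_hens_per_group,
    n_features = n_features,
    ages = ages,
    frac_aging_features = frac_aging_features,
    frac_laying_features = frac_laying_features,
    aging_effect_size = aging_effect_size,
    molt_attenuation = molt_attenuation,
    laying_effect_size = laying_effect_size,
    cv_base = cv_base,
    cv_age_slope = cv_age_slope,
    cv_molt_reduction = cv_molt_reduction,
    efficiency_decline_per_month = efficiency_decline_per_month,
    molt_recovery_efficiency = molt_recovery_efficiency,
    sterility_mortality_coupling = sterility_mortality_coupling,
    dropout_rate = dropout_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("seed", "n_hens_per_group", "n_features", "ages",
              "frac_aging_features", "frac_laying_features",
              "aging_effect_size", "molt_attenuation", "laying_effect_size",
              "cv_base", "cv_age_slope", "cv_molt_reduction",
              "efficiency_decline_per_month", "molt_recovery_efficiency",
              "sterility_mortality_coupling", "dropout_rate")) {
    stopifnot_finite(cfg[[f]], f)
  }
  fracs <- c("frac_aging_features", "frac_laying_features", "dropout_rate",
             "molt_recovery_efficiency", "sterility_mortality_coupling",
             "efficiency_decline_per_month")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("`", f, "` must lie in [0, 1]."))
    }
  }
  if (cfg$n_features < 1) abort("`n_features` must be >= 1.")
  if (cfg$n_hens_per_group < 2) abort("`n_hens_per_group` must be >= 2.")
  if (length(cfg$ages) < 2 || any(diff(cfg$ages) <= 0)) {
    abort("`ages` must be strictly increasing with at least two timepoints.")
  }
  if (cfg$molt_attenuation <= 0 || cfg$molt_attenuation > 1) {
    abort("`molt_attenuation` must lie in (0, 1].")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  hens/group:", x$n_hens_per_group,
      " features:", x$n_features,
      " sampling ages:", paste(x$ages, collapse = ", "), "months\n")
  cat("  planted: ", round(x$frac_aging_features * x$n_features),
      " aging features (", x$aging_effect_size, " SD/yr), ",
      round(x$frac_laying_features * x$n_features),
      " fecundity-coupled features\n", sep = "")
  cat("  molt attenuation:", signif(x$molt_attenuation, 3),
      " CV base:", x$cv_base, "\n")
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' The YAML keys mirror the `sim_config()` argument names exactly, so a
#' config written by one run can seed another verbatim.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), names(formals(sim_config)))
  if (length(extra)) {
    abort(paste0("Unknown config fields: ", paste(extra, collapse = ", ")))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}
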
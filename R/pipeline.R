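# End-to-end orchestration: simulate -> phenotypes -> biomarker screens ->
# age models -> noise statistics -> report. Every stage reads/writes the
# package's plain-text interfaces, so any stage can also be run on
# user-supplied tables.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", name, "] ", conditionMessage(e)))
  })
}

#' Recovery of a planted feature set by a biomarker screen
#'
#' @param set A `biomarker_set`.
#' @param truth_features Tibble of planted ids (first column feature ids).
#' @param universe Size of the feature universe.
#' @return One-row tibble: `n_selected`, `n_true`, `sensitivity`
#'   (recall of planted ids), `precision` (fraction of selections
#'   planted).
#' @export
selection_performance <- function(set, truth_features, universe) {
  sel <- set$feature_id
  true_ids <- truth_features[[1]]
  tp <- length(intersect(sel, true_ids))
  tibble(
    n_selected = length(sel), n_true = length(true_ids),
    sensitivity = if (length(true_ids)) tp / length(true_ids) else NA_real_,
    precision = if (length(sel)) tp / length(sel) else NA_real_
  )
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes the whole chain — cohort simulation, reproduction/survival
#' phenotypes, both biomarker screens and their intersection, the PCA age
#' axis and random-forest age model, leave-one-out efficiency prediction,
#' and all noise statistics — writing every intermediate table plus a
#' machine-readable summary to `outdir`. Identical configs produce
#' byte-identical summaries.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param n_perm Permutations for every permutation test (default 200).
#' @param q_cutoff FDR cutoff for both screens (default 0.1).
#' @param efficiency_mode `"rfr"` or `"lasso_rfr"` for the LOO efficiency
#'   model.
#' @param ntree Forest size (default 500).
#' @return The summary as a nested list (invisibly writes
#'   `summary.json` when `outdir` is given).
#' @export
run_pipeline <- function(config, outdir = NULL, n_perm = 200L,
                         q_cutoff = 0.1, efficiency_mode = "rfr",
                         ntree = 500L) {
  cohort <- run_stage("simulate", simulate_cohort(config))
  mt <- cohort$metabolites
  ages3 <- config$ages[config$ages != 23][1:3]

  eff <- run_stage("phenotypes", monthly_efficiency(cohort$laying))
  surv <- run_stage("phenotypes", survival_records(cohort$laying))
  surv_c <- filter(surv, .data$group == "control")
  surv_m <- filter(surv, .data$group == "molted")
  mort_c <- mortality_fraction(surv_c)
  mort_m <- mortality_fraction(surv_m)
  fisher_p <- fisher_exact_2x2(sterility_mortality_table(surv_c))
  binom_p <- binomial_survival_test(mort_c$deaths, mort_c$n,
                                    mort_m$deaths, mort_m$n)

  aging <- run_stage("select-biomarkers",
                     select_aging_biomarkers(mt, q_cutoff, ages3))
  laying_bm <- run_stage("select-biomarkers",
                         select_laying_biomarkers(mt, eff, q_cutoff))
  common <- run_stage("select-biomarkers",
                      common_markers(aging, laying_bm, mt))
  perf_aging <- selection_performance(aging, cohort$truth$aging_features,
                                      config$n_features)
  perf_laying <- selection_performance(laying_bm, cohort$truth$laying_features,
                                       config$n_features)

  # marker-based modelling only makes sense when the screens returned
  # something to model on (a signal-free cohort legitimately yields an
  # empty set, which the summary flags via the biomarker counts)
  model_seed <- child_seed(config$seed, "age-model")
  have_aging <- nrow(aging) >= 2
  axis <- contrast <- age_pred <- NULL
  spans <- list(control = NA_real_, molted = NA_real_)
  if (have_aging) {
    axis <- run_stage("age-model", {
      norm <- zscore_normalize(mt, features = aging$feature_id)
      pca_age_axis(norm, ages3)
    })
    contrast <- run_stage("age-model", {
      axis_aging_contrast(axis, min(ages3), max(ages3), n_perm,
                          child_seed(config$seed, "axis-contrast"))
    })
    age_model <- run_stage("age-model",
                           train_age_regressor(mt, aging$feature_id,
                                               model_seed, ages3, ntree))
    age_pred <- run_stage("age-model", predict(age_model, mt))
    spans <- list(
      control = predicted_age_span(age_pred, "control", min(ages3), max(ages3)),
      molted = predicted_age_span(age_pred, "molted", min(ages3), max(ages3))
    )
  }

  have_laying <- nrow(laying_bm) >= 2
  loo <- transfer <- NULL
  if (have_laying) {
    loo <- run_stage("predict-efficiency",
                     loo_predict_efficiency(mt, eff, laying_bm$feature_id,
                                            child_seed(config$seed, "loo"),
                                            efficiency_mode, ntree))
    eff_model <- run_stage("predict-efficiency",
                           train_efficiency_regressor(
                             mt, eff, laying_bm$feature_id,
                             child_seed(config$seed, "transfer"),
                             efficiency_mode, ntree))
    transfer <- run_stage("predict-efficiency",
                          predict_efficiency_transfer(eff_model, mt, eff))
  }

  noise <- run_stage("noise",
                     noise_trajectory(mt, n_perm = n_perm,
                                      seed = child_seed(config$seed, "noise")))
  repro_noise <- run_stage("noise", {
    alive_all <- surv |> filter(!.data$died)
    window <- seq(24, min(30, max(config$ages) - 1))
    eff_alive <- filter(eff, .data$hen_id %in% alive_all$hen_id)
    # molted hens lay nothing across the molt window, so their CV is
    # undefined there; report their trajectory outside it
    traj <- bind_rows(
      reproduction_noise_trajectory(eff_alive, groups = "control"),
      reproduction_noise_trajectory(
        filter(eff_alive, !(.data$month %in% MOLT_START_MONTH:MOLT_END_MONTH)),
        groups = "molted")
    )
    list(
      trajectory = traj,
      slope_test = reproduction_slope_test(
        eff, surv$hen_id[surv$group == "control" & !surv$died],
        surv$hen_id[surv$group == "molted" & !surv$died],
        window, n_perm, child_seed(config$seed, "repro-slope"))
    )
  })
  cyto <- run_stage("noise",
                    cytokine_panel_comparison(cohort$cytokines,
                                              baseline_age = min(config$ages),
                                              n_perm = n_perm,
                                              seed = child_seed(config$seed, "cyto")))

  summary <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    phenotypes = list(
      mortality_control = as.list(mort_c),
      mortality_molted = as.list(mort_m),
      sterility_table_control = as.vector(sterility_mortality_table(surv_c)),
      fisher_p_sterility_mortality = fisher_p,
      binomial_p_mortality_difference = binom_p
    ),
    biomarkers = list(
      n_aging = nrow(aging), n_laying = nrow(laying_bm),
      n_common = nrow(common),
      aging_recovery = as.list(perf_aging),
      laying_recovery = as.list(perf_laying)
    ),
    age_model = list(
      pc1_var = if (have_aging) axis$var_explained[1] else NA_real_,
      pc2_var = if (have_aging) axis$var_explained[2] else NA_real_,
      axis_contrast_p = if (have_aging) contrast$p_value else NA_real_,
      median_predicted = if (have_aging) median_predicted_ages(age_pred),
      control_span = spans$control, molted_span = spans$molted
    ),
    efficiency_model = list(
      loo = if (have_laying) as.list(glance(loo)),
      transfer_range_capture = if (have_laying) attr(transfer, "range_capture") else NA_real_
    ),
    noise = list(
      metabolic = as_tibble(noise),
      metabolic_comparisons = attr(noise, "comparisons"),
      reproduction = repro_noise$trajectory,
      reproduction_slope_p = repro_noise$slope_test$p_value,
      cytokine_medians = attr(cyto, "medians"),
      cytokine_comparisons = attr(cyto, "comparisons")
    )
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_sim_config(config, p("config.yaml"))
    write_metabolite_table(mt, p("metabolites.tsv"))
    write_laying_log(cohort$laying, p("laying.csv"))
    write_sim_truth(cohort$truth, p("truth.json"))
    write_efficiency(eff, p("efficiency.tsv"))
    write_biomarker_set(aging, p("biomarkers_aging.json"))
    write_biomarker_set(aging, p("biomarkers_aging.tsv"))
    write_biomarker_set(laying_bm, p("biomarkers_laying.json"))
    write_biomarker_set(common, p("biomarkers_common.json"))
    if (have_aging) {
      readr::write_tsv(axis$scores, p("age_axis.tsv"))
      readr::write_tsv(age_pred, p("age_predictions.tsv"))
    }
    if (have_laying) readr::write_tsv(as_tibble(loo), p("efficiency_loo.tsv"))
    write_noise_trajectory(noise, p("noise_metabolic.tsv"))
    write_noise_trajectory(repro_noise$trajectory, p("noise_reproduction.tsv"))
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    writeLines(c(paste("run completed:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 paste("config hash:", summary$config_hash)),
               p("run.log"))
  }
  invisible(summary)
}
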
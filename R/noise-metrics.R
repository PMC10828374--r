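# Population-noise statistics: per-feature coefficients of variation, the
# metabolome-wide noise scalar (median of CVs), reproduction noise, their
# trajectories, and the cytokine-panel median comparison. All CVs are
# computed on raw positive intensities -- never on z-scores, whose
# near-zero means make sigma/mu meaningless.

#' Coefficient of variation of a feature
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Scale-invariant, which is what lets features spanning orders of
#' magnitude be pooled into one noise statistic.
#'
#' @param values Positive numeric vector, length >= 2.
#' @return sigma / mu.
#' @examples
#' feature_cv(c(1, 2, 3))  # 0.5
#' @export
feature_cv <- function(values) {
  check_numeric_input(values, "values", 2L)
  m <- mean(values)
  if (m <= 0) {
    abort("Mean must be positive: CVs are computed on raw intensities, not centered data.")
  }
  sd(values) / m
}

row_cvs <- function(x) {
  m <- rowMeans(x)
  if (any(m <= 0)) {
    abort("Non-positive feature mean: CVs require raw positive intensities.")
  }
  n <- ncol(x)
  v <- (rowSums(x^2) - n * m^2) / (n - 1)
  sqrt(pmax(v, 0)) / m
}

#' Metabolome-wide noise of one (group, age) cell
#'
#' Computes a CV per feature across the cell's samples and summarizes them
#' by their median — the metabolic-noise scalar.
#'
#' @param table A [metabolite_table()].
#' @param group Group name.
#' @param age Age in months.
#' @return A `noise_summary`: tibble (`feature_id`, `cv`) with attributes
#'   `group`, `age_months`, `median_cv`, `n_samples`.
#' @export
metabolic_noise <- function(table, group, age) {
  stopifnot(inherits(table, "metabolite_table"))
  sub <- filter_table(table, group = group, ages = age)
  if (ncol(sub$intensities) < 2) {
    abort("Need at least 2 samples in the (group, age) cell.")
  }
  cvs <- row_cvs(sub$intensities)
  structure(
    tibble(feature_id = sub$features$feature_id, cv = unname(cvs)),
    group = group, age_months = age, median_cv = median(cvs),
    n_samples = ncol(sub$intensities),
    class = c("noise_summary", class(tibble())))
}

#' @export
print.noise_summary <- function(x, ...) {
  cat("<noise_summary> ", attr(x, "group"), " at ", attr(x, "age_months"),
      " months: median CV = ", signif(attr(x, "median_cv"), 4),
      " over ", nrow(x), " features (n = ", attr(x, "n_samples"),
      ")\n", sep = "")
  invisible(x)
}

#' @export
glance.noise_summary <- function(x, ...) {
  tibble(group = attr(x, "group"), age_months = attr(x, "age_months"),
         median_cv = attr(x, "median_cv"), n_samples = attr(x, "n_samples"))
}

#' Metabolic-noise trajectory with between-group permutation tests
#'
#' The median-of-CV scalar per (group, age) cell, plus — at every age
#' where both groups are present — a hen-label permutation test on the
#' difference of the two medians: hens are reassigned between the groups,
#' the full median-of-CV is recomputed per permuted group, and the
#' fraction of permutations with an absolute difference at least the
#' observed one is the p-value.
#'
#' @param table A [metabolite_table()].
#' @param groups Groups to include (default both).
#' @param ages Ages to include (default: all in the table).
#' @param n_perm Permutations per comparison (default 1000).
#' @param seed Optional seed.
#' @return A `noise_trajectory` tibble (`group`, `age_months`,
#'   `median_cv`, `n_samples`) with a `comparisons` attribute
#'   (`age_months`, `observed_diff`, `p_value`).
#' @export
noise_trajectory <- function(table, groups = c("control", "molted"),
                             ages = NULL, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(table, "metabolite_table"))
  ages <- ages %||% sort(unique(table$samples$age_months))
  cells <- table$samples |>
    filter(.data$group %in% groups, .data$age_months %in% ages) |>
    count(.data$group, .data$age_months) |>
    filter(.data$n >= 2)
  traj <- purrr::pmap(cells, function(group, age_months, n) {
    glance(metabolic_noise(table, group, age_months))
  }) |> bind_rows()

  comparisons <- list()
  if (length(groups) == 2) {
    shared <- intersect(traj$age_months[traj$group == groups[1]],
                        traj$age_months[traj$group == groups[2]])
    for (a in shared) {
      comparisons[[length(comparisons) + 1L]] <-
        noise_cell_comparison(table, groups, a, n_perm,
                              child_seed(seed, paste0("age", a)))
    }
  }
  structure(traj, comparisons = bind_rows(comparisons),
            class = c("noise_trajectory", class(traj)))
}

# Permutation test of |median-of-CV difference| between two groups at one
# age, permuting hen labels and recomputing the full statistic each time.
noise_cell_comparison <- function(table, groups, age, n_perm, seed) {
  sub <- filter_table(table, ages = age)
  sub <- filter_table(sub, samples = sub$samples$sample_id[sub$samples$group %in% groups])
  x <- sub$intensities
  is_a <- sub$samples$group == groups[1]
  n_a <- sum(is_a)
  med_cv <- function(cols) median(row_cvs(x[, cols, drop = FALSE]))
  obs <- abs(med_cv(which(is_a)) - med_cv(which(!is_a)))
  n_extreme <- with_rng_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(ncol(x), n_a)
      abs(med_cv(idx) - med_cv(setdiff(seq_len(ncol(x)), idx))) >=
        obs - 1e-12
    }, logical(1)))
  })
  tibble(age_months = age, observed_diff = obs,
         p_value = n_extreme / n_perm, n_perm = n_perm)
}

#' Reproduction noise per group and month
#'
#' The CV of individual monthly laying efficiencies across the living
#' hens of a group, per month.
#'
#' @param efficiency Monthly efficiency tibble with `hen_id`, `group`,
#'   `month`, `efficiency`.
#' @param groups Groups to include (default: all present).
#' @param months Months to include (default: all present).
#' @return Tibble `group`, `month`, `cv`, `n_hens`.
#' @export
reproduction_noise_trajectory <- function(efficiency, groups = NULL,
                                          months = NULL) {
  groups <- groups %||% unique(efficiency$group)
  months <- months %||% sort(unique(efficiency$month))
  cells <- efficiency |>
    filter(.data$group %in% groups, .data$month %in% months) |>
    group_by(.data$group, .data$month)
  sizes <- summarise(cells, n = n(), .groups = "drop")
  if (any(sizes$n < 2)) {
    bad <- sizes[sizes$n < 2, ]
    abort(paste0("Fewer than 2 living hens for ", bad$group[1],
                 " in month ", bad$month[1], "."))
  }
  cells |>
    summarise(cv = {
      if (mean(.data$efficiency) <= 0) {
        abort("All-zero efficiencies: reproduction CV undefined.")
      }
      sd(.data$efficiency) / mean(.data$efficiency)
    }, n_hens = n(), .groups = "drop")
}

#' Paired permutation test on reproduction-noise slopes
#'
#' Compares the slope of the control and molted reproduction-noise
#' trajectories over a post-molt window (the months it takes the molted
#' CV to return to its baseline; every hen must be alive across it) using
#' the paired within-hen permutation engine: each hen's efficiencies are
#' shuffled across the window's months, the per-month CVs and their
#' slopes are recomputed, and the slope difference is compared to the
#' observed one.
#'
#' @param efficiency Monthly efficiency tibble.
#' @param control_ids,molted_ids Hen ids per group.
#' @param window Months of the comparison window (>= 3, default 24:30).
#' @param n_perm Permutations (default 1000).
#' @param seed Optional seed.
#' @return A `perm_test`.
#' @export
reproduction_slope_test <- function(efficiency, control_ids, molted_ids,
                                    window = 24:30, n_perm = 1000L,
                                    seed = NULL) {
  if (length(window) < 3) abort("`window` must span at least 3 months.")
  mat_for <- function(ids) {
    sub <- efficiency |>
      filter(.data$hen_id %in% ids, .data$month %in% window)
    wide <- sub |>
      select("hen_id", "month", "efficiency") |>
      pivot_wider(names_from = "month", values_from = "efficiency")
    absent <- setdiff(as.character(sort(window)), names(wide))
    if (length(absent)) {
      abort(paste0("Some hens are missing months inside the window (",
                   paste(absent, collapse = ", "), ")."))
    }
    m <- as.matrix(wide[, as.character(sort(window)), drop = FALSE])
    rownames(m) <- wide$hen_id
    if (anyNA(m)) {
      abort("Some hens are missing months inside the window (all hens must be alive across it).")
    }
    m
  }
  perm_slope_diff_paired(mat_for(control_ids), mat_for(molted_ids),
                         n_perm = n_perm, seed = seed)
}

#' Cytokine-panel medians with permutation comparisons
#'
#' Each channel is averaged over the hens of a (group, age) cell and
#' normalized by that channel's group value at the baseline age; the
#' median of the normalized channels is the cell's representative
#' immune measure. At every non-baseline age where both groups are
#' present, hen labels are permuted between the groups (baselines held
#' fixed) and the absolute difference of the two medians is compared to
#' the observed one.
#'
#' @param panel Tibble `hen_id`, `group`, `age_months`, `channel`,
#'   `value` (positive).
#' @param baseline_age Age the normalization references (default 21).
#' @param n_perm Permutations (default 1000).
#' @param seed Optional seed.
#' @return A `panel_summary` tibble (`group`, `age_months`, `channel`,
#'   `normalized`) with attributes `medians` (`group`, `age_months`,
#'   `median_normalized`) and `comparisons` (`age_months`, `p_value`).
#' @export
cytokine_panel_comparison <- function(panel, baseline_age = 21,
                                      n_perm = 1000L, seed = NULL) {
  need <- c("hen_id", "group", "age_months", "channel", "value")
  if (!all(need %in% names(panel))) {
    abort(paste0("`panel` needs columns: ", paste(need, collapse = ", ")))
  }
  if (!baseline_age %in% panel$age_months) abort("Baseline age missing from panel.")
  baseline <- panel |>
    filter(.data$age_months == baseline_age) |>
    group_by(.data$group, .data$channel) |>
    summarise(base = mean(.data$value), .groups = "drop")
  if (any(baseline$base <= 0)) abort("Zero baseline value for a channel.")
  cells <- panel |>
    group_by(.data$group, .data$age_months, .data$channel) |>
    summarise(mean_value = mean(.data$value), .groups = "drop") |>
    left_join(baseline, by = c("group", "channel")) |>
    mutate(normalized = .data$mean_value / .data$base)
  medians <- cells |>
    group_by(.data$group, .data$age_months) |>
    summarise(median_normalized = median(.data$normalized), .groups = "drop")

  comp_ages <- setdiff(
    intersect(unique(panel$age_months[panel$group == "control"]),
              unique(panel$age_months[panel$group == "molted"])),
    baseline_age
  )
  comparisons <- purrr::map(comp_ages, function(a) {
    at_age <- filter(panel, .data$age_months == a)
    wide <- at_age |>
      pivot_wider(id_cols = c("hen_id", "group"), names_from = "channel",
                  values_from = "value")
    chans <- setdiff(names(wide), c("hen_id", "group"))
    base_for <- function(g) {
      b <- baseline |> filter(.data$group == g)
      b$base[match(chans, b$channel)]
    }
    stat <- function(groups) {
      m <- function(g) {
        rows <- which(groups == g)
        median(colMeans(as.matrix(wide[rows, chans])) / base_for(g))
      }
      abs(m("control") - m("molted"))
    }
    obs <- stat(wide$group)
    n_extreme <- with_rng_seed(child_seed(seed, paste0("age", a)), {
      sum(vapply(seq_len(n_perm), function(i) {
        stat(sample(wide$group)) >= obs - 1e-12
      }, logical(1)))
    })
    tibble(age_months = a, observed_diff = obs,
           p_value = n_extreme / n_perm, n_perm = n_perm)
  }) |> bind_rows()

  structure(
    cells |> select("group", "age_months", "channel", "normalized"),
    medians = medians, comparisons = comparisons, baseline_age = baseline_age,
    class = c("panel_summary", class(tibble()))
  )
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("<panel_summary> baseline", attr(x, "baseline_age"), "months\n")
  print(attr(x, "medians"))
  comp <- attr(x, "comparisons")
  if (nrow(comp)) print(comp)
  invisible(x)
}

#' Write a noise trajectory as tidy TSV
#'
#' @param trajectory Output of [noise_trajectory()] or
#'   [reproduction_noise_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_noise_trajectory <- function(trajectory, path) {
  readr::write_tsv(as_tibble(trajectory), path)
  invisible(path)
}
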
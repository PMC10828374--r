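# Feature screens: aging biomarkers (pairwise Mann-Whitney + per-pair BH
# with an OR pooling rule and a strict median-monotonicity filter), laying
# biomarkers (Spearman against sampling-month efficiency + BH), and their
# consistency-filtered intersection.

new_biomarker_set <- function(records, kind, params) {
  structure(records, kind = kind, params = params,
            class = c("biomarker_set", class(records)))
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("<biomarker_set:", attr(x, "kind"), "> ", nrow(x),
      " features selected\n", sep = "")
  NextMethod()
}

#' @export
glance.biomarker_set <- function(x, ...) {
  p <- attr(x, "params")
  tibble(kind = attr(x, "kind"), n_selected = nrow(x),
         n_tested = p$n_tested %||% NA_integer_,
         q_cutoff = p$q_cutoff %||% NA_real_)
}

group_medians_by_age <- function(table, group = "control", ages) {
  sub <- filter_table(table, group = group, ages = ages)
  out <- sapply(ages, function(a) {
    cols <- sub$samples$age_months == a
    apply(sub$intensities[, cols, drop = FALSE], 1, median)
  })
  colnames(out) <- paste0("t", ages)
  out
}

#' Select aging biomarkers
#'
#' For each pair of the three reference timepoints, every feature gets a
#' two-tailed Mann-Whitney p-value between the control groups at those
#' ages; each pair's full p-value list is Benjamini-Hochberg corrected at
#' `q_cutoff`. Features significant in at least one pair (the OR pooling
#' rule) are kept, and features whose three control group medians are not
#' strictly monotone in age are then removed. Survivors carry a direction
#' (increasing or decreasing with age) and the pairs that admitted them.
#'
#' Medians are computed on raw intensities; z-scoring is a per-feature
#' monotone affine map, so the monotonicity verdict would be identical.
#'
#' @param table A [metabolite_table()] containing control samples at the
#'   three reference ages (other samples are ignored).
#' @param q_cutoff BH FDR cutoff per pair (default 0.1).
#' @param ages The three reference ages (default `c(21, 27, 33)`; the
#'   validation timepoint never enters selection).
#' @return A `biomarker_set` tibble: `feature_id`, `chemical_group`,
#'   per-pair `p_*` and `q_*`, `significant_pairs`, medians per age,
#'   `direction`. Attributes: `kind = "aging"`, `params`, and
#'   `pre_monotonic` (the OR-pooled ids before the monotonicity filter).
#' @export
select_aging_biomarkers <- function(table, q_cutoff = 0.1,
                                    ages = c(21, 27, 33)) {
  stopifnot(inherits(table, "metabolite_table"))
  if (length(ages) != 3) abort("Exactly three reference ages are required.")
  sub <- filter_table(table, group = "control", ages = ages)
  counts <- table(sub$samples$age_months)
  if (length(counts) < 3) abort("A reference timepoint is missing from the table.")
  if (any(counts < 3)) abort("Each age group needs at least 3 samples.")

  x <- sub$intensities
  cols_by_age <- lapply(ages, function(a) which(sub$samples$age_months == a))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  pair_names <- vapply(pairs, function(p) {
    paste0("t", ages[p[1]], "_t", ages[p[2]])
  }, character(1))

  pmat <- sapply(seq_along(pairs), function(k) {
    i <- cols_by_age[[pairs[[k]][1]]]
    j <- cols_by_age[[pairs[[k]][2]]]
    vapply(seq_len(nrow(x)), function(f) mw_p(x[f, i], x[f, j]), numeric(1))
  })
  qmat <- apply(pmat, 2, function(p) bh_adjust(p, q_cutoff)$q_values)
  sig <- qmat <= q_cutoff
  colnames(pmat) <- paste0("p_", pair_names)
  colnames(qmat) <- paste0("q_", pair_names)

  med <- group_medians_by_age(table, "control", ages)
  increasing <- med[, 1] < med[, 2] & med[, 2] < med[, 3]
  decreasing <- med[, 1] > med[, 2] & med[, 2] > med[, 3]
  monotone <- increasing | decreasing

  selected_any <- rowSums(sig) > 0
  keep <- selected_any & monotone
  records <- bind_cols(
    sub$features,
    as_tibble(pmat), as_tibble(qmat),
    tibble(
      significant_pairs = apply(sig, 1, function(s) {
        paste(pair_names[s], collapse = ",")
      }),
      median_t1 = med[, 1], median_t2 = med[, 2], median_t3 = med[, 3],
      direction = ifelse(increasing, "increasing",
                         ifelse(decreasing, "decreasing", NA_character_))
    )
  )
  names(records)[names(records) %in% c("median_t1", "median_t2", "median_t3")] <-
    paste0("median_", colnames(med))
  new_biomarker_set(
    records[keep, ],
    kind = "aging",
    params = list(q_cutoff = q_cutoff, ages = ages,
                  n_tested = nrow(x),
                  pairs = pair_names)
  ) |>
    (\(bs) {
      attr(bs, "pre_monotonic") <- sub$features$feature_id[selected_any]
      bs
    })()
}

#' Select laying (reproduction) biomarkers
#'
#' Pools the control samples across timepoints, pairs each sample with the
#' hen's laying efficiency in its sampling month, screens every feature by
#' Spearman correlation between intensity and efficiency, and controls the
#' FDR over the full feature list by Benjamini-Hochberg.
#'
#' @param table A [metabolite_table()].
#' @param efficiency Monthly efficiency tibble
#'   (from [monthly_efficiency()]): `hen_id`, `month`, `efficiency`.
#' @param q_cutoff BH FDR cutoff (default 0.1).
#' @param group Group whose samples are screened (default `"control"`).
#' @return A `biomarker_set` tibble: `feature_id`, `chemical_group`,
#'   `rho`, `p_value`, `q_value`, `sign`.
#' @export
select_laying_biomarkers <- function(table, efficiency, q_cutoff = 0.1,
                                     group = "control") {
  stopifnot(inherits(table, "metabolite_table"))
  sub <- filter_table(table, group = group)
  eff <- sub$samples |>
    left_join(efficiency, by = c("hen_id", "sampling_month" = "month"))
  if (anyNA(eff$efficiency)) {
    missing <- eff$sample_id[is.na(eff$efficiency)]
    abort(paste0("No efficiency for sample(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  x <- sub$intensities
  res <- t(vapply(seq_len(nrow(x)), function(f) {
    spearman_rho_p(x[f, ], eff$efficiency)
  }, numeric(2)))
  adj <- bh_adjust(res[, "p"], q_cutoff)
  records <- bind_cols(
    sub$features,
    tibble(rho = res[, "rho"], p_value = res[, "p"],
           q_value = adj$q_values,
           sign = ifelse(res[, "rho"] >= 0, 1L, -1L))
  )
  new_biomarker_set(
    records[adj$rejected, ],
    kind = "laying",
    params = list(q_cutoff = q_cutoff, group = group,
                  n_tested = nrow(x), n_samples = ncol(x))
  )
}

#' Common aging-and-reproduction markers
#'
#' Intersects the aging and laying biomarker sets by feature id, then
#' keeps only features consistent with the molt slowing aging while
#' improving performance: (a) the efficiency correlation must oppose the
#' age direction (higher efficiency looks metabolically younger), and (b)
#' the molted group's median at the last timepoint must lie strictly
#' between the control medians at the first and last timepoints (molted
#' expression is younger than its age-matched control). Both conditions
#' are an operationalization of a qualitative consistency requirement and
#' can be toggled individually.
#'
#' @param aging,laying Biomarker sets from [select_aging_biomarkers()] and
#'   [select_laying_biomarkers()], computed on the same feature universe.
#' @param table The full [metabolite_table()] including molted samples
#'   (needed for condition (b); pass `NULL` to skip it).
#' @param require_sign_consistency Apply condition (a) (default TRUE).
#' @param require_molt_intermediate Apply condition (b) (default TRUE).
#' @return A `biomarker_set` of kind `"common"` with the aging direction,
#'   laying correlation, and the medians used by the filter.
#' @export
common_markers <- function(aging, laying, table = NULL,
                           require_sign_consistency = TRUE,
                           require_molt_intermediate = TRUE) {
  stopifnot(inherits(aging, "biomarker_set"), inherits(laying, "biomarker_set"))
  ids <- intersect(aging$feature_id, laying$feature_id)
  params <- list(
    require_sign_consistency = require_sign_consistency,
    require_molt_intermediate = require_molt_intermediate,
    n_intersection = length(ids)
  )
  if (length(ids) == 0) {
    return(new_biomarker_set(
      tibble(feature_id = character(), chemical_group = character(),
             direction = character(), rho = numeric()),
      kind = "common", params = params
    ))
  }
  rec <- tibble(feature_id = ids) |>
    left_join(aging |> as_tibble() |>
                select("feature_id", "chemical_group", "direction"),
              by = "feature_id") |>
    left_join(laying |> as_tibble() |> select("feature_id", "rho", "sign"),
              by = "feature_id")
  keep <- rep(TRUE, nrow(rec))
  if (require_sign_consistency) {
    age_sign <- ifelse(rec$direction == "increasing", 1L, -1L)
    keep <- keep & (rec$sign == -age_sign)
  }
  if (require_molt_intermediate) {
    if (is.null(table)) {
      abort("`table` with molted samples is required for the molt-intermediate condition.")
    }
    ages <- attr(aging, "params")$ages
    med_c <- group_medians_by_age(table, "control", ages)[rec$feature_id, , drop = FALSE]
    molted_ages <- sort(unique(table$samples$age_months[table$samples$group == "molted"]))
    last_age <- max(molted_ages)
    sub_m <- filter_table(table, group = "molted", ages = last_age)
    med_m <- apply(sub_m$intensities[rec$feature_id, , drop = FALSE], 1, median)
    lo <- pmin(med_c[, 1], med_c[, 3])
    hi <- pmax(med_c[, 1], med_c[, 3])
    keep <- keep & med_m > lo & med_m < hi
    rec$median_molted_last <- med_m
  }
  new_biomarker_set(rec[keep, ], kind = "common", params = params)
}

#' Serialize a biomarker set
#'
#' @param set A `biomarker_set`.
#' @param path Output path; `.json` writes records plus selection
#'   parameters, `.tsv` a flat table.
#' @return `path`, invisibly.
#' @export
write_biomarker_set <- function(set, path) {
  stopifnot(inherits(set, "biomarker_set"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(kind = attr(set, "kind"), params = attr(set, "params"),
           records = as_tibble(set)),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  } else {
    readr::write_tsv(as_tibble(set), path)
  }
  invisible(path)
}
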
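#' Construct a metabolite intensity table
#'
#' The container every statistic in the package consumes: a strictly
#' positive feature-by-sample intensity matrix together with per-feature
#' annotation (chemical group) and per-sample metadata (hen, treatment
#' group, age at sampling, calendar month of sampling).
#'
#' @param intensities Numeric matrix, features in rows, samples in columns.
#'   All entries must be positive (raw LC-MS-style intensities, arbitrary
#'   units); coefficient-of-variation statistics are meaningless on
#'   centered data, so z-scored input is rejected.
#' @param features Tibble with columns `feature_id` (unique) and
#'   `chemical_group`.
#' @param samples Tibble with columns `sample_id` (unique, matching the
#'   matrix columns), `hen_id`, `group` (`"control"` or `"molted"`),
#'   `age_months`, `sampling_month`.
#' @return A `metabolite_table`.
#' @export
metabolite_table <- function(intensities, features, samples) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    abort("`intensities` must be a numeric matrix (features x samples).")
  }
  features <- as_tibble(features)
  samples <- as_tibble(samples)
  if (!all(c("feature_id", "chemical_group") %in% names(features))) {
    abort("`features` needs columns `feature_id` and `chemical_group`.")
  }
  need <- c("sample_id", "hen_id", "group", "age_months", "sampling_month")
  if (!all(need %in% names(samples))) {
    abort(paste0("`samples` needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(features) != nrow(intensities) ||
      nrow(samples) != ncol(intensities)) {
    abort("Dimensions of `intensities` do not match `features`/`samples`.")
  }
  if (anyDuplicated(features$feature_id)) abort("`feature_id` must be unique.")
  if (anyDuplicated(samples$sample_id)) abort("`sample_id` must be unique.")
  if (anyNA(intensities) || any(intensities <= 0)) {
    abort("All intensities must be positive and non-missing.")
  }
  if (!all(samples$group %in% c("control", "molted"))) {
    abort("`group` must be 'control' or 'molted'.")
  }
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- samples$sample_id
  structure(
    list(intensities = intensities, features = features, samples = samples),
    class = "metabolite_table"
  )
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("<metabolite_table> ", nrow(x$intensities), " features x ",
      ncol(x$intensities), " samples\n", sep = "")
  tab <- table(x$samples$group, x$samples$age_months)
  print(tab)
  invisible(x)
}

#' @export
dim.metabolite_table <- function(x) dim(x$intensities)

#' Subset a metabolite table by features and/or samples
#'
#' @param table A `metabolite_table`.
#' @param features Character vector of feature ids (default: keep all).
#' @param samples Character vector of sample ids, or a logical/filter on the
#'   sample metadata via `group`/`ages`.
#' @param group Optional group to keep.
#' @param ages Optional ages (months) to keep.
#' @return A `metabolite_table`.
#' @export
filter_table <- function(table, features = NULL, samples = NULL,
                         group = NULL, ages = NULL) {
  stopifnot(inherits(table, "metabolite_table"))
  keep_s <- rep(TRUE, nrow(table$samples))
  if (!is.null(samples)) keep_s <- keep_s & table$samples$sample_id %in% samples
  if (!is.null(group)) keep_s <- keep_s & table$samples$group %in% group
  if (!is.null(ages)) keep_s <- keep_s & table$samples$age_months %in% ages
  keep_f <- if (is.null(features)) {
    rep(TRUE, nrow(table$features))
  } else {
    table$features$feature_id %in% features
  }
  if (!any(keep_s)) abort("No samples left after filtering.")
  if (!any(keep_f)) abort("No features left after filtering.")
  metabolite_table(
    table$intensities[keep_f, keep_s, drop = FALSE],
    table$features[keep_f, ],
    table$samples[keep_s, ]
  )
}

#' Long-format view of a metabolite table
#'
#' @param x A `metabolite_table`.
#' @param ... Unused.
#' @return A tibble with one row per (feature, sample) pair carrying the
#'   intensity and all metadata.
#' @export
tidy.metabolite_table <- function(x, ...) {
  long <- as_tibble(x$intensities, rownames = "feature_id") |>
    pivot_longer(-"feature_id", names_to = "sample_id",
                 values_to = "intensity")
  long |>
    left_join(x$features, by = "feature_id") |>
    left_join(x$samples, by = "sample_id")
}

#' @export
glance.metabolite_table <- function(x, ...) {
  tibble(
    n_features = nrow(x$intensities),
    n_samples = ncol(x$intensities),
    n_hens = length(unique(x$samples$hen_id)),
    n_groups = length(unique(x$samples$group)),
    n_ages = length(unique(x$samples$age_months))
  )
}

#' Write / read a metabolite table as a TSV pair
#'
#' The intensity TSV has features in rows: first column `feature_id`,
#' second `chemical_group`, then one column per sample. Sample metadata
#' travels in a companion TSV (`sample_id`, `hen_id`, `group`,
#' `age_months`, `sampling_month`).
#'
#' @param table A `metabolite_table`.
#' @param path Intensity TSV path.
#' @param samples_path Metadata TSV path (default: `path` with a
#'   `.samples.tsv` suffix).
#' @return `write_metabolite_table()` returns the paths invisibly;
#'   `read_metabolite_table()` returns a `metabolite_table`.
#' @export
write_metabolite_table <- function(table, path,
                                   samples_path = sub("\\.tsv$", ".samples.tsv", path)) {
  stopifnot(inherits(table, "metabolite_table"))
  wide <- bind_cols(table$features,
                    as_tibble(table$intensities, .name_repair = "minimal"))
  readr::write_tsv(wide, path)
  readr::write_tsv(table$samples, samples_path)
  invisible(c(path, samples_path))
}

#' @rdname write_metabolite_table
#' @export
read_metabolite_table <- function(path,
                                  samples_path = sub("\\.tsv$", ".samples.tsv", path)) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  features <- wide[, c("feature_id", "chemical_group")]
  mat <- as.matrix(wide[, setdiff(names(wide), c("feature_id", "chemical_group"))])
  metabolite_table(mat, features, samples)
}
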
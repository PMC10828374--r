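# Reproduction and survival phenotypes derived from daily laying logs.

#' Monthly laying efficiency per hen
#'
#' Efficiency is eggs laid divided by days, computed per calendar month.
#' Hens dying mid-month contribute only over the days they were alive
#' (log rows exist only while a hen is alive); set
#' `denominator = "calendar"` to divide by the full month length instead.
#'
#' @param laying Long laying log with columns `hen_id`, `day`, `egg` and,
#'   if `month` is absent, a `calendar` attribute (see [laying_calendar()]).
#' @param denominator `"alive"` (default) or `"calendar"`.
#' @return Tibble with `hen_id`, `group` (if present), `month`, `n_eggs`,
#'   `n_days`, `efficiency`.
#' @export
monthly_efficiency <- function(laying, denominator = c("alive", "calendar")) {
  denominator <- match.arg(denominator)
  if (!all(c("hen_id", "day", "egg") %in% names(laying))) {
    abort("`laying` needs columns hen_id, day, egg.")
  }
  calendar <- attr(laying, "calendar")
  if (!"month" %in% names(laying)) {
    if (is.null(calendar)) abort("Need a `month` column or a calendar attribute.")
    laying$month <- month_of_day(laying$day, calendar)
  }
  grp <- intersect(c("hen_id", "group", "month"), names(laying))
  out <- laying |>
    group_by(across(all_of(grp))) |>
    summarise(n_eggs = sum(.data$egg), n_days = n(), .groups = "drop")
  if (denominator == "calendar") {
    if (is.null(calendar)) abort("Calendar attribute required for denominator = 'calendar'.")
    out$n_days <- calendar$n_days[match(out$month, calendar$month)]
  }
  out |>
    mutate(efficiency = .data$n_eggs / .data$n_days) |>
    arrange(.data$hen_id, .data$month)
}

#' Laying efficiency of one hen in one month
#'
#' @inheritParams monthly_efficiency
#' @param hen_id Hen identifier.
#' @param month Age-month.
#' @return One-row tibble (`hen_id`, `month`, `n_eggs`, `n_days`,
#'   `efficiency`).
#' @examples
#' log <- tibble::tibble(hen_id = "H1", day = 1:30, month = 21L,
#'                       egg = rep(c(1L, 0L), 15))
#' laying_efficiency(log, "H1", 21)
#' @export
laying_efficiency <- function(laying, hen_id, month) {
  out <- monthly_efficiency(laying) |>
    filter(.data$hen_id == !!hen_id, .data$month == !!month)
  if (nrow(out) == 0) {
    abort(paste0("Hen ", hen_id, " has no living days in month ", month, "."))
  }
  out
}

#' Cohort median laying efficiency for one month
#'
#' Computed in the stated order: the median of per-hen egg counts first,
#' then division by the number of days in the month. Dead hens are counted
#' with zero eggs by default so the statistic tracks the whole enrolled
#' population rather than its survivors.
#'
#' @inheritParams monthly_efficiency
#' @param hen_ids Hens composing the cohort.
#' @param month Age-month.
#' @param include_dead Count hens without living days this month as zero
#'   producers (default TRUE).
#' @return Median efficiency (scalar fraction).
#' @export
cohort_median_efficiency <- function(laying, hen_ids, month,
                                     include_dead = TRUE) {
  if (length(hen_ids) == 0) abort("Empty cohort.")
  calendar <- attr(laying, "calendar")
  eff <- monthly_efficiency(laying) |>
    filter(.data$month == !!month, .data$hen_id %in% hen_ids)
  if (nrow(eff) == 0) abort("No living hens in that month.")
  counts <- eff$n_eggs[match(hen_ids, eff$hen_id)]
  if (include_dead) counts[is.na(counts)] <- 0L else counts <- counts[!is.na(counts)]
  n_days <- if (!is.null(calendar) && month %in% calendar$month) {
    calendar$n_days[calendar$month == month]
  } else {
    max(eff$n_days)
  }
  median(counts) / n_days
}

#' Detect sterility onset for one hen
#'
#' A hen is sterile after three consecutive weeks -- 21 consecutive
#' calendar days while alive -- without laying. Returns the first day of
#' the earliest such window, or `NA` if none exists.
#'
#' @inheritParams monthly_efficiency
#' @param hen_id Hen identifier.
#' @param window_days Run length defining sterility (default 21).
#' @return Integer day (or `NA_integer_`).
#' @export
detect_sterility <- function(laying, hen_id, window_days = 21L) {
  rows <- laying |> filter(.data$hen_id == !!hen_id) |> arrange(.data$day)
  if (nrow(rows) == 0) abort(paste0("Unknown hen ", hen_id, "."))
  eggs <- rows$egg
  if (length(eggs) < window_days) return(NA_integer_)
  run <- 0L
  for (i in seq_along(eggs)) {
    run <- if (eggs[i] == 0L) run + 1L else 0L
    if (run == window_days) return(rows$day[i - window_days + 1L])
  }
  NA_integer_
}

#' Survival and sterility records for a cohort
#'
#' @inheritParams monthly_efficiency
#' @param window_days Sterility run length (default 21).
#' @return Tibble with `hen_id`, `group`, `died`, `death_day`,
#'   `sterile`, `sterility_onset_day`.
#' @export
survival_records <- function(laying, window_days = 21L) {
  deaths <- attr(laying, "deaths")
  hens <- distinct(laying, .data$hen_id, .data$group)
  hens$death_day <- if (!is.null(deaths)) {
    deaths$death_day[match(hens$hen_id, deaths$hen_id)]
  } else {
    NA_integer_
  }
  hens$died <- !is.na(hens$death_day)
  hens$sterility_onset_day <- vapply(
    hens$hen_id, function(h) detect_sterility(laying, h, window_days),
    integer(1)
  )
  hens$sterile <- !is.na(hens$sterility_onset_day)
  hens[, c("hen_id", "group", "died", "death_day", "sterile",
           "sterility_onset_day")]
}

#' Cohort mortality as a percentage
#'
#' @param survival Tibble with a logical `died` column (one row per
#'   enrolled hen), e.g. from [survival_records()].
#' @return One-row tibble: `n`, `deaths`, `fraction`, and `percent`
#'   (nearest integer, the convention mortality figures are reported in).
#' @examples
#' # a 32-hen cohort with 11 deaths
#' mortality_fraction(tibble::tibble(died = rep(c(TRUE, FALSE), c(11, 21))))
#' @export
mortality_fraction <- function(survival) {
  if (nrow(survival) == 0) abort("Empty cohort.")
  deaths <- sum(survival$died)
  tibble(n = nrow(survival), deaths = deaths,
         fraction = deaths / nrow(survival),
         percent = round(100 * deaths / nrow(survival)))
}

#' Sterility-by-mortality contingency table
#'
#' Cross-tabulates sterility against death for a cohort, in the layout
#' consumed by [fisher_exact_2x2()]: rows sterile/non-sterile, columns
#' died/survived.
#'
#' @param survival Tibble with logical `sterile` and `died` columns.
#' @return 2x2 integer matrix.
#' @export
sterility_mortality_table <- function(survival) {
  m <- matrix(
    c(sum(survival$sterile & survival$died),
      sum(survival$sterile & !survival$died),
      sum(!survival$sterile & survival$died),
      sum(!survival$sterile & !survival$died)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("sterile", "not_sterile"), c("died", "survived"))
  )
  storage.mode(m) <- "integer"
  m
}

#' Read a long-form laying log CSV
#'
#' @param path CSV with columns `hen_id`, `day`, `egg`; a companion
#'   `.hens.csv` (hen_id, group, death_day) is read if present.
#' @param calendar Calendar mapping days to months
#'   (default [laying_calendar()]).
#' @return Laying log tibble with `month` attached.
#' @export
read_laying_log <- function(path, calendar = laying_calendar()) {
  log <- readr::read_csv(path, show_col_types = FALSE)
  hens_path <- sub("\\.csv$", ".hens.csv", path)
  if (file.exists(hens_path)) {
    hens <- readr::read_csv(hens_path, show_col_types = FALSE)
    log <- left_join(log, hens[, c("hen_id", "group")], by = "hen_id")
    attr(log, "deaths") <- hens |> filter(!is.na(.data$death_day))
  }
  log$month <- month_of_day(log$day, calendar)
  attr(log, "calendar") <- calendar
  log
}

#' Write monthly efficiency records as TSV
#'
#' @param efficiency Output of [monthly_efficiency()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_efficiency <- function(efficiency, path) {
  readr::write_tsv(efficiency, path)
  invisible(path)
}
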
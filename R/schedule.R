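## Fertility schedules: tibbles with columns `age` (consecutive integer
## years) and `asfr` (births per woman per year).  All user-facing functions
## take such a data frame first and return tibbles.

validate_schedule <- function(schedule, ages = 15:49, allow_extra_ages = FALSE,
                              arg = "schedule") {
  if (!is.data.frame(schedule)) abort(paste0("`", arg, "` must be a data frame"))
  if (!all(c("age", "asfr") %in% names(schedule))) {
    abort(paste0("`", arg, "` must have columns `age` and `asfr`"))
  }
  age <- schedule$age
  rate <- schedule$asfr
  if (!is.numeric(age) || !is.numeric(rate)) {
    abort("`age` and `asfr` must be numeric")
  }
  if (anyNA(age) || anyNA(rate) || any(!is.finite(rate))) {
    abort("`age` and `asfr` must be finite and non-missing")
  }
  if (any(age != round(age))) abort("`age` must be whole years")
  if (nrow(schedule) < 1L) abort(paste0("`", arg, "` is empty"))
  dup <- age[duplicated(age)]
  if (length(dup)) {
    abort(paste0("duplicate age(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (is.unsorted(age, strictly = TRUE)) abort("`age` must be strictly increasing")
  if (!all(diff(age) == 1)) abort("`age` must be consecutive integer years")
  if (any(rate < 0)) abort("`asfr` must be >= 0")
  if (!allow_extra_ages && (min(age) < min(ages) || max(age) > max(ages))) {
    abort(paste0(
      "ages outside ", min(ages), "-", max(ages),
      "; pass allow_extra_ages = TRUE to keep them"
    ))
  }
  tibble::as_tibble(schedule[c("age", "asfr")])
}

#' Construct a fertility schedule
#'
#' @param age Integer ages in years (consecutive; 15--49 for the standard
#'   reproductive span).
#' @param asfr Fertility rate per woman per year at each age.
#' @param allow_extra_ages Keep ages outside 15--49 instead of erroring.
#' @return A tibble with columns `age`, `asfr`.
#' @examples
#' fertility_schedule(15:49, dnorm(15:49, 23, 5))
#' @export
fertility_schedule <- function(age, asfr, allow_extra_ages = FALSE) {
  validate_schedule(tibble::tibble(age = age, asfr = asfr),
    allow_extra_ages = allow_extra_ages
  )
}

#' Summarise a fertility schedule
#'
#' Computes the observed total fertility rate (sum of single-year rates),
#' the peak rate and its age (youngest age on ties), and the mean late-age
#' (45--49) rate.
#'
#' @param schedule Data frame with columns `age`, `asfr`.
#' @param region Optional region label carried into the output.
#' @return One-row tibble with columns `region`, `tfr`, `peak_rate`,
#'   `peak_age`, `late_age_rate`.
#' @export
summarize_schedule <- function(schedule, region = NA_character_) {
  schedule <- validate_schedule(schedule, allow_extra_ages = TRUE)
  i <- which.max(schedule$asfr)
  late <- dplyr::filter(schedule, .data$age >= 45, .data$age <= 49)
  tibble::tibble(
    region = region,
    tfr = sum(schedule$asfr),
    peak_rate = schedule$asfr[i],
    peak_age = as.integer(schedule$age[i]),
    late_age_rate = if (nrow(late)) mean(late$asfr) else NA_real_
  )
}

#' Read / write a fertility schedule CSV
#'
#' The file format is a two-column CSV with header `age,asfr`, one row per
#' single year of age.  Reading validates the schedule: duplicate or
#' non-consecutive ages, missing columns and non-numeric rates are errors
#' that name the offending age or row.
#'
#' @param path CSV file path.
#' @param allow_extra_ages Permit ages outside 15--49.
#' @return `read_schedule()`: a validated schedule tibble.
#' @export
read_schedule <- function(path, allow_extra_ages = FALSE) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("age", "asfr") %in% names(raw))) {
    abort(paste0(
      "schedule file must have columns `age` and `asfr`; found: ",
      paste(names(raw), collapse = ", ")
    ))
  }
  age <- suppressWarnings(as.numeric(raw$age))
  rate <- suppressWarnings(as.numeric(raw$asfr))
  bad <- which(is.na(rate) | is.na(age))
  if (length(bad)) {
    abort(paste0(
      "non-numeric or missing value in row(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  dup <- age[duplicated(age)]
  if (length(dup)) {
    abort(paste0("duplicate age(s): ", paste(unique(dup), collapse = ", ")))
  }
  validate_schedule(tibble::tibble(age = age, asfr = rate),
    allow_extra_ages = allow_extra_ages
  )
}

#' @rdname read_schedule
#' @param schedule Data frame with columns `age`, `asfr`.
#' @return `write_schedule()`: `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  schedule <- validate_schedule(schedule, allow_extra_ages = TRUE)
  readr::write_csv(schedule, path, progress = FALSE)
  invisible(path)
}

#' Plot a fertility schedule
#'
#' @param schedule Data frame with columns `age`, `asfr`.
#' @param smoothed Optional second schedule (e.g. from [smooth_schedule()])
#'   drawn as a line over the observed points.
#' @return A ggplot object.
#' @export
plot_schedule <- function(schedule, smoothed = NULL) {
  schedule <- validate_schedule(schedule, allow_extra_ages = TRUE)
  p <- ggplot2::ggplot(schedule, ggplot2::aes(x = .data$age, y = .data$asfr)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::labs(
      x = "Age (years)", y = "ASFR (births per woman per year)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(smoothed)) {
    smoothed <- validate_schedule(smoothed, allow_extra_ages = TRUE)
    p <- p + ggplot2::geom_line(data = smoothed, colour = "steelblue")
  }
  p
}
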
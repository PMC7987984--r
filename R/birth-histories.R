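## Single-year ASFR from retrospective birth histories.
##
## Birth histories use DHS conventions: dates are century-month codes
## (CMC = 12 * (year - 1900) + month) and age is completed years
## (months of age %/% 12).  One row per (woman, child); childless women
## appear once with `child_dob_cmc = NA`.

validate_histories <- function(histories) {
  need <- c("woman_id", "woman_dob_cmc", "interview_cmc")
  if (!is.data.frame(histories) || !all(need %in% names(histories))) {
    abort(paste0(
      "`histories` must be a data frame with columns ",
      paste(c(need, "child_dob_cmc"), collapse = ", ")
    ))
  }
  if (nrow(histories) == 0L) abort("`histories` is empty")
  if (!"child_dob_cmc" %in% names(histories)) {
    histories$child_dob_cmc <- NA_real_
  }
  if (!"weight" %in% names(histories)) histories$weight <- 1
  histories$weight[is.na(histories$weight)] <- 1
  if (any(histories$weight < 0)) abort("weights must be nonnegative")

  women <- dplyr::distinct(
    histories, .data$woman_id, .data$woman_dob_cmc,
    .data$interview_cmc, .data$weight
  )
  if (anyDuplicated(women$woman_id)) {
    abort("inconsistent woman-level fields: a woman_id appears with differing dob, interview or weight")
  }
  if (any(women$interview_cmc <= women$woman_dob_cmc)) {
    bad <- women$woman_id[women$interview_cmc <= women$woman_dob_cmc]
    abort(paste0(
      "interview date not after woman's own birth for woman_id: ",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  kids <- histories[!is.na(histories$child_dob_cmc), ]
  if (nrow(kids)) {
    early <- kids$child_dob_cmc < kids$woman_dob_cmc
    if (any(early)) {
      abort(paste0(
        "child born before mother's own birth for woman_id: ",
        paste(head(unique(kids$woman_id[early]), 5L), collapse = ", ")
      ))
    }
    late <- kids$child_dob_cmc > kids$interview_cmc
    if (any(late)) {
      abort(paste0(
        "child born after interview for woman_id: ",
        paste(head(unique(kids$woman_id[late]), 5L), collapse = ", ")
      ))
    }
  }
  list(women = women, births = kids)
}

#' Compute single-year ASFR from birth histories
#'
#' Estimates the age-specific fertility rate for completed ages 15--49 over
#' a retrospective window ending the month before the interview (the usual
#' "3 years preceding the survey" convention; the interview month itself is
#' excluded).  For each age x,
#' \deqn{ASFR(x) = \frac{\sum_i w_i\, b_i(x)}{\sum_i w_i\, e_i(x)}}
#' where \eqn{b_i(x)} counts woman i's births in the window while she was
#' aged x in completed years, and \eqn{e_i(x)} is her exposure in
#' woman-years, accumulated month by month: each calendar month in
#' `[interview - window_months, interview - 1]` during which her completed
#' age is x contributes 1/12.
#'
#' Ages with zero exposure get rate 0; they are reported via a warning and
#' the `zero_exposure_ages` attribute of the result.
#'
#' @param histories Data frame with columns `woman_id`, `woman_dob_cmc`,
#'   `interview_cmc`, `child_dob_cmc` (NA for childless women) and optional
#'   `weight` (default 1); one row per woman-child pair.
#' @param window_months Length of the retrospective window (default 36,
#'   i.e. the 3 years before the survey).
#' @param ages Completed ages to report (default 15--49).
#' @return Schedule tibble (`age`, `asfr`) with attributes
#'   `zero_exposure_ages` (integer vector) and `exposure_years` (named
#'   vector of weighted woman-years by age).
#' @examples
#' h <- tibble::tibble(
#'   woman_id = c(1, 1, 2), woman_dob_cmc = c(1000, 1000, 1012),
#'   interview_cmc = 1240, child_dob_cmc = c(1220, NA, NA)
#' )
#' compute_asfr(h)
#' @export
compute_asfr <- function(histories, window_months = 36, ages = 15:49) {
  if (!is.numeric(window_months) || window_months < 1) {
    abort("`window_months` must be >= 1")
  }
  parts <- validate_histories(histories)
  women <- parts$women
  births <- parts$births

  win_lo <- women$interview_cmc - window_months # first month in window
  win_hi <- women$interview_cmc - 1 # last month in window

  # months woman i spends at completed age x inside the window:
  # overlap of her age-month interval [12x, 12x+11] (shifted by dob)
  # with [win_lo, win_hi]
  exposure_months <- vapply(ages, function(x) {
    age_lo <- women$woman_dob_cmc + 12 * x
    age_hi <- age_lo + 11
    ov <- pmin(win_hi, age_hi) - pmax(win_lo, age_lo) + 1
    sum(women$weight * pmax(ov, 0))
  }, numeric(1))

  if (nrow(births)) {
    in_win <- births$child_dob_cmc >= (births$interview_cmc - window_months) &
      births$child_dob_cmc <= (births$interview_cmc - 1)
    births <- births[in_win, ]
  }
  birth_counts <- vapply(ages, function(x) {
    if (!nrow(births)) return(0)
    age_at_birth <- (births$child_dob_cmc - births$woman_dob_cmc) %/% 12
    sum(births$weight[age_at_birth == x])
  }, numeric(1))

  exposure_years <- exposure_months / 12
  rate <- ifelse(exposure_years > 0, birth_counts / exposure_years, 0)
  zero <- ages[exposure_years == 0]
  if (length(zero)) {
    warn(paste0(
      "zero exposure at age(s) ", paste(zero, collapse = ", "),
      "; rate set to 0"
    ))
  }
  out <- tibble::tibble(age = as.integer(ages), asfr = rate)
  attr(out, "zero_exposure_ages") <- as.integer(zero)
  attr(out, "exposure_years") <- setNames(exposure_years, ages)
  out
}

#' Read / write birth-history CSV files
#'
#' One row per (woman, child); childless women have an empty
#' `child_dob_cmc` field.  Columns: `woman_id`, `woman_dob_cmc`,
#' `interview_cmc`, `child_dob_cmc`, `weight`.
#'
#' @param path CSV file path.
#' @return `read_birth_histories()`: a tibble of histories.
#' @export
read_birth_histories <- function(path) {
  out <- readr::read_csv(path,
    col_types = readr::cols(
      woman_id = readr::col_character(),
      woman_dob_cmc = readr::col_double(),
      interview_cmc = readr::col_double(),
      child_dob_cmc = readr::col_double(),
      weight = readr::col_double()
    ),
    progress = FALSE
  )
  validate_histories(out)
  out
}

#' @rdname read_birth_histories
#' @param histories Data frame of birth histories.
#' @return `write_birth_histories()`: `path`, invisibly.
#' @export
write_birth_histories <- function(histories, path) {
  validate_histories(histories)
  readr::write_csv(histories, path, progress = FALSE)
  invisible(path)
}
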
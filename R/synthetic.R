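## Seeded generators: noisy schedules from a model family, and DHS-style
## birth-history microdata whose monthly hazard follows a chosen schedule.
##
## The microdata generator emulates an NFHS/DHS-like retrospective survey:
## interview ages uniform over completed ages 15-49 at month resolution,
## and in each month of life from exact age 15 a birth with probability
## f(completed age)/12, independently month to month.  No 9-month
## refractory period or parity structure is imposed -- at human fertility
## rates (< 0.25/yr) this barely affects single-year ASFR estimation and
## keeps the events/exposure oracle exact.

#' Generate a (noisy) schedule from a model family
#'
#' @inheritParams fertility_rate
#' @param noise `"none"` for the exact model curve, `"gaussian"` for
#'   additive seeded N(0, sd^2) noise truncated at 0, or `"binomial"` for
#'   births ~ Binomial(women_per_age, f(x)) divided by `women_per_age`.
#' @param sd Gaussian noise standard deviation (rate units).
#' @param women_per_age Binomial denominator per age.
#' @param seed Integer seed (used for the noisy variants).
#' @param ages Integer ages of the schedule.
#' @return Schedule tibble (`age`, `asfr`).
#' @examples
#' generate_schedule("hadwiger", c(a = 1.21, b = 3.69, c = 24.2),
#'   noise = "gaussian", sd = 0.002, seed = 1
#' )
#' @export
generate_schedule <- function(family, params,
                              noise = c("none", "gaussian", "binomial"),
                              sd = 0.002, women_per_age = 1000, seed = NULL,
                              ages = 15:49,
                              phi_arg = c("literal", "centered")) {
  noise <- match.arg(noise)
  truth <- fertility_rate(family, ages, params, phi_arg = match.arg(phi_arg))
  rates <- switch(noise,
    none = truth,
    gaussian = {
      if (sd <= 0) abort("`sd` must be > 0")
      if (!is.null(seed)) set.seed(seed)
      pmax(truth + rnorm(length(truth), 0, sd), 0)
    },
    binomial = {
      if (women_per_age < 1) abort("`women_per_age` must be >= 1")
      if (any(truth > 1)) abort("truth rate > 1: binomial noise undefined")
      if (!is.null(seed)) set.seed(seed)
      rbinom(length(truth), women_per_age, truth) / women_per_age
    }
  )
  tibble::tibble(age = as.integer(ages), asfr = rates)
}

#' Simulate DHS-style birth histories from a fertility schedule
#'
#' Draws `n_women` women whose completed age at interview is uniform over
#' 15--49 at month resolution, then simulates a birth in each month of
#' life from exact age 15 up to the month before the interview with
#' probability f(completed age)/12.  Dates are returned as century-month
#' codes (CMC = 12(year - 1900) + month); the interview month is fixed per
#' run.
#'
#' @param schedule Data frame with columns `age`, `asfr` -- the true
#'   hazard schedule (ages 15--49); monthly hazards `asfr/12` must be < 1.
#' @param n_women Number of women to simulate.
#' @param seed Integer seed.
#' @param interview_cmc Interview month for all women (default CMC 1396,
#'   i.e. April 2016, an NFHS-4-era fieldwork month).
#' @return Birth-history tibble (`woman_id`, `woman_dob_cmc`,
#'   `interview_cmc`, `child_dob_cmc`, `weight`), one row per woman-child
#'   and one NA-child row per childless woman; ready for [compute_asfr()].
#' @examples
#' sched <- generate_schedule("pk",
#'   c(b = 0.19, mu = 22, sigma1 = 3, sigma2 = 9),
#'   noise = "none"
#' )
#' h <- simulate_birth_histories(sched, n_women = 500, seed = 1)
#' @export
simulate_birth_histories <- function(schedule, n_women, seed = NULL,
                                     interview_cmc = 1396) {
  schedule <- validate_schedule(schedule, allow_extra_ages = TRUE)
  if (any(schedule$asfr / 12 >= 1)) {
    abort("monthly hazard asfr/12 must be < 1 at all ages")
  }
  if (n_women < 1) abort("`n_women` must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  hazard <- setNames(schedule$asfr / 12, schedule$age)
  ages <- schedule$age

  # completed age at interview, month resolution: 180..599 months for 15-49
  age_months <- sample.int(
    12 * (max(ages) - min(ages) + 1), n_women,
    replace = TRUE
  ) - 1 + 12 * min(ages)
  dob <- interview_cmc - age_months

  # months woman i lives at completed age x before the interview:
  # overlap of [12x, 12x+11] with [12*min(age), age_months_i - 1]
  n_months <- outer(age_months, 12 * ages, function(am, lo) {
    pmax(pmin(am - 1, lo + 11) - lo + 1, 0)
  })
  counts <- matrix(
    rbinom(length(n_months), as.vector(n_months),
      rep(hazard, each = n_women)
    ),
    nrow = n_women
  )

  idx <- which(counts > 0, arr.ind = TRUE)
  birth_rows <- if (nrow(idx)) {
    months_at_age <- n_months[idx] # months lived in that age block
    block_lo <- 12 * ages[idx[, 2]] # age-month offset of block start
    offs <- mapply(function(m, b) sample.int(m, b), months_at_age,
      counts[idx],
      SIMPLIFY = FALSE
    )
    woman <- rep(idx[, 1], counts[idx])
    tibble::tibble(
      woman_id = as.character(woman),
      woman_dob_cmc = dob[woman],
      interview_cmc = interview_cmc,
      child_dob_cmc = dob[woman] + rep(block_lo, counts[idx]) +
        unlist(offs) - 1,
      weight = 1
    )
  } else {
    tibble::tibble(
      woman_id = character(), woman_dob_cmc = numeric(),
      interview_cmc = numeric(), child_dob_cmc = numeric(),
      weight = numeric()
    )
  }

  childless <- setdiff(seq_len(n_women), unique(as.integer(birth_rows$woman_id)))
  all_rows <- dplyr::bind_rows(
    birth_rows,
    tibble::tibble(
      woman_id = as.character(childless),
      woman_dob_cmc = dob[childless],
      interview_cmc = interview_cmc,
      child_dob_cmc = NA_real_,
      weight = 1
    )
  )
  dplyr::arrange(all_rows, as.integer(.data$woman_id), .data$child_dob_cmc)
}
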
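## Goodness-of-fit statistics and AICc-based model comparison.

#' AIC and small-sample corrected AIC from an SSE
#'
#' Uses the least-squares forms
#' \deqn{AIC = 2k + n \ln\left(\frac{SSE}{n - k}\right)}
#' \deqn{AICc = AIC + \frac{2k(k+1)}{n - k - 1}}
#' Note the residual-degrees-of-freedom divisor `n - k` inside the log
#' (not the more common `n`); the published NFHS-4 AICc values reproduce
#' only under this form, so it is used throughout.
#'
#' @param sse Minimized sum of squared errors (> 0; an exact-interpolation
#'   fit with `sse = 0` returns `-Inf` for both with a warning).
#' @param n Number of observations (ages); must exceed `k + 1`.
#' @param k Number of free parameters.
#' @return A list with elements `aic` and `aicc`.
#' @examples
#' aic_aicc(sse = 0.0684, n = 35, k = 3)
#' @export
aic_aicc <- function(sse, n, k) {
  if (!is.numeric(sse) || length(sse) != 1L || sse < 0) {
    abort("`sse` must be a nonnegative scalar")
  }
  if (n <= k + 1) abort("`n` must exceed k + 1")
  if (sse == 0) {
    warn("sse = 0: AIC/AICc are -Inf (exact interpolation)")
    return(list(aic = -Inf, aicc = -Inf))
  }
  aic <- 2 * k + n * log(sse / (n - k))
  list(aic = aic, aicc = aic + 2 * k * (k + 1) / (n - k - 1))
}

#' Coefficient of determination of a model on a schedule
#'
#' Defined as \eqn{1 - SSE / \sum_x (f(x) - \bar f)^2} about the mean
#' observed rate.  (A convention: no single formula is universal for
#' nonlinear fits.)
#'
#' @param schedule Data frame with columns `age`, `asfr` (nonconstant).
#' @inheritParams fertility_rate
#' @return Scalar R-squared (at most 1; can be negative for a fit worse
#'   than the mean).
#' @export
r_squared <- function(schedule, family, params,
                      phi_arg = c("literal", "centered")) {
  schedule <- validate_schedule(schedule, allow_extra_ages = TRUE)
  if (length(unique(schedule$asfr)) == 1L) {
    abort("R-squared is undefined for constant observed rates")
  }
  sse <- model_sse(schedule, family, params, phi_arg = match.arg(phi_arg))
  tss <- sum((schedule$asfr - mean(schedule$asfr))^2)
  1 - sse / tss
}

#' Compare fitted models by AICc
#'
#' Ranks a set of fits of the same schedule by AICc (ascending).  When two
#' fits differ by less than 0.01 AICc units the one with fewer parameters
#' is preferred, encoding the usual parsimony rule for effectively tied
#' fits.  The result is independent of the input order.
#'
#' @param fits List of `fert_fit` objects fitted to the same schedule.
#' @param region Optional region label.
#' @return A tibble with one row per fit -- columns `region`, `family`,
#'   `k`, `sse`, `aic`, `aicc`, `r_squared`, `best` -- sorted by AICc.
#' @export
compare_models <- function(fits, region = NA_character_) {
  if (!is.list(fits) || length(fits) < 2L ||
      !all(vapply(fits, inherits, logical(1), "fert_fit"))) {
    abort("`fits` must be a list of >= 2 fert_fit objects")
  }
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L) {
    abort("fits were computed on different numbers of observations")
  }
  tab <- purrr::map_dfr(fits, glance)
  if (anyDuplicated(tab$family)) abort("duplicate family in `fits`")
  tab <- dplyr::arrange(tab, .data$aicc, .data$k, .data$family)
  # parsimony tie-break: among fits within 0.01 of the minimum AICc the
  # smallest k wins
  tied <- which(tab$aicc - min(tab$aicc) < 0.01)
  best_i <- tied[order(tab$k[tied], tab$family[tied])][1]
  tab |>
    dplyr::mutate(
      region = region, best = dplyr::row_number() == best_i,
      .before = 1
    ) |>
    dplyr::select(
      "region", "family", "k", "sse", "aic", "aicc", "r_squared", "best"
    )
}

#' Pearson correlation between a fitted parameter and a summary measure
#'
#' Used to interpret model parameters across regions, e.g. the Hadwiger
#' scale parameter against observed TFR.
#'
#' @param data Data frame with one row per region.
#' @param x,y Column names (tidy-select) of the two numeric variables.
#' @return One-row tibble with columns `x`, `y`, `n`, `r`.
#' @examples
#' d <- tibble::tibble(a = c(1.2, 0.9, 1.5), tfr = c(2.2, 1.6, 2.8))
#' correlate_params(d, a, tfr)
#' @export
correlate_params <- function(data, x, y) {
  xq <- rlang::enquo(x)
  yq <- rlang::enquo(y)
  xv <- dplyr::pull(data, !!xq)
  yv <- dplyr::pull(data, !!yq)
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3L) abort("need at least 3 complete pairs")
  if (length(unique(xv)) == 1L || length(unique(yv)) == 1L) {
    abort("correlation is undefined for a constant vector")
  }
  tibble::tibble(
    x = rlang::as_name(xq), y = rlang::as_name(yq),
    n = length(xv), r = cor(xv, yv)
  )
}
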
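## Local polynomial (loess-style) smoothing of a raw single-year schedule.
##
## At each age x0 the ceil(span * n) nearest ages (rank distance) are fit
## with a weighted polynomial, tricube weights w = (1 - (d/dmax)^3)^3 on
## distance scaled by the window radius dmax, and the fit is evaluated at
## x0.  This is the classical definition; package-specific interpolation
## shortcuts (cell/surface approximations) are deliberately not emulated.

#' Smooth a fertility schedule by local polynomial regression
#'
#' Loess-style smoothing of the raw single-year ASFR.  The default 20%
#' span (`span = 0.2`) keeps enough local structure to preserve the peak
#' while removing single-age fluctuation and digit preference; with n = 35
#' ages this is a 7-point moving local quadratic.
#'
#' @param schedule Data frame with columns `age`, `asfr`.
#' @param span Fraction of points in each local window, in (0, 1].
#' @param degree Local polynomial degree (0, 1 or 2).
#' @param allow_extra_ages Permit ages outside 15--49.
#' @return Schedule tibble with the same ages and smoothed rates.
#' @examples
#' sched <- fertility_schedule(15:49, dnorm(15:49, 23, 5) + 0.002)
#' smooth_schedule(sched, span = 0.2)
#' @export
smooth_schedule <- function(schedule, span = 0.2, degree = 2,
                            allow_extra_ages = FALSE) {
  schedule <- validate_schedule(schedule, allow_extra_ages = allow_extra_ages)
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    abort("`span` must be in (0, 1]")
  }
  if (!degree %in% 0:2) abort("`degree` must be 0, 1 or 2")
  x <- as.numeric(schedule$age)
  y <- schedule$asfr
  n <- length(x)
  q <- ceiling(span * n)
  if (q < degree + 1) {
    abort(paste0(
      "window of ", q, " point(s) cannot support degree ", degree,
      "; increase `span`"
    ))
  }
  fitted <- vapply(seq_len(n), function(i) {
    local_poly_fit(x, y, x0 = x[i], q = q, degree = degree)
  }, numeric(1))
  tibble::tibble(age = schedule$age, asfr = fitted)
}

# weighted polynomial fit at x0 over the q nearest neighbours
local_poly_fit <- function(x, y, x0, q, degree) {
  d <- abs(x - x0)
  dmax <- sort(d, partial = q)[q]
  keep <- which(d <= dmax)
  w <- (1 - (d[keep] / dmax)^3)^3
  pos <- w > 0
  keep <- keep[pos]
  w <- w[pos]
  xc <- x[keep] - x0 # center so the intercept is the fitted value
  X <- outer(xc, 0:degree, `^`)
  fit <- lm.wfit(X, y[keep], w)
  fit$coefficients[1]
}
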
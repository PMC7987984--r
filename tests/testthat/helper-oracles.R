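# Independent oracles and small fixtures used across the suite.

# India-level reference parameter vectors (published NFHS-4 estimates)
india_mg <- c(alpha = 4.3619, beta = 4.0885, gamma = 13.1039, m = 16.4648)
india_mpk <- c(a = 0.00307, b = 0.1902, mu = 21.3593, sigma1 = 3.4055, sigma2 = 8.9152)
india_msn <- c(theta = 0.1924, lambda = 21.3305, s1 = 2.4382, s2 = 6.4817, delta = 2.8960)
india_mgp <- c(p = 165.321, q = 2.4261, r = 13.3747, s = 0.00392)
india_hadwiger <- c(a = 1.2141, b = 3.6940, c = 24.2482)

# a realistic unimodal right-skewed schedule (noiseless model curve)
india_like_schedule <- function() {
  generate_schedule("modified_gompertz", india_mg, noise = "none")
}

# brute-force local-regression oracle: for each x0, tricube-weighted
# polynomial fit over the ceil(span*n) nearest points, solved by normal
# equations -- an independent path from the package's QR-based lm.wfit
oracle_loess <- function(x, y, span, degree) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(x, function(x0) {
    d <- abs(x - x0)
    dmax <- sort(d)[q]
    keep <- which(d <= dmax & (1 - (d / dmax)^3)^3 > 0)
    w <- (1 - (d[keep] / dmax)^3)^3
    X <- outer(x[keep] - x0, 0:degree, `^`)
    beta <- solve(t(X) %*% diag(w) %*% X, t(X) %*% (w * y[keep]))
    beta[1]
  }, numeric(1))
}

# hand-counted two-woman worked example: woman A is exactly 240 months old
# at interview with one birth at completed age 18, woman B is 228 months
# old with none; over a 36-month window ASFR(18) = 1 / (1 + 1) = 0.5
two_woman_histories <- function(interview = 1396) {
  tibble::tibble(
    woman_id = c("A", "B"),
    woman_dob_cmc = c(interview - 240, interview - 228),
    interview_cmc = interview,
    child_dob_cmc = c(interview - 240 + 12 * 18 + 4, NA),
    weight = 1
  )
}
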
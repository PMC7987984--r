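test_that("Hadwiger curve matches its closed form", {
  p <- india_hadwiger
  # at x = c the power and exponential terms vanish, leaving a*b/c
  expect_equal(
    fertility_rate("hadwiger", unname(p["c"]), p),
    unname(p["a"] * p["b"] / p["c"])
  )
  expect_equal(fertility_rate("hadwiger", 24.2482, p), 0.1849575,
    tolerance = 1e-6
  )
  expect_lt(fertility_rate("hadwiger", 1e-3, p), 1e-300) # x -> 0+ limit
  expect_error(fertility_rate("hadwiger", -1, p), "x > 0")
})

test_that("P-K family peaks at mu with value a + b and is symmetric when spreads match", {
  expect_equal(
    fertility_rate("modified_pk", unname(india_mpk["mu"]), india_mpk),
    unname(india_mpk["a"] + india_mpk["b"])
  )
  sym <- c(b = 0.2, mu = 25, sigma1 = 4, sigma2 = 4)
  for (d in c(0.5, 2, 7)) {
    expect_equal(
      fertility_rate("pk", 25 - d, sym),
      fertility_rate("pk", 25 + d, sym)
    )
  }
  # bounded bell: the exponent carries the negative sign
  expect_lt(fertility_rate("pk", 49, sym), sym["b"])
})

test_that("the Gompertz family reduces and maximizes in closed form", {
  x <- seq(15, 49, by = 0.25)
  p3 <- c(alpha = 4, beta = 4.1, m = 16)
  p4 <- c(alpha = 4, beta = 4.1, gamma = 1, m = 16)
  expect_equal(
    fertility_rate("gompertz", x, p3),
    fertility_rate("modified_gompertz", x, p4)
  )
  # maximizer m + beta*ln(alpha), maximum (alpha/beta)^gamma * e^-(1+ln alpha)
  pk_ <- model_peak("modified_gompertz", india_mg)
  x_star <- unname(india_mg["m"] + india_mg["beta"] * log(india_mg["alpha"]))
  f_star <- unname((india_mg["alpha"] / india_mg["beta"])^india_mg["gamma"] *
    exp(-(1 + log(india_mg["alpha"]))))
  expect_equal(pk_$peak_age, x_star, tolerance = 1e-3)
  expect_equal(pk_$peak_rate, f_star, tolerance = 1e-6)
  expect_equal(x_star, 22.4868, tolerance = 1e-4)
})

test_that("skew normal families evaluate as defined", {
  # delta = 0 collapses to the symmetric normal density
  p <- c(lambda = 22, sigma = 5, delta = 0)
  x <- 15:49
  expect_equal(
    fertility_rate("skew_normal", x, p),
    dnorm((x - 22) / 5) / 5
  )
  # at x = lambda the modified curve is theta * Phi((delta*lambda - lambda)/s1)
  v <- fertility_rate("modified_skew_normal", unname(india_msn["lambda"]), india_msn)
  expect_equal(v, unname(india_msn["theta"]), tolerance = 1e-8)
  # literal vs centered Phi argument genuinely differ for small delta
  p2 <- c(theta = 0.19, lambda = 22, s1 = 3, s2 = 7, delta = 0.5)
  expect_false(isTRUE(all.equal(
    fertility_rate("modified_skew_normal", 18, p2, phi_arg = "literal"),
    fertility_rate("modified_skew_normal", 18, p2, phi_arg = "centered")
  )))
  # junction mismatch of the piecewise Phi term is negligible at the
  # published India values
  lam <- unname(india_msn["lambda"])
  gap <- abs(
    pnorm((india_msn["delta"] * lam - lam) / india_msn["s1"]) -
      pnorm((india_msn["delta"] * lam - lam) / india_msn["s2"])
  )
  expect_lt(gap, 1e-9)
})

test_that("G-P family respects its domain and beta-kernel mode", {
  p3 <- c(p = 1e-4, q = 3, r = 10)
  expect_equal(fertility_rate("gp", 49, p3), 0)
  expect_error(fertility_rate("gp", 50, p3), "<= 49")
  expect_equal(
    fertility_rate("modified_gp", 15, india_mgp),
    unname(india_mgp["s"])
  )
  expect_error(fertility_rate("modified_gp", 14, india_mgp), "15 <= x")
  pk_ <- model_peak("modified_gp", india_mgp)
  x_star <- unname(15 + 49 * india_mgp["q"] / (india_mgp["q"] + india_mgp["r"]))
  expect_equal(pk_$peak_age, x_star, tolerance = 1e-3)
  expect_equal(x_star, 22.5238, tolerance = 1e-3)
  expect_equal(pk_$peak_rate,
    fertility_rate("modified_gp", x_star, india_mgp),
    tolerance = 1e-6
  )
})

test_that("model_peak agrees with closed-form maximizers across families", {
  expect_equal(
    model_peak("modified_pk", india_mpk)$peak_age,
    unname(india_mpk["mu"]),
    tolerance = 1e-3
  )
  expect_equal(
    model_peak("modified_pk", india_mpk)$peak_rate,
    unname(india_mpk["a"] + india_mpk["b"]),
    tolerance = 1e-6
  )
})

test_that("implied TFR sums the curve over integer ages", {
  # near-degenerate flat families
  flat <- c(a = 0.01, b = 1e-6, mu = 22, sigma1 = 3, sigma2 = 9)
  expect_equal(model_implied_tfr("modified_pk", flat), 35 * 0.01,
    tolerance = 1e-3
  )
  # Gompertz family: discrete sum tracks the analytic integral
  # beta * (alpha/beta)^gamma / alpha within 2%
  analytic <- unname(
    india_mg["beta"] * (india_mg["alpha"] / india_mg["beta"])^india_mg["gamma"] /
      india_mg["alpha"]
  )
  expect_equal(model_implied_tfr("modified_gompertz", india_mg), analytic,
    tolerance = 0.02
  )
})

test_that("every family is nonnegative and reductions hold pointwise", {
  x <- seq(15, 49, by = 0.5)
  set.seed(42)
  for (rep in 1:20) {
    ppk <- c(
      b = runif(1, 0.05, 0.3), mu = runif(1, 18, 30),
      sigma1 = runif(1, 1, 6), sigma2 = runif(1, 4, 12)
    )
    a <- runif(1, 0, 0.01)
    expect_true(all(fertility_rate("pk", x, ppk) >= 0))
    expect_equal(
      fertility_rate("modified_pk", x, c(a = 0, ppk)),
      fertility_rate("pk", x, ppk)
    )
    pg <- c(
      alpha = runif(1, 1, 8), beta = runif(1, 2, 8),
      m = runif(1, 12, 18)
    )
    expect_true(all(fertility_rate("gompertz", x, pg) >= 0))
    expect_equal(
      fertility_rate("modified_gompertz", x, c(pg[c("alpha", "beta")], gamma = 1, m = unname(pg["m"]))),
      fertility_rate("gompertz", x, pg)
    )
    pmgp <- c(
      p = runif(1, 1, 500), q = runif(1, 0.5, 4),
      r = runif(1, 5, 20), s = runif(1, 0, 0.01)
    )
    expect_true(all(fertility_rate("modified_gp", x, pmgp) >= 0))
    psn <- c(lambda = runif(1, 18, 28), sigma = runif(1, 2, 9), delta = runif(1, -4, 4))
    expect_true(all(fertility_rate("skew_normal", x, psn) >= 0))
  }
})

test_that("parameter JSON round-trips with ASCII symbol names", {
  path <- withr::local_tempfile(fileext = ".json")
  write_params("modified_gompertz", india_mg, path)
  back <- read_params(path)
  expect_equal(back$family, "modified_gompertz")
  expect_equal(back$params, india_mg)
  expect_error(
    fertility_rate("modified_gompertz", 20, c(alpha = 4, beta = 4, m = 16)),
    "must be named"
  )
})
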
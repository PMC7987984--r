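test_that("AIC/AICc follow the least-squares small-sample formulas", {
  # SSE = n - k makes the log term vanish
  ic <- aic_aicc(sse = 32, n = 35, k = 3)
  expect_equal(ic$aic, 6)
  expect_equal(ic$aicc, 6 + 24 / 31)

  # published NFHS-4 cells with 3-significant-figure SSE
  expect_equal(aic_aicc(0.0684, 35, 3)$aicc, -208.41, tolerance = 0.05 / 208)
  expect_equal(aic_aicc(0.00718, 35, 3)$aicc, -287.307, tolerance = 0.05 / 287)

  expect_warning(ic0 <- aic_aicc(0, 35, 3), "exact interpolation")
  expect_identical(ic0$aicc, -Inf)
  expect_error(aic_aicc(0.1, 5, 4), "exceed")

  # the correction vanishes as n grows
  big <- aic_aicc(1e6 * 0.01, 1e6, 4)
  expect_lt(big$aicc - big$aic, 1e-4)
})

test_that("R-squared equals its two-path recomputation", {
  sched <- india_like_schedule()
  expect_equal(r_squared(sched, "modified_gompertz", india_mg), 1)
  # a constant model at the mean has R2 ~ 0
  flat <- c(
    a = mean(sched$asfr), b = 1e-15, mu = 22,
    sigma1 = 3, sigma2 = 9
  )
  expect_equal(r_squared(sched, "modified_pk", flat), 0, tolerance = 1e-6)

  p <- c(b = 0.18, mu = 23, sigma1 = 3, sigma2 = 8)
  direct <- r_squared(sched, "pk", p)
  recomputed <- 1 - model_sse(sched, "pk", p) /
    sum((sched$asfr - mean(sched$asfr))^2)
  expect_lt(abs(direct - recomputed), 1e-12)

  expect_error(
    r_squared(fertility_schedule(15:49, rep(0.1, 35)), "pk", p),
    "constant"
  )
})

test_that("compare_models ranks by AICc with the parsimony tie rule", {
  sched <- generate_schedule("modified_gompertz", india_mg,
    noise = "gaussian", sd = 0.004, seed = 21
  )
  fits <- lapply(
    c("hadwiger", "gompertz", "modified_gompertz", "pk"),
    function(f) fit_fertility_model(sched, f, n_starts = 6)
  )
  cmp <- compare_models(fits, region = "sim")
  expect_equal(cmp$family[1], cmp$family[which.min(cmp$aicc)])
  expect_true(cmp$best[1])
  expect_equal(sum(cmp$best), 1L)
  expect_true(!is.unsorted(cmp$aicc))

  # permutation invariance
  cmp2 <- compare_models(rev(fits), region = "sim")
  expect_equal(cmp, cmp2)

  # a tie within 0.01 AICc goes to the smaller k
  tie <- list(
    structure(list(family = "modified_pk", n = 35L, k = 5L, sse = 1e-4,
      aic = -400, aicc = -390.001, r_squared = 0.99, converged = TRUE,
      start_index = 1L), class = "fert_fit"),
    structure(list(family = "modified_gompertz", n = 35L, k = 4L, sse = 1e-4,
      aic = -400, aicc = -390.0, r_squared = 0.99, converged = TRUE,
      start_index = 1L), class = "fert_fit")
  )
  expect_equal(compare_models(tie)$family[compare_models(tie)$best],
    "modified_gompertz")

  # mismatched n is an error
  bad <- tie
  bad[[1]]$n <- 20L
  expect_error(compare_models(bad), "different numbers")
})

test_that("correlate_params is the Pearson product-moment correlation", {
  d <- tibble::tibble(u = 1:5, up = 2 * (1:5) + 3, down = -(1:5))
  expect_equal(correlate_params(d, u, up)$r, 1)
  expect_equal(correlate_params(d, u, down)$r, -1)
  expect_error(correlate_params(d[1:2, ], u, up), "at least 3")
  d$const <- 1
  expect_error(correlate_params(d, u, const), "constant")

  # Hadwiger scale parameter against published TFR across the 7 regions
  had <- nfhs4_parameters("hadwiger")
  tfr <- nfhs4_region_summaries()
  r <- correlate_params(dplyr::left_join(had, tfr, by = "region"), a, tfr)$r
  expect_equal(round(r, 3), 0.997)
})
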
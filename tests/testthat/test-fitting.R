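test_that("model_sse matches a term-by-term oracle", {
  sched <- fertility_schedule(c(20, 21), c(0.1, 0.3), allow_extra_ages = TRUE)
  # a constant model at 0.2: squared errors 0.01 + 0.01
  flat <- c(a = 0.2, b = 1e-15, mu = 20, sigma1 = 1, sigma2 = 1)
  expect_equal(model_sse(sched, "modified_pk", flat), 0.02, tolerance = 1e-9)

  truth <- india_like_schedule()
  expect_equal(model_sse(truth, "modified_gompertz", india_mg), 0)

  set.seed(5)
  for (i in 1:5) {
    p <- c(
      b = runif(1, 0.1, 0.3), mu = runif(1, 18, 28),
      sigma1 = runif(1, 2, 5), sigma2 = runif(1, 5, 12)
    )
    fx <- fertility_rate("pk", truth$age, p)
    oracle <- sum(vapply(
      seq_len(35),
      function(j) (truth$asfr[j] - fx[j])^2, numeric(1)
    ))
    got <- model_sse(truth, "pk", p)
    expect_gte(got, 0)
    expect_equal(got, oracle, tolerance = 1e-14)
  }
})

test_that("initialization is deterministic and data-driven", {
  sched <- generate_schedule("modified_pk", india_mpk, noise = "none")
  s1 <- initialize_params(sched, "modified_pk")
  s2 <- initialize_params(sched, "modified_pk")
  expect_identical(s1, s2)
  bell_height <- unname(india_mpk["a"] + india_mpk["b"])
  expect_lt(abs(s1[["b"]] - bell_height) / bell_height, 0.05)
  expect_true(s1[["mu"]] %in% c(21, 22))
  expect_error(
    initialize_params(fertility_schedule(15:49, rep(0, 35)), "pk"),
    "all-zero"
  )
})

test_that("refitting with the same seed reproduces the identical result", {
  sched <- generate_schedule("modified_gompertz", india_mg,
    noise = "gaussian", sd = 0.004, seed = 2
  )
  f1 <- fit_fertility_model(sched, "hadwiger", n_starts = 6, seed = 123)
  f2 <- fit_fertility_model(sched, "hadwiger", n_starts = 6, seed = 123)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$sse, f2$sse)
  expect_identical(f1$start_index, f2$start_index)
})

test_that("the optimum never exceeds the SSE of any tried start", {
  sched <- generate_schedule("modified_gompertz", india_mg,
    noise = "gaussian", sd = 0.005, seed = 9
  )
  f <- fit_fertility_model(sched, "pk", n_starts = 10, seed = 77)
  expect_lte(f$sse, model_sse(sched, "pk", initialize_params(sched, "pk")))
  expect_true(f$converged)
})

test_that("modified families never fit worse than their nested base", {
  for (seed in 1:3) {
    sched <- generate_schedule("modified_gompertz", india_mg,
      noise = "gaussian", sd = 0.004, seed = seed
    )
    base_pk <- fit_fertility_model(sched, "pk", n_starts = 8)
    mod_pk <- fit_fertility_model(sched, "modified_pk", n_starts = 8)
    expect_lte(mod_pk$sse, base_pk$sse + 1e-10)
    base_g <- fit_fertility_model(sched, "gompertz", n_starts = 8)
    mod_g <- fit_fertility_model(sched, "modified_gompertz", n_starts = 8)
    expect_lte(mod_g$sse, base_g$sse + 1e-10)
  }
})

test_that("tidiers expose the fit in broom shape", {
  sched <- india_like_schedule()
  f <- fit_fertility_model(sched, "modified_gompertz",
    n_starts = 4,
    compute_se = TRUE
  )
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("alpha", "beta", "gamma", "m"))
  gl <- glance(f)
  expect_equal(gl$k, 4L)
  expect_equal(gl$n, 35L)
  au <- augment(f)
  expect_equal(au$.resid, au$asfr - au$.fitted)
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(plot_schedule(sched, smooth_schedule(sched)), "ggplot")
})

test_that("fitting to the smoothed schedule is available behind a flag", {
  sched <- generate_schedule("modified_gompertz", india_mg,
    noise = "gaussian", sd = 0.01, seed = 4
  )
  raw <- fit_fertility_model(sched, "hadwiger", n_starts = 5)
  smo <- fit_fertility_model(sched, "hadwiger", n_starts = 5, fit_to = "smoothed")
  # the smoothed target differs from the raw one, so the optima differ
  expect_false(isTRUE(all.equal(raw$sse, smo$sse)))
  expect_equal(
    smo$data$asfr,
    pmax(smooth_schedule(sched, span = 0.2, allow_extra_ages = TRUE)$asfr, 0)
  )
})
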
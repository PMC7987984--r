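## Nonlinear least-squares fitting of a model family to a schedule.
##
## The objective is the plain SSE over the schedule's ages; minimization
## uses nlminb (PORT: bounded quasi-Newton) from a data-driven start plus
## seeded multiplicative/additive jitters, and -- for families that nest a
## base family exactly -- one extra start at the fitted base solution
## extended with the neutral value of the new parameter, which guarantees
## the modified family never fits worse than its base.

## box constraints per family; the data are rates (< ~0.3/yr), peak ages
## sit in 15-49, so generous demographic boxes
FAMILY_BOUNDS <- list(
  hadwiger = list(
    lower = c(a = 0.01, b = 0.1, c = 15),
    upper = c(a = 10, b = 20, c = 45)
  ),
  pk = list(
    lower = c(b = 1e-6, mu = 10, sigma1 = 0.1, sigma2 = 0.1),
    upper = c(b = 1, mu = 49, sigma1 = 30, sigma2 = 30)
  ),
  modified_pk = list(
    lower = c(a = 0, b = 1e-6, mu = 10, sigma1 = 0.1, sigma2 = 0.1),
    upper = c(a = 0.05, b = 1, mu = 49, sigma1 = 30, sigma2 = 30)
  ),
  gompertz = list(
    lower = c(alpha = 0.1, beta = 0.1, m = 10),
    upper = c(alpha = 30, beta = 30, m = 49)
  ),
  modified_gompertz = list(
    lower = c(alpha = 0.1, beta = 0.1, gamma = 0.1, m = 10),
    upper = c(alpha = 30, beta = 30, gamma = 50, m = 49)
  ),
  skew_normal = list(
    lower = c(lambda = 10, sigma = 0.1, delta = -20),
    upper = c(lambda = 49, sigma = 30, delta = 20)
  ),
  modified_skew_normal = list(
    lower = c(theta = 1e-6, lambda = 10, s1 = 0.1, s2 = 0.1, delta = -20),
    upper = c(theta = 1, lambda = 49, s1 = 30, s2 = 30, delta = 20)
  ),
  gp = list(
    lower = c(p = 1e-6, q = 0.01, r = 0.01),
    upper = c(p = 1e6, q = 50, r = 50)
  ),
  modified_gp = list(
    lower = c(p = 1e-6, q = 0.01, r = 0.01, s = 0),
    upper = c(p = 1e6, q = 50, r = 50, s = 0.05)
  )
)

## parameters jittered additively (years) rather than multiplicatively
LOCATION_PARAMS <- c("mu", "lambda", "m", "c")

#' Sum of squared errors of a model on a schedule
#'
#' @param schedule Data frame with columns `age`, `asfr`.
#' @inheritParams fertility_rate
#' @return Scalar SSE, \eqn{\sum_x (f(x) - \hat f(x))^2}.
#' @export
model_sse <- function(schedule, family, params,
                      phi_arg = c("literal", "centered")) {
  schedule <- validate_schedule(schedule, allow_extra_ages = TRUE)
  fx <- fertility_rate(family, schedule$age, params,
    phi_arg = match.arg(phi_arg)
  )
  sum((schedule$asfr - fx)^2)
}

#' Data-driven starting values for a family
#'
#' Peak-shaped families start the level parameter at the maximum observed
#' rate, the location at its age, and the pre-/post-peak spreads at 3 and 9
#' years; late-age constants start at the mean rate over ages 45--49.  The
#' Gompertz family starts at m = min(age) - 1, beta = 4, alpha = 4 and
#' (modified) gamma = 10; Hadwiger at c = peak age, a = TFR/2, b = 3.5.
#' The G-P family inverts the beta-kernel mode relation q/(q+r) at the
#' observed peak age.  All values are clipped into the fitting bounds.
#' Deterministic: no randomness is used.
#'
#' @param schedule Data frame with columns `age`, `asfr`.
#' @inheritParams fertility_rate
#' @return Named numeric vector of starting values.
#' @export
initialize_params <- function(schedule, family) {
  family <- check_family(family)
  schedule <- validate_schedule(schedule, allow_extra_ages = TRUE)
  if (all(schedule$asfr == 0)) {
    abort("all-zero schedule: no peak to initialize from")
  }
  peak_i <- which.max(schedule$asfr)
  peak_rate <- schedule$asfr[peak_i]
  peak_age <- as.numeric(schedule$age[peak_i])
  late <- schedule$asfr[schedule$age >= 45 & schedule$age <= 49]
  late_mean <- if (length(late)) mean(late) else 0
  tfr <- sum(schedule$asfr)

  start <- switch(family,
    hadwiger = c(a = tfr / 2, b = 3.5, c = peak_age),
    pk = c(b = peak_rate, mu = peak_age, sigma1 = 3, sigma2 = 9),
    modified_pk = c(
      a = late_mean, b = peak_rate, mu = peak_age, sigma1 = 3, sigma2 = 9
    ),
    gompertz = c(alpha = 4, beta = 4, m = min(schedule$age) - 1),
    modified_gompertz = c(
      alpha = 4, beta = 4, gamma = 10, m = min(schedule$age) - 1
    ),
    skew_normal = c(lambda = peak_age, sigma = 4, delta = 2),
    modified_skew_normal = c(
      theta = peak_rate, lambda = peak_age, s1 = 3, s2 = 9, delta = 2
    ),
    gp = gp_start(peak_rate, peak_age, shifted = FALSE),
    modified_gp = c(gp_start(peak_rate - late_mean, peak_age, shifted = TRUE),
      s = late_mean
    )
  )
  clip_bounds(start, family)
}

# invert the beta-kernel mode relation at the observed peak
gp_start <- function(peak_rate, peak_age, shifted) {
  q <- 2.5
  if (shifted) {
    u <- min(max((peak_age - 15) / 49, 0.02), 0.98)
    r <- q * (1 - u) / u
    p <- max(peak_rate, 1e-4) / (u^q * (1 - u)^r)
  } else {
    u <- min(max(peak_age / 49, 0.02), 0.98)
    r <- q * (1 - u) / u
    p <- max(peak_rate, 1e-4) / (peak_age^q * (1 - u)^r)
  }
  c(p = p, q = q, r = r)
}

clip_bounds <- function(params, family, bounds = FAMILY_BOUNDS[[family]]) {
  nm <- names(params)
  pmin(pmax(params, bounds$lower[nm]), bounds$upper[nm])
}

#' Fit a parametric fertility model by nonlinear least squares
#'
#' Minimizes the SSE of the chosen family on a schedule with
#' [stats::nlminb()] (bounded quasi-Newton) from the [initialize_params()]
#' start plus `n_starts - 1` seeded jitters (multiplicative log-normal, sd
#' 0.3, on positive parameters; additive +/-3 years on location
#' parameters).  For `modified_pk` and `modified_gompertz` one further
#' start is the fitted base family extended with the neutral extra
#' parameter (a = 0, gamma = 1), so the modified family's SSE never
#' exceeds the base family's.  The best local optimum is returned with
#' AIC, AICc and R-squared attached.
#'
#' @param schedule Data frame with columns `age`, `asfr`.
#' @inheritParams fertility_rate
#' @param n_starts Number of starts (>= 1; the first is the deterministic
#'   heuristic).
#' @param seed Integer seed for the jittered starts.
#' @param fit_to Fit to the `"raw"` schedule (default) or to its
#'   loess-smoothed version (`"smoothed"`, span `span`, degree 2).
#' @param span Smoothing span used when `fit_to = "smoothed"`.
#' @param bounds Optional list with named vectors `lower`, `upper`
#'   overriding the default boxes.
#' @param tol SSE tolerance used in convergence control and the nesting
#'   guarantee.
#' @param max_iter Iteration cap per start.
#' @param compute_se Also compute Gauss-Newton asymptotic standard errors
#'   (reported by [tidy()] only when this is `TRUE`; by convention they are
#'   not part of the default output).
#' @return An object of class `fert_fit`: a list with the fitted `params`,
#'   `sse`, `n`, `k`, `aic`, `aicc`, `r_squared`, `converged`,
#'   `start_index`, the data fitted and the fitted curve.  Use [tidy()],
#'   [glance()], [augment()], [autoplot()].
#' @examples
#' sched <- generate_schedule("modified_gompertz",
#'   c(alpha = 4.36, beta = 4.09, gamma = 13.1, m = 16.46),
#'   noise = "none"
#' )
#' fit <- fit_fertility_model(sched, "modified_gompertz", n_starts = 5)
#' glance(fit)
#' @export
fit_fertility_model <- function(schedule, family, n_starts = 20,
                                seed = 20210323,
                                fit_to = c("raw", "smoothed"), span = 0.2,
                                bounds = NULL, tol = 1e-12, max_iter = 500,
                                compute_se = FALSE,
                                phi_arg = c("literal", "centered")) {
  family <- check_family(family)
  fit_to <- match.arg(fit_to)
  phi_arg <- match.arg(phi_arg)
  schedule <- validate_schedule(schedule, allow_extra_ages = TRUE)
  if (n_starts < 1) abort("`n_starts` must be >= 1")
  data <- if (fit_to == "smoothed") {
    smooth_schedule(schedule, span = span, allow_extra_ages = TRUE)
  } else {
    schedule
  }
  # local smoothing can dip negative in near-zero tails; rates are bounded
  # below by zero
  data$asfr <- pmax(data$asfr, 0)
  if (is.null(bounds)) bounds <- FAMILY_BOUNDS[[family]]
  pnames <- family_params(family)
  lower <- bounds$lower[pnames]
  upper <- bounds$upper[pnames]

  x <- as.numeric(data$age)
  y <- data$asfr
  objective <- function(par) {
    fx <- try(
      fertility_rate(family, x, setNames(par, pnames), phi_arg = phi_arg),
      silent = TRUE
    )
    if (inherits(fx, "try-error") || any(!is.finite(fx))) {
      return(1e10)
    }
    sum((y - fx)^2)
  }

  starts <- build_starts(data, family, n_starts, seed, lower, upper)
  if (family %in% names(NESTED_BASE)) {
    base_fit <- fit_fertility_model(data, NESTED_BASE[[family]],
      n_starts = n_starts, seed = seed, bounds = NULL, tol = tol,
      max_iter = max_iter, phi_arg = phi_arg
    )
    neutral <- switch(family,
      modified_pk = c(a = 0, base_fit$params),
      modified_gompertz = {
        bp <- base_fit$params
        c(alpha = unname(bp["alpha"]), beta = unname(bp["beta"]),
          gamma = 1, m = unname(bp["m"]))
      }
    )
    starts <- c(starts, list(clip_bounds(neutral[pnames], family, bounds)))
  }

  best <- NULL
  converged_any <- FALSE
  for (i in seq_along(starts)) {
    par0 <- starts[[i]]
    sse0 <- objective(par0)
    res <- tryCatch(
      nlminb(par0, objective,
        lower = lower, upper = upper,
        control = list(
          eval.max = 4L * max_iter, iter.max = max_iter,
          rel.tol = 1e-14, abs.tol = 0, x.tol = 1e-12
        )
      ),
      error = function(e) NULL
    )
    cand <- if (!is.null(res) && is.finite(res$objective) &&
      res$objective <= sse0) {
      # PORT reports flat-Hessian optima as "singular convergence"; for a
      # least-squares ridge that is still a converged solution
      ok <- res$convergence == 0 || grepl(
        "relative convergence|absolute function convergence|X-convergence|singular convergence",
        res$message %||% ""
      )
      converged_any <- converged_any || ok
      list(par = res$par, sse = res$objective, start_index = i)
    } else {
      list(par = par0, sse = sse0, start_index = i)
    }
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  if (is.null(best) || !is.finite(best$sse) || best$sse >= 1e10) {
    abort(paste0(
      "no start converged for family '", family, "' (", length(starts),
      " starts tried)"
    ))
  }

  params <- setNames(as.numeric(best$par), pnames)
  n <- nrow(data)
  k <- length(pnames)
  ic <- aic_aicc(max(best$sse, 0), n, k)
  r2 <- if (length(unique(y)) > 1) {
    1 - best$sse / sum((y - mean(y))^2)
  } else {
    NA_real_
  }
  fitted_vals <- fertility_rate(family, x, params, phi_arg = phi_arg)

  out <- list(
    family = family,
    params = params,
    sse = best$sse,
    n = n, k = k,
    aic = ic$aic, aicc = ic$aicc,
    r_squared = r2,
    converged = converged_any,
    start_index = best$start_index,
    n_starts = length(starts),
    seed = seed,
    fit_to = fit_to,
    phi_arg = phi_arg,
    data = tibble::tibble(age = data$age, asfr = y, fitted = fitted_vals)
  )
  if (compute_se) {
    out$std_errors <- gauss_newton_se(family, params, x, y, best$sse, phi_arg)
  }
  structure(out, class = "fert_fit")
}

build_starts <- function(schedule, family, n_starts, seed, lower, upper) {
  start0 <- initialize_params(schedule, family)
  starts <- list(start0)
  if (n_starts > 1) {
    withr_seed <- function(code) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        else suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
        add = TRUE
      )
      set.seed(seed)
      code
    }
    starts <- c(starts, withr_seed({
      lapply(seq_len(n_starts - 1), function(j) {
        par <- start0
        for (nm in names(par)) {
          if (nm %in% LOCATION_PARAMS) {
            par[nm] <- par[nm] + runif(1, -3, 3)
          } else {
            par[nm] <- par[nm] * exp(rnorm(1, 0, 0.3))
          }
        }
        clip_bounds(par, family, list(lower = lower, upper = upper))
      })
    }))
  }
  starts
}

# asymptotic covariance via the Gauss-Newton approximation J'J
gauss_newton_se <- function(family, params, x, y, sse, phi_arg) {
  k <- length(params)
  n <- length(x)
  J <- matrix(0, n, k)
  for (j in seq_len(k)) {
    h <- max(1e-6, 1e-6 * abs(params[j]))
    up <- dn <- params
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    J[, j] <- (fertility_rate(family, x, up, phi_arg = phi_arg) -
      fertility_rate(family, x, dn, phi_arg = phi_arg)) / (2 * h)
  }
  sigma2 <- sse / (n - k)
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) {
    return(setNames(rep(NA_real_, k), names(params)))
  }
  setNames(sqrt(pmax(diag(cov), 0)), names(params))
}

#' @export
print.fert_fit <- function(x, ...) {
  cat("<fert_fit> family:", x$family, "\n")
  cat("  params:", paste0(
    names(x$params), " = ", signif(x$params, 5),
    collapse = ", "
  ), "\n")
  cat(sprintf(
    "  sse = %.6g  aicc = %.4f  r2 = %.5f  (n = %d, k = %d)\n",
    x$sse, x$aicc, x$r_squared, x$n, x$k
  ))
  invisible(x)
}

#' Tidy a fitted fertility model
#'
#' @param x A `fert_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (and `std.error` if the
#'   fit was run with `compute_se = TRUE`).
#' @method tidy fert_fit
#' @export
tidy.fert_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$params), estimate = unname(x$params))
  if (!is.null(x$std_errors)) out$std.error <- unname(x$std_errors)
  out
}

#' One-row summary of a fitted fertility model
#'
#' @param x A `fert_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `n`, `k`, `sse`, `aic`, `aicc`,
#'   `r_squared`, `converged`, `start_index`.
#' @method glance fert_fit
#' @export
glance.fert_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, n = x$n, k = x$k, sse = x$sse,
    aic = x$aic, aicc = x$aicc, r_squared = x$r_squared,
    converged = x$converged, start_index = x$start_index
  )
}

#' Observed data with fitted values and residuals
#'
#' @param x A `fert_fit` object.
#' @param ... Unused.
#' @return The fitted schedule with `.fitted` and `.resid` columns.
#' @method augment fert_fit
#' @export
augment.fert_fit <- function(x, ...) {
  tibble::tibble(
    age = x$data$age,
    asfr = x$data$asfr,
    .fitted = x$data$fitted,
    .resid = x$data$asfr - x$data$fitted
  )
}

#' Plot observed and fitted ASFR
#'
#' @param object A `fert_fit` object.
#' @param ... Unused.
#' @return A ggplot of the observed points and the fitted curve evaluated
#'   on a fine age grid.
#' @method autoplot fert_fit
#' @export
autoplot.fert_fit <- function(object, ...) {
  grid <- seq(min(object$data$age), max(object$data$age), by = 0.1)
  curve <- tibble::tibble(
    age = grid,
    asfr = fertility_rate(object$family, grid, object$params,
      phi_arg = object$phi_arg
    )
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age, y = .data$asfr)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(
      x = "Age (years)", y = "ASFR (births per woman per year)",
      title = paste("Fitted", object$family, "model")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
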
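#' Root-sum-of-squares goodness of fit
#'
#' `GF = 1 - sqrt(sum((O - E)^2)) / sqrt(sum((O - mean(O))^2))`: one minus
#' the ratio of the root sum of squared residuals to the root sum of squared
#' deviations of the observations from their mean. A perfect fit gives
#' `GF = 1`; predicting the observed mean everywhere gives 0. Note this is a
#' ratio of roots, not of sums — it is not the coefficient of determination.
#'
#' @param observed observed values (length >= 2, not all equal).
#' @param predicted predicted values, same length.
#' @return the goodness-of-fit score, at most 1.
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have the same length", call. = FALSE)
  if (length(observed) < 2L)
    stop("at least two observations are required", call. = FALSE)
  denom <- sqrt(sum((observed - mean(observed))^2))
  if (denom == 0)
    stop("all observed values are equal: goodness of fit is undefined",
         call. = FALSE)
  1 - sqrt(sum((observed - predicted)^2)) / denom
}

#' Predicted masses at observed ages
#'
#' Integrates a rate model from `W0` at the first observed age and returns
#' the dense-output masses at each observed age.
#'
#' @param model a growth model parameter object (any class with a
#'   [growth_rate()] method).
#' @param ages strictly increasing observation ages (days).
#' @param W0 initial mass (mg), anchored at `ages[1]`.
#' @param rtol,atol solver tolerances.
#' @return predicted masses (mg) at `ages`.
#' @export
predict_masses <- function(model, ages, W0, rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(ages) >= 2L, all(diff(ages) > 0), W0 > 0)
  # strict right-hand side: a maintenance singularity inside the integration
  # domain is a genuine model failure here (callers penalise it), so it is
  # propagated rather than guarded; solver diagnostics from hopeless
  # parameter sets explored during optimisation are silenced
  invisible(utils::capture.output(
    sol <- suppressWarnings(deSolve::lsoda(
      y = c(W = W0), times = ages,
      func = function(t, y, parms) list(growth_rate(model, y[[1L]], 1)),
      parms = NULL, rtol = rtol, atol = atol, maxsteps = 2000L
    ))
  ))
  if (nrow(sol) < length(ages) || any(!is.finite(sol[, 2L])))
    stop("integration failed over the observation ages", call. = FALSE)
  unname(sol[, 2L])
}

#' Least-squares objective for the inverse method
#'
#' Sum of squared deviations between observed average masses and the model
#' trajectory through the observed ages, for a parameter vector `theta` of a
#' registry model. Integration failures return a large penalty (1e12 mg^2)
#' with a warning so that optimizers can continue past pathological
#' parameter combinations.
#'
#' @param theta named parameter vector (names per the registry entry).
#' @param data data frame with columns `age` and `mass` (averaged
#'   mass-at-age data, ages strictly increasing).
#' @param model registry key (see [growth_model_registry()]).
#' @param W0 initial mass; defaults to the first observed mass.
#' @param registry the model registry.
#' @return the residual sum of squares (mg^2).
#' @export
sse_objective <- function(theta, data, model = "MGM_eq33", W0 = NULL,
                          registry = growth_model_registry()) {
  spec <- registry[[model]]
  if (is.null(spec)) stop("unknown model: ", model, call. = FALSE)
  if (is.null(W0)) W0 <- data$mass[1L]
  names(theta) <- spec$par_names
  obj <- tryCatch({
    m <- spec$make(theta)
    pred <- predict_masses(m, data$age, W0)
    sum((data$mass - pred)^2)
  }, error = function(e) {
    warning("objective penalised: ", conditionMessage(e), call. = FALSE)
    1e12
  })
  if (!is.finite(obj)) 1e12 else obj
}

# Latin-hypercube starting values on the bounds, log-spaced for scale
# parameters.
.lhs_starts <- function(n_starts, lower, upper, log_scale) {
  k <- length(lower)
  u <- lhs::randomLHS(n_starts, k)
  starts <- matrix(NA_real_, n_starts, k, dimnames = list(NULL, names(lower)))
  for (j in seq_len(k)) {
    nm <- names(lower)[j]
    if (nm %in% log_scale) {
      lo <- log(max(lower[j], 1e-6))
      hi <- log(upper[j])
      starts[, j] <- exp(lo + u[, j] * (hi - lo))
    } else {
      starts[, j] <- lower[j] + u[, j] * (upper[j] - lower[j])
    }
  }
  starts
}

#' Fit a growth model to averaged mass-at-age data
#'
#' The inverse method: bounded local least-squares optimisation
#' (Levenberg-Marquardt, [minpack.lm::nls.lm()]) of the model trajectory
#' against averaged data, from a seeded Latin-hypercube multi-start. The initial mass is fixed at the
#' first observed mass, not estimated. The goodness of fit
#' ([goodness_of_fit()]) is evaluated on the fitted mass-vs-age curve.
#'
#' For data with multiplicative (e.g. lognormal) noise, `weights =
#' "relative"` divides residuals by the observed masses, the
#' variance-stabilised estimator; the default `"none"` is the plain
#' least-squares of the classical inverse method. `fixed` holds named
#' parameters at known values, which is essential in recovery studies of
#' weakly identified parameters: the expenditure normalisation and the
#' defence normalisation are strongly collinear along the growth curve, so
#' the former is only estimable conditional on the latter.
#'
#' @inheritParams sse_objective
#' @param bounds optional list with named vectors `lower` and `upper`
#'   overriding the registry defaults.
#' @param n_starts number of multi-start runs (default 16).
#' @param seed integer seed making the start set, and hence the fit,
#'   reproducible.
#' @param weights `"none"` (absolute residuals) or `"relative"` (residuals
#'   divided by observed mass).
#' @param fixed optional named numeric vector of parameters held fixed
#'   (excluded from optimisation).
#' @return an object of class `mgm_fit`: a list with the registry key
#'   (`model_name`), named parameter estimates (`params`), `sse`, `gf`,
#'   `n_obs`, `starts`, per-start convergence flags (`converged`), `seed`,
#'   the fitted model object (`model`), predicted masses (`fitted`) and the
#'   per-start diagnostics table (`all_starts`).
#' @export
fit_model <- function(data, model = "MGM_eq33", bounds = NULL,
                      n_starts = 16L, seed = 1L, W0 = NULL,
                      weights = c("none", "relative"), fixed = NULL,
                      registry = growth_model_registry()) {
  stopifnot(is.data.frame(data), all(c("age", "mass") %in% names(data)))
  weights <- match.arg(weights)
  if (!all(diff(data$age) > 0))
    stop("observation ages must be strictly increasing", call. = FALSE)
  spec <- registry[[model]]
  if (is.null(spec)) stop("unknown model: ", model, call. = FALSE)
  if (is.null(W0)) W0 <- data$mass[1L]
  b <- if (is.null(bounds)) spec$bounds(data) else bounds
  stopifnot(all(is.finite(b$lower)), all(is.finite(b$upper)))
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), spec$par_names)
    if (length(bad))
      stop("fixed parameters not in the model: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  free <- setdiff(spec$par_names, names(fixed))
  if (!length(free)) stop("no free parameters left to fit", call. = FALSE)
  lower <- stats::setNames(b$lower[free], free)
  upper <- stats::setNames(b$upper[free], free)
  w <- if (weights == "relative") 1 / data$mass else rep(1, nrow(data))

  full_theta <- function(th_free) {
    theta <- c(th_free, unlist(fixed))[spec$par_names]
    stats::setNames(theta, spec$par_names)
  }
  set.seed(seed)
  starts <- .lhs_starts(n_starts, lower, upper, spec$log_scale)
  if (is.function(spec$smart_start)) {
    ss <- spec$smart_start(data)[free]
    starts[1L, ] <- pmin(pmax(ss, lower), upper)
  }
  n_penalised <- 0L
  # Levenberg-Marquardt on the residual vector, per start; scale parameters
  # are optimised on the log scale (vastly better conditioning across the
  # orders of magnitude the bounds span), and integration failures yield a
  # constant huge residual so the search backs away.
  is_log <- free %in% spec$log_scale
  to_eta <- function(th) ifelse(is_log, log(th), th)
  to_theta <- function(eta) {
    th <- ifelse(is_log, exp(eta), eta)
    stats::setNames(th, free)
  }
  resid_fn <- function(eta) {
    tryCatch({
      pred <- predict_masses(spec$make(full_theta(to_theta(eta))),
                             data$age, W0)
      (data$mass - pred) * w
    }, error = function(e) {
      n_penalised <<- n_penalised + 1L
      rep(1e6, nrow(data))
    })
  }
  runs <- lapply(seq_len(n_starts), function(i) {
    minpack.lm::nls.lm(par = to_eta(starts[i, ]),
                       lower = to_eta(lower), upper = to_eta(upper),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 300L, ftol = 1e-14, ptol = 1e-12))
  })
  devs <- vapply(runs, `[[`, numeric(1), "deviance")
  converged <- vapply(runs, function(r) r$info %in% 1:4, logical(1))
  if (all(devs >= 1e12))
    stop("no start converged to a feasible fit; per-start objectives: ",
         paste(signif(devs, 3), collapse = ", "), call. = FALSE)
  best <- which.min(devs)
  theta <- full_theta(to_theta(runs[[best]]$par))
  fitted_model <- spec$make(theta)
  fitted <- predict_masses(fitted_model, data$age, W0)
  structure(list(model_name = model, params = theta, fixed = fixed,
                 sse = sum((data$mass - fitted)^2),
                 objective = devs[best], weights = weights,
                 gf = goodness_of_fit(data$mass, fitted),
                 n_obs = nrow(data), starts = n_starts,
                 converged = converged, seed = seed,
                 W0 = W0, model = fitted_model, fitted = fitted,
                 n_penalised_evals = n_penalised,
                 all_starts = data.frame(start = seq_len(n_starts),
                                         objective = devs,
                                         converged = converged)),
            class = "mgm_fit")
}

#' @export
print.mgm_fit <- function(x, ...) {
  cat(sprintf("Inverse-method fit of '%s' to %d averaged observations\n",
              x$model_name, x$n_obs))
  cat("  parameters:\n")
  for (nm in names(x$params))
    cat(sprintf("    %-6s = %.6g\n", nm, x$params[[nm]]))
  cat(sprintf("  SSE = %.6g mg^2    GF = %.6g\n", x$sse, x$gf))
  cat(sprintf("  %d/%d starts converged (seed %d)\n",
              sum(x$converged), x$starts, x$seed))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit an [fit_model()] result.
#' @param path optional destination file; if `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mgm_fit"))
  payload <- list(model = fit$model_name, params = as.list(fit$params),
                  sse = fit$sse, gf = fit$gf, n_obs = fit$n_obs,
                  starts = fit$starts, converged = sum(fit$converged),
                  seed = fit$seed, W0 = fit$W0)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
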
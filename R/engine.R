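#' Instantaneous growth rate
#'
#' Evaluates `dW/dt` for a growth model at body mass `W` and relative food
#' acquirement `phi`. For the full model this is
#' `[e S - R_F(S) - R_M(phi, W)] / (E_M(W) + E_S(W))`; reduced and
#' comparator models have their own closed forms. Negative values are
#' returned as such (they indicate a state above the ultimate mass, outside
#' the default integration domain); singular maintenance denominators raise
#' an error.
#'
#' @param model a model parameter object (`mgm_params`, `mgm33_params`,
#'   `gsgm_params`, `vb_params` or `logistic_params`).
#' @param W body mass (mg), > 0; may be a vector.
#' @param phi relative food acquirement in \[0, 1\] (ignored by comparator
#'   models, which are ad-libitum descriptions).
#' @param ... passed to methods.
#' @return growth rate (mg/day), same length as `W`.
#' @export
growth_rate <- function(model, W, phi = 1, ...) UseMethod("growth_rate")

#' @export
growth_rate.mgm_params <- function(model, W, phi = 1, ...) {
  if (any(W <= 0)) stop("body mass 'W' must be positive", call. = FALSE)
  S <- ingestion_rate(phi, W, model$ingestion)
  EM <- energy_density_EM(W, model$composition)
  ES <- growth_overhead_ES(W, model$composition)
  RF <- feeding_cost(S, model$feeding)
  RM <- maintenance_cost(phi, W, model$maintenance,
                         p_R = model$composition$p_R(W))
  (model$e * S - RF - RM) / (EM + ES)
}

#' @export
growth_rate.mgm33_params <- function(model, W, phi = 1, ...) {
  if (any(W <= 0)) stop("body mass 'W' must be positive", call. = FALSE)
  denom <- 1 - model$a_N * W
  if (any(denom <= 0))
    stop(sprintf("defence fraction >= 1 at body mass %g mg: maintenance would diverge",
                 W[which(denom <= 0)[1L]]), call. = FALSE)
  model$a * W^model$beta - model$c * W / denom
}

# Guarded right-hand side for solver trial steps: in the (unreachable)
# region where the defence fraction exceeds 1, report a strong decline so
# adaptive steps retreat instead of crashing on the singularity error.
.rate_guarded <- function(model, W, phi) {
  tryCatch(growth_rate(model, W, phi), error = function(e) -abs(W) * 1e3)
}

.phi_fun <- function(phi) {
  if (is.function(phi)) return(phi)
  if (is.numeric(phi) && length(phi) == 1L && is.finite(phi) &&
      phi >= 0 && phi <= 1) {
    force(phi)
    return(function(t) phi)
  }
  stop("'phi' must be a scalar in [0, 1] or a function of time", call. = FALSE)
}

#' Integrate the growth equation
#'
#' Solves `dW/dt = growth_rate(model, W, phi(t))` from `W0` with an adaptive
#' stiff-capable solver (`deSolve::lsoda`), returning dense output at the
#' requested ages.
#'
#' @param model a growth model parameter object.
#' @param W0 initial body mass (mg), > 0.
#' @param t_end final age (days), > 0.
#' @param phi relative food acquirement: a scalar in \[0, 1\] or a
#'   piecewise/continuous function of age (e.g. a [stats::stepfun()]).
#' @param ages ages at which the solution is reported; default 1001 evenly
#'   spaced points on \[0, t_end\].
#' @param rtol,atol solver tolerances (defaults 1e-9 and 1e-12 mg).
#' @return an object of class `growth_trajectory`: a data frame with columns
#'   `age` and `mass`, carrying the model and `phi` as attributes.
#' @export
integrate_growth <- function(model, W0, t_end, phi = 1, ages = NULL,
                             rtol = 1e-9, atol = 1e-12) {
  stopifnot(is.numeric(W0), length(W0) == 1L, W0 > 0)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("'t_end' must be a positive duration in days", call. = FALSE)
  phi_f <- .phi_fun(phi)
  r0 <- growth_rate(model, W0, phi_f(0))
  if (!is.finite(r0))
    stop("growth rate is not finite at the initial mass", call. = FALSE)
  if (is.null(ages)) ages <- seq(0, t_end, length.out = 1001L)
  stopifnot(all(diff(ages) > 0), min(ages) >= 0, max(ages) <= t_end)
  if (ages[1L] > 0) ages <- c(0, ages)
  sol <- deSolve::lsoda(
    y = c(W = W0), times = ages,
    func = function(t, y, parms) list(.rate_guarded(model, y[[1L]], phi_f(t))),
    parms = NULL, rtol = rtol, atol = atol
  )
  out <- data.frame(age = sol[, 1L], mass = sol[, 2L])
  structure(out, class = c("growth_trajectory", "data.frame"),
            model = model, phi = phi)
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf("Growth trajectory: %d ages on [%g, %g] days, mass %g -> %g mg\n",
              nrow(x), min(x$age), max(x$age), x$mass[1L], x$mass[nrow(x)]))
  invisible(x)
}

#' Ultimate (asymptotic) body mass
#'
#' The positive root of `growth_rate(model, W, phi) = 0` above `W0`, located
#' by a bracketing root finder to a relative tolerance of 1e-10. Growth must
#' be positive at `W0`; if no downturn is found after extensive bracket
#' expansion, growth is indefinite under the supplied parameters and an
#' error is raised.
#'
#' @inheritParams integrate_growth
#' @param phi relative food acquirement (scalar).
#' @param W0 lower end of the search bracket (mg).
#' @return ultimate mass (mg).
#' @export
ultimate_mass <- function(model, phi = 1, W0 = 0.67) {
  phi <- .phi_fun(phi)(0)
  f <- function(W) growth_rate(model, W, phi)
  if (f(W0) <= 0)
    stop(paste("no ultimate mass: growth rate is non-positive at the initial",
               "mass (immediate decline)"), call. = FALSE)
  lo <- W0
  hi <- W0
  for (k in seq_len(120L)) {
    cand <- hi * 2
    v <- tryCatch(f(cand), error = function(e) NULL)
    if (is.null(v)) {
      # singular point between hi and cand; shrink toward it until finite
      upper <- cand
      for (j in seq_len(200L)) {
        upper <- (hi + upper) / 2
        v <- tryCatch(f(upper), error = function(e) NULL)
        if (!is.null(v)) break
      }
      if (is.null(v) || v > 0)
        stop("could not bracket the ultimate mass near the maintenance singularity",
             call. = FALSE)
      hi <- upper
      break
    }
    if (v <= 0) { hi <- cand; break }
    lo <- cand
    hi <- cand
    if (k == 120L)
      stop("no ultimate mass: growth never declines (indefinite growth)",
           call. = FALSE)
  }
  r <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10 * hi,
                      maxiter = 2000L)
  r$root
}

#' Summarize a growth trajectory
#'
#' Derived descriptors of a trajectory under constant `phi`: ultimate mass
#' `W_U` (from the rate function's root, not the trajectory end), maximum
#' growth rate `Wdot_max` and the mass `W_star` where it occurs (by
#' continuous maximisation of the rate function), `W95 = 0.95 W_U` and the
#' first age `t95` reaching it, the dimensionless ratios
#' `omega_star = W_star / W_U` and `Omega = Wdot_max / ((W95 - W0) / t95)`
#' (maximum over average life-time growth rate, with "life time" taken as
#' `t95`), and an age-at-mass-fraction interpolator.
#'
#' @param traj a [integrate_growth()] trajectory (constant `phi`).
#' @param model the model parameters; defaults to those stored in `traj`.
#' @return an object of class `trajectory_summary`: a list with elements
#'   `W_U`, `Wdot_max`, `W_star`, `W95`, `t95`, `omega_star`, `Omega` and
#'   `t_at_fraction` (a function of the mass fraction `omega_U`).
#' @export
summarize_trajectory <- function(traj, model = attr(traj, "model")) {
  stopifnot(inherits(traj, "growth_trajectory"))
  phi <- attr(traj, "phi")
  if (!is.numeric(phi))
    stop("trajectory summaries require a constant 'phi'", call. = FALSE)
  W0 <- traj$mass[1L]
  W_U <- ultimate_mass(model, phi = phi, W0 = W0)
  opt <- stats::optimize(function(W) growth_rate(model, W, phi),
                         interval = c(min(W0, 1e-6), W_U),
                         maximum = TRUE, tol = 1e-10 * W_U)
  # monotone (mass, age) table for inverse interpolation; the solver can
  # emit numerically equal masses on the plateau
  ms <- cummax(traj$mass)
  keep <- !duplicated(ms)
  # monotone cubic inverse interpolation (linear fallback) of the dense
  # solution; accuracy is set by the trajectory's age resolution
  inv <- tryCatch(stats::splinefun(ms[keep], traj$age[keep], method = "hyman"),
                  error = function(e)
                    function(x) stats::approx(ms[keep], traj$age[keep],
                                              xout = x)$y)
  t_at_fraction <- function(omega_U) {
    target <- omega_U * W_U
    if (any(target > max(ms) + 1e-9))
      stop(sprintf(paste("trajectory ends at %.4g mg, before the requested",
                         "mass fraction; integrate to a larger t_end"),
                   max(ms)), call. = FALSE)
    inv(target)
  }
  t95 <- t_at_fraction(0.95)
  structure(list(W_U = W_U, Wdot_max = opt$objective, W_star = opt$maximum,
                 W95 = 0.95 * W_U, t95 = t95,
                 omega_star = opt$maximum / W_U,
                 Omega = opt$objective / ((0.95 * W_U - W0) / t95),
                 W0 = W0, phi = phi, t_at_fraction = t_at_fraction),
            class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("Growth trajectory summary\n")
  cat(sprintf("  W_U   = %.6g mg    W95 = %.6g mg    t95 = %.6g days\n",
              x$W_U, x$W95, x$t95))
  cat(sprintf("  Wdot_max = %.6g mg/day at W* = %.6g mg\n", x$Wdot_max, x$W_star))
  cat(sprintf("  omega* = W*/W_U = %.4f    Omega = %.4f\n", x$omega_star, x$Omega))
  invisible(x)
}

#' Food-restriction scenario sweep
#'
#' Integrates and summarizes one trajectory per combination of fixed
#' relative food acquirement `phi` and defence reduction exponent `delta`,
#' tabulating `W_U`, `W95`, `t95` and ages at the requested mass fractions.
#' Failures in single cells (e.g. immediate decline at very low `phi`) are
#' recorded in the `error` column without aborting the sweep.
#'
#' @param model an [mgm_params()] object; its `delta` is overridden per row.
#' @param phi_grid relative food acquirements to sweep.
#' @param delta_grid defence reduction exponents to sweep.
#' @param W0 initial mass (mg).
#' @param t_end integration horizon (days); must be long enough to reach
#'   `W95` in every cell.
#' @param fractions mass fractions `omega_U` at which ages are reported.
#' @return a data frame with one row per `(delta, phi)`, sorted by `delta`
#'   then decreasing `phi`.
#' @export
food_restriction_sweep <- function(model, phi_grid, delta_grid = 1,
                                   W0 = 0.67, t_end = 600,
                                   fractions = c(0.5, 0.75, 0.9)) {
  stopifnot(inherits(model, "mgm_params"))
  grid <- expand.grid(phi = sort(phi_grid, decreasing = TRUE),
                      delta = sort(delta_grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    phi <- grid$phi[i]
    delta <- grid$delta[i]
    m <- model
    m$maintenance$delta <- delta
    res <- tryCatch({
      traj <- integrate_growth(m, W0 = W0, t_end = t_end, phi = phi)
      s <- summarize_trajectory(traj, m)
      c(list(phi = phi, delta = delta, W_U = s$W_U, W95 = s$W95, t95 = s$t95),
        stats::setNames(as.list(s$t_at_fraction(fractions)),
                        sprintf("t_at_%g", fractions)),
        list(error = NA_character_))
    }, error = function(e) {
      c(list(phi = phi, delta = delta, W_U = NA_real_, W95 = NA_real_,
             t95 = NA_real_),
        stats::setNames(as.list(rep(NA_real_, length(fractions))),
                        sprintf("t_at_%g", fractions)),
        list(error = conditionMessage(e)))
    })
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$delta, -out$phi), , drop = FALSE]
}

#' Energy-budget series along a trajectory
#'
#' Recomputes every budget term at each reported age: ingestion `S`,
#' assimilation `e S`, maintenance `R_M`, feeding `R_F`, growth overhead
#' `R_G = E_S dW/dt`, bound energy `G = E_M dW/dt`, and the closure residual
#' `e S - R_M - R_F - R_G - G` (zero up to floating-point error, since the
#' growth equation is an exact rearrangement of the balance). Ages with
#' non-positive bound-energy rate are flagged in `shrinking`.
#'
#' @param traj a [integrate_growth()] trajectory.
#' @param model the model parameters; defaults to those stored in `traj`.
#' @return a data frame with one row per age and a `rel_residual` column
#'   (residual relative to assimilated energy).
#' @export
energy_budget_series <- function(traj, model = attr(traj, "model")) {
  stopifnot(inherits(traj, "growth_trajectory"),
            inherits(model, "mgm_params"))
  phi_f <- .phi_fun(attr(traj, "phi"))
  phis <- vapply(traj$age, phi_f, numeric(1))
  W <- traj$mass
  out <- do.call(rbind, lapply(seq_along(W), function(i) {
    S <- ingestion_rate(phis[i], W[i], model$ingestion)
    EM <- energy_density_EM(W[i], model$composition)
    ES <- growth_overhead_ES(W[i], model$composition)
    RF <- feeding_cost(S, model$feeding)
    RM <- maintenance_cost(phis[i], W[i], model$maintenance,
                           p_R = model$composition$p_R(W[i]))
    dWdt <- (model$e * S - RF - RM) / (EM + ES)
    data.frame(age = traj$age[i], mass = W[i], phi = phis[i], S = S,
               assimilated = model$e * S, R_M = RM, R_F = RF,
               R_G = ES * dWdt, G = EM * dWdt, dWdt = dWdt)
  }))
  out$residual <- out$assimilated - out$R_M - out$R_F - out$R_G - out$G
  out$rel_residual <- out$residual / pmax(out$assimilated, .Machine$double.xmin)
  out$shrinking <- out$G <= 0
  out
}
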
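#' Generalized standard growth model (GSGM)
#'
#' The umbrella supply-minus-expenditure power law
#' `dW/dt = a W^b - c W^d` that subsumes the classical mechanistic growth
#' models (von Bertalanffy, ontogenetic growth model, standard DEB). Bounded
#' growth requires `0 < b < d`; `d` defaults to 1, the value that these
#' models share and that fits insect data best among d <= 1.
#'
#' @param a supply normalisation, > 0.
#' @param b supply allometric exponent.
#' @param c expenditure normalisation, > 0.
#' @param d expenditure exponent, in (b, 1].
#' @return an object of class `gsgm_params`.
#' @export
gsgm_params <- function(a, b, c, d = 1) {
  stopifnot(a > 0, c > 0, b > 0, b < d, d <= 1)
  structure(list(a = a, b = b, c = c, d = d), class = "gsgm_params")
}

#' GSGM growth rate
#'
#' @param W body mass (mg), > 0; may be a vector.
#' @param p a [gsgm_params()] object.
#' @return growth rate (mg/day).
#' @export
gsgm_rate <- function(W, p) {
  stopifnot(inherits(p, "gsgm_params"))
  if (any(W <= 0)) stop("body mass 'W' must be positive", call. = FALSE)
  p$a * W^p$b - p$c * W^p$d
}

#' @export
growth_rate.gsgm_params <- function(model, W, phi = 1, ...) gsgm_rate(W, model)

#' Ratio of mass at maximum growth to ultimate mass under GSGM
#'
#' For `dW/dt = a W^b - c W^d` the rate peaks at
#' `W* = (a b / (c d))^(1/(d-b))` while the ultimate mass is
#' `W_U = (a/c)^(1/(d-b))`, so the ratio is `(b/d)^(1/(d-b))` independent of
#' `a` and `c`. For `d = 1` this is `b^(1/(1-b))`, whose supremum over
#' `b` in (0, 1) is `1/e`: GSGM can never place the growth-rate peak beyond
#' about 37% of the ultimate mass, which is what excludes it for insects
#' with near-symmetric rate humps.
#'
#' @param b supply exponent, `0 < b < d`.
#' @param d expenditure exponent.
#' @return the dimensionless ratio `W*/W_U`.
#' @export
gsgm_omega_star <- function(b, d = 1) {
  if (any(b <= 0) || any(b >= d))
    stop("'b' must satisfy 0 < b < d", call. = FALSE)
  (b / d)^(1 / (d - b))
}

#' von Bertalanffy parameters
#'
#' `dW/dt = a W^beta - b W`, the reduced maintenance-growth model with
#' `b_N = 0` and fixed `phi`, where `a = (e - k_F) phi alpha / (E_M + E_S)`
#' and `b = gamma_B / ((E_M + E_S)(1 - a_N phi^delta))`.
#'
#' @param a supply normalisation, > 0.
#' @param b specific expenditure rate (1/day), > 0.
#' @param beta supply exponent, in (0, 1).
#' @return an object of class `vb_params`.
#' @export
vb_params <- function(a, b, beta = 2 / 3) {
  stopifnot(a > 0, b > 0, beta > 0, beta < 1)
  structure(list(a = a, b = b, beta = beta), class = "vb_params")
}

#' @export
growth_rate.vb_params <- function(model, W, phi = 1, ...) {
  if (any(W <= 0)) stop("body mass 'W' must be positive", call. = FALSE)
  model$a * W^model$beta - model$b * W
}

#' Closed-form von Bertalanffy trajectory
#'
#' The Bernoulli-equation solution of `dW/dt = a W^beta - b W`:
#' `W(t) = (a/b + (W0^(1-beta) - a/b) exp(-(1-beta) b t))^(1/(1-beta))`,
#' used as an analytic oracle for the integrator.
#'
#' @param t age(s) in days.
#' @param a,b rate constants (see [vb_params()]).
#' @param beta supply exponent in (0, 1); `beta = 1` is the degenerate
#'   exponential case and is rejected (solve `dW/dt = (a - b) W` directly).
#' @param W0 initial mass (mg).
#' @return mass(es) at `t` (mg).
#' @export
vb_closed_form <- function(t, a, b, beta, W0) {
  stopifnot(b > 0, W0 > 0)
  if (beta >= 1 || beta <= 0) {
    if (isTRUE(all.equal(beta, 1)))
      stop("beta = 1 is the degenerate exponential case W0 * exp((a - b) t)",
           call. = FALSE)
    stop("'beta' must lie in (0, 1)", call. = FALSE)
  }
  u <- 1 - beta
  (a / b + (W0^u - a / b) * exp(-u * b * t))^(1 / u)
}

#' Logistic comparator
#'
#' `dW/dt = r W (1 - W/K)`; its growth-rate curve is an exactly symmetric
#' parabola in `W`, peaking at `K/2`.
#'
#' @param r intrinsic rate (1/day), > 0.
#' @param K asymptotic mass (mg), > 0.
#' @return an object of class `logistic_params`.
#' @export
logistic_params <- function(r, K) {
  stopifnot(r > 0, K > 0)
  structure(list(r = r, K = K), class = "logistic_params")
}

#' Logistic growth rate
#'
#' @param W body mass (mg); may be a vector.
#' @param r intrinsic rate (1/day).
#' @param K asymptotic mass (mg).
#' @return growth rate (mg/day).
#' @export
logistic_rate <- function(W, r, K) {
  stopifnot(r > 0, K > 0)
  r * W * (1 - W / K)
}

#' @export
growth_rate.logistic_params <- function(model, W, phi = 1, ...) {
  if (any(W <= 0)) stop("body mass 'W' must be positive", call. = FALSE)
  logistic_rate(W, model$r, model$K)
}

# ---- model registry ---------------------------------------------------------

#' Registry of fittable growth models
#'
#' Named collection of rate models available to [fit_model()] and the
#' command line. Each entry supplies parameter names, default bounds as a
#' function of the data, a constructor from a named parameter vector,
#' starting-value scales, and a data-informed starting point (`smart_start`,
#' in the spirit of self-starting nonlinear models): the supply term is
#' anchored on the initial growth slope and the expenditure term on growth
#' stalling near the largest observed mass. Additional user models can be
#' appended via `extra` (a named list with the same fields).
#'
#' @param extra optional named list of additional model specifications.
#' @return a named list of model specifications
#'   (`MGM_eq33`, `GSGM`, `VB`, `logistic`, plus any extras).
#' @export
growth_model_registry <- function(extra = list()) {
  # initial specific slope of the data, for supply-anchored starts
  early_slope <- function(data) {
    s <- (data$mass[2L] - data$mass[1L]) / (data$age[2L] - data$age[1L])
    max(s, 1e-3 * max(data$mass) / max(data$age))
  }
  reg <- list(
    MGM_eq33 = list(
      par_names = c("a", "beta", "c", "a_N"),
      make = function(theta) mgm33_params(theta[["a"]], theta[["beta"]],
                                          theta[["c"]], theta[["a_N"]]),
      bounds = function(data) {
        Wmax <- max(data$mass)
        list(lower = c(a = 1e-4, beta = 0.4, c = 1e-6, a_N = 0),
             upper = c(a = 1e3, beta = 1.2, c = 1e3, a_N = 0.999 / Wmax))
      },
      smart_start = function(data) {
        Wmax <- max(data$mass)
        a <- early_slope(data) / data$mass[1L]^0.75
        a_N <- 0.5 / Wmax
        c(a = a, beta = 0.75, c = a * Wmax^(-0.25) * (1 - a_N * Wmax),
          a_N = a_N)
      },
      log_scale = c("a", "c")
    ),
    GSGM = list(
      par_names = c("a", "b", "c"),
      make = function(theta) gsgm_params(theta[["a"]], theta[["b"]],
                                         theta[["c"]], d = 1),
      bounds = function(data) {
        list(lower = c(a = 1e-4, b = 0.05, c = 1e-6),
             upper = c(a = 1e3, b = 0.995, c = 1e3))
      },
      smart_start = function(data) {
        Wmax <- max(data$mass)
        a <- early_slope(data) / data$mass[1L]^(2 / 3)
        c(a = a, b = 2 / 3, c = a * Wmax^(-1 / 3))
      },
      log_scale = c("a", "c")
    ),
    VB = list(
      par_names = c("a", "b", "beta"),
      make = function(theta) vb_params(theta[["a"]], theta[["b"]],
                                       theta[["beta"]]),
      bounds = function(data) {
        list(lower = c(a = 1e-4, b = 1e-6, beta = 0.4),
             upper = c(a = 1e3, b = 1e2, beta = 0.99))
      },
      smart_start = function(data) {
        Wmax <- max(data$mass)
        a <- early_slope(data) / data$mass[1L]^(2 / 3)
        c(a = a, b = a * Wmax^(-1 / 3), beta = 2 / 3)
      },
      log_scale = c("a", "b")
    ),
    logistic = list(
      par_names = c("r", "K"),
      make = function(theta) logistic_params(theta[["r"]], theta[["K"]]),
      bounds = function(data) {
        Wmax <- max(data$mass)
        list(lower = c(r = 1e-4, K = Wmax / 2),
             upper = c(r = 10, K = 10 * Wmax))
      },
      smart_start = function(data) {
        K <- 1.05 * max(data$mass)
        W1 <- data$mass[1L]
        c(r = early_slope(data) / (W1 * (1 - W1 / K)), K = K)
      },
      log_scale = "r"
    )
  )
  if (length(extra)) {
    stopifnot(!is.null(names(extra)), all(nzchar(names(extra))))
    reg[names(extra)] <- extra
  }
  reg
}
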
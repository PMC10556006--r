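#' Full maintenance-growth model parameter set
#'
#' Bundles the component parameter blocks with the assimilation efficiency
#' `e` into a complete model. The growth equation is
#' `dW/dt = [e S(phi, W) - R_F(S) - R_M(phi, W)] / (E_M(W) + E_S(W))`.
#' With constant composition it is the simplified one-tissue model, and with
#' `b_N = 0` and fixed `phi` it is a mechanistic von Bertalanffy equation.
#'
#' @param ingestion an [ingestion_params()] object.
#' @param composition a [composition_params()] object.
#' @param feeding a [feeding_params()] object.
#' @param maintenance a [maintenance_params()] object.
#' @param e assimilation efficiency, in (0, 1); must exceed `k_F`, otherwise
#'   the supply term `(e - k_F) phi alpha W^beta` can never be positive.
#' @return an object of class `mgm_params`.
#' @seealso [mgm_default_params()], [mgm33_params()], [growth_rate()]
#' @export
mgm_params <- function(ingestion, composition, feeding, maintenance, e = 0.7) {
  stopifnot(inherits(ingestion, "ingestion_params"),
            inherits(composition, "composition_params"),
            inherits(feeding, "feeding_params"),
            inherits(maintenance, "maintenance_params"),
            is.numeric(e), length(e) == 1L, e > 0, e < 1)
  if (is.null(feeding$cost_fn) && e - feeding$k_F <= 0)
    stop("'e - k_F' must be positive: assimilation cannot cover feeding costs",
         call. = FALSE)
  structure(list(ingestion = ingestion, composition = composition,
                 feeding = feeding, maintenance = maintenance, e = e),
            class = "mgm_params")
}

#' Package default parameter set
#'
#' A complete parameterisation calibrated to house-cricket-like growth:
#' hatchling mass around 0.67 mg, asymptotic mass around 410 mg reached
#' (95% level) after roughly 100 days ad libitum, a hump-shaped growth-rate
#' curve with its maximum near half the ultimate mass, and an ad-libitum
#' defence fraction of about 0.45 at the ultimate mass, which keeps the
#' restriction response monotone for `delta <= 1`.
#'
#' @param delta defence reduction exponent (default 1).
#' @param b_N relative defence allocation exponent (default 1); `a_N` is
#'   interpreted in mg^-b_N.
#' @param a_N defence-allocation normalisation.
#' @return an object of class `mgm_params`.
#' @export
mgm_default_params <- function(delta = 1, b_N = 1, a_N = 0.0011) {
  mgm_params(
    ingestion = ingestion_params(alpha = 4.5, beta = 0.75),
    composition = composition_params(),
    feeding = feeding_params(k_F = 0.1),
    maintenance = maintenance_params(gamma_BS = 0.33, a_NS = a_N, b_NS = b_N,
                                     delta = delta),
    e = 0.7
  )
}

#' Ad-libitum four-parameter growth model
#'
#' The reduced ad-libitum model with linear relative defence allocation
#' (`b_N = 1`): `dW/dt = a W^beta - c W / (1 - a_N W)`, where
#' `a = (e - k_F) alpha / (E_M + E_S)` and `c = gamma_B / (E_M + E_S)`.
#' This is the four-parameter form `(a, beta, c, a_N)` used when fitting the
#' model to averaged mass-at-age data.
#'
#' @param a supply normalisation (mg^(1-beta)/day), > 0.
#' @param beta supply allometric exponent.
#' @param c expenditure normalisation (1/day), >= 0.
#' @param a_N defence-allocation normalisation (1/mg), >= 0; masses must stay
#'   below `1/a_N`.
#' @return an object of class `mgm33_params`.
#' @export
mgm33_params <- function(a, beta, c, a_N) {
  stopifnot(a > 0, beta >= 0, beta < 1.5, c >= 0, a_N >= 0)
  structure(list(a = a, beta = beta, c = c, a_N = a_N), class = "mgm33_params")
}

#' Reduce a full parameter set to the ad-libitum four-parameter form
#'
#' Valid when composition is constant and `b_N = 1`; evaluates `E_M`, `E_S`
#' and `gamma_B` at the reference mass `W_ref`.
#'
#' @param p an [mgm_params()] object.
#' @param W_ref mass at which mass-dependent hooks are evaluated (mg).
#' @return an [mgm33_params()] object.
#' @export
as_mgm33 <- function(p, W_ref = 1) {
  stopifnot(inherits(p, "mgm_params"))
  if (p$maintenance$b_NS != 1)
    stop("the four-parameter reduction assumes b_N = 1", call. = FALSE)
  EMES <- energy_density_EM(W_ref, p$composition) +
    growth_overhead_ES(W_ref, p$composition)
  gB <- if (is.null(p$maintenance$gamma_BS_fn)) p$maintenance$gamma_BS
        else p$maintenance$gamma_BS_fn(W_ref)
  mgm33_params(a = (p$e - p$feeding$k_F) * p$ingestion$alpha / EMES,
               beta = p$ingestion$beta,
               c = gB / EMES,
               a_N = p$maintenance$a_NS)
}

#' @export
print.mgm_params <- function(x, ...) {
  cat("Maintenance-growth model parameters (mg, day, J)\n")
  cat(sprintf("  ingestion:   S_max = %g * W^%g%s\n", x$ingestion$alpha,
              x$ingestion$beta,
              if (is.finite(x$ingestion$W_break))
                sprintf(" up to W' = %g mg (%s)", x$ingestion$W_break,
                        x$ingestion$post_break_policy) else ""))
  cat(sprintf("  assimilation e = %g, feeding k_F = %s\n", x$e,
              if (is.null(x$feeding$cost_fn)) format(x$feeding$k_F)
              else "<custom cost function>"))
  m <- x$maintenance
  cat(sprintf("  maintenance: gamma_BS = %s, gamma_BR = %g J/mg/day\n",
              if (is.null(m$gamma_BS_fn)) format(m$gamma_BS) else "<fn(W)>",
              m$gamma_BR))
  cat(sprintf("  defence:     rho = a_N W^b_N phi^delta, a_N = %g, b_N = %g, delta = %g\n",
              m$a_NS, m$b_NS, m$delta))
  cat(sprintf("  composition: E_M(1 mg) = %g, E_S(1 mg) = %g J/mg\n",
              energy_density_EM(1, x$composition),
              growth_overhead_ES(1, x$composition)))
  invisible(x)
}

#' @export
print.mgm33_params <- function(x, ...) {
  cat(sprintf("Ad-libitum MGM: dW/dt = %g W^%g - %g W / (1 - %g W)\n",
              x$a, x$beta, x$c, x$a_N))
  invisible(x)
}

# ---- flat config round trip -------------------------------------------------

.config_keys <- c("alpha", "beta", "W_break", "post_break_policy",
                  "E_CP", "E_L", "E_MR", "E_SSD", "E_SSG", "E_SR",
                  "f_CP", "f_L", "f_R", "f_G", "p_R",
                  "k_F", "gamma_BS", "gamma_BR",
                  "a_NS", "a_NR", "b_NS", "b_NR", "delta", "e")

#' Read a model parameter set from a flat config file
#'
#' The file (YAML or JSON, chosen by extension) holds one key per parameter,
#' named after the model symbols (`alpha`, `beta`, `e`, `k_F`, `gamma_BS`,
#' `a_NS`, `b_NS`, `delta`, ...). Missing keys take the package defaults.
#' Only constant-valued parameters can be represented; function-valued hooks
#' (e.g. a mass-dependent `f_G`) must be set in code.
#'
#' @param path file path; `.yml`/`.yaml` parsed as YAML, `.json` as JSON.
#' @return an [mgm_params()] object.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  d <- mgm_default_params()
  g <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  mgm_params(
    ingestion = ingestion_params(
      alpha = g("alpha", d$ingestion$alpha), beta = g("beta", d$ingestion$beta),
      # "Inf" survives JSON only as a string; coerce back
      W_break = as.numeric(g("W_break", d$ingestion$W_break)),
      post_break_policy = g("post_break_policy", d$ingestion$post_break_policy)),
    composition = composition_params(
      E_CP = g("E_CP", d$composition$E_CP), E_L = g("E_L", d$composition$E_L),
      E_MR = g("E_MR", d$composition$E_MR), E_SSD = g("E_SSD", d$composition$E_SSD),
      E_SSG = g("E_SSG", d$composition$E_SSG), E_SR = g("E_SR", d$composition$E_SR),
      f_CP = g("f_CP", d$composition$f_CP(1)), f_L = g("f_L", d$composition$f_L(1)),
      f_R = g("f_R", d$composition$f_R(1)), f_G = g("f_G", d$composition$f_G(1)),
      p_R = g("p_R", d$composition$p_R(1))),
    feeding = feeding_params(k_F = g("k_F", d$feeding$k_F)),
    maintenance = maintenance_params(
      gamma_BS = g("gamma_BS", d$maintenance$gamma_BS),
      gamma_BR = g("gamma_BR", d$maintenance$gamma_BR),
      a_NS = g("a_NS", d$maintenance$a_NS), a_NR = g("a_NR", d$maintenance$a_NR),
      b_NS = g("b_NS", d$maintenance$b_NS), b_NR = g("b_NR", d$maintenance$b_NR),
      delta = g("delta", d$maintenance$delta)),
    e = g("e", d$e)
  )
}

#' Write a model parameter set to a flat config file
#'
#' Inverse of [read_model_config()]; the round trip is lossless for
#' constant-valued parameter sets. Function-valued hooks cannot be
#' serialised and raise an error.
#'
#' @param p an [mgm_params()] object.
#' @param path destination; format chosen by extension as in
#'   [read_model_config()].
#' @return `path`, invisibly.
#' @export
write_model_config <- function(p, path) {
  stopifnot(inherits(p, "mgm_params"))
  if (!is.null(p$feeding$cost_fn) || !is.null(p$maintenance$gamma_BS_fn))
    stop("function-valued hooks cannot be written to a flat config",
         call. = FALSE)
  comp <- p$composition
  const_at <- function(f, nm) {
    v <- f(c(1, 2, 5, 50, 500))
    if (diff(range(v)) > 0)
      stop(sprintf("mass-dependent '%s' cannot be written to a flat config", nm),
           call. = FALSE)
    v[1L]
  }
  cfg <- list(alpha = p$ingestion$alpha, beta = p$ingestion$beta,
              W_break = p$ingestion$W_break,
              post_break_policy = p$ingestion$post_break_policy,
              E_CP = comp$E_CP, E_L = comp$E_L, E_MR = comp$E_MR,
              E_SSD = comp$E_SSD, E_SSG = comp$E_SSG, E_SR = comp$E_SR,
              f_CP = const_at(comp$f_CP, "f_CP"), f_L = const_at(comp$f_L, "f_L"),
              f_R = const_at(comp$f_R, "f_R"), f_G = const_at(comp$f_G, "f_G"),
              p_R = const_at(comp$p_R, "p_R"),
              k_F = p$feeding$k_F,
              gamma_BS = p$maintenance$gamma_BS, gamma_BR = p$maintenance$gamma_BR,
              a_NS = p$maintenance$a_NS, a_NR = p$maintenance$a_NR,
              b_NS = p$maintenance$b_NS, b_NR = p$maintenance$b_NR,
              delta = p$maintenance$delta, e = p$e)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    # YAML has no native Inf literal that round-trips everywhere; use .inf
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
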
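#' @title Energy-budget component parameters
#'
#' @description Constructors for the parameter blocks of the
#' maintenance-growth model (MGM). Units are fixed package-wide: mass in mg,
#' time in days, energy in J. Rates are therefore J/day, mass-specific rates
#' J/mg/day and the ingestion normalisation `alpha` has units
#' J mg^-beta day^-1.
#'
#' @name mgm-components
NULL

# Coerce a constant or function-of-mass to function(W); hooks such as f_G(W)
# or gamma_BS(W) plug in here.
.as_mass_fn <- function(x, name) {
  if (is.function(x)) return(x)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar or a function of mass", name),
         call. = FALSE)
  force(x)
  function(W) rep_len(x, length(W))
}

.check_fraction <- function(x, name) {
  if (any(x < 0 | x > 1))
    stop(sprintf("'%s' must lie in [0, 1] (got %g)", name, x[which(x < 0 | x > 1)[1L]]),
         call. = FALSE)
  x
}

#' Ingestion parameters
#'
#' Maximum (ad libitum) ingestion rate is allometric, `S_max = alpha * W^beta`,
#' up to a body mass `W_break` where the allometry may cease to hold.
#'
#' @param alpha normalisation constant (J mg^-beta day^-1), > 0.
#' @param beta allometric exponent, in (0, 1.5].
#' @param W_break body mass (mg) above which the allometry potentially breaks;
#'   `Inf` (the default) keeps the power law throughout.
#' @param post_break_policy what happens above `W_break`: `"hold-allometry"`
#'   keeps `alpha * W^beta`; `"cap-at-break-value"` freezes ingestion at
#'   `alpha * W_break^beta`.
#' @return an object of class `ingestion_params`.
#' @export
ingestion_params <- function(alpha, beta, W_break = Inf,
                             post_break_policy = c("hold-allometry",
                                                   "cap-at-break-value")) {
  post_break_policy <- match.arg(post_break_policy)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(beta), length(beta) == 1L, beta > 0, beta <= 1.5,
            is.numeric(W_break), length(W_break) == 1L, W_break > 0)
  structure(list(alpha = alpha, beta = beta, W_break = W_break,
                 post_break_policy = post_break_policy),
            class = "ingestion_params")
}

#' Realised ingestion rate
#'
#' `S(phi, W) = phi * S_max(W)` where `phi` in \[0, 1\] is the relative food
#' acquirement (realised over ad-libitum ingestion at the current size).
#'
#' @param phi relative food acquirement, in \[0, 1\].
#' @param W body mass (mg), > 0; may be a vector.
#' @param p an [ingestion_params()] object.
#' @return ingestion rate (J/day), same length as `W`.
#' @export
ingestion_rate <- function(phi, W, p) {
  stopifnot(inherits(p, "ingestion_params"))
  if (any(!is.finite(W)) || any(W <= 0))
    stop("body mass 'W' must be positive and finite", call. = FALSE)
  if (length(phi) != 1L || !is.finite(phi) || phi < 0 || phi > 1)
    stop("'phi' must be a single value in [0, 1]", call. = FALSE)
  Weff <- if (p$post_break_policy == "cap-at-break-value") pmin(W, p$W_break) else W
  phi * p$alpha * Weff^p$beta
}

#' Tissue composition and synthesis-cost parameters
#'
#' Describes what newly synthesized tissue is made of and what it costs to
#' build. Somatic tissue is split into carbohydrate/protein (energy density
#' `E_CP`) and lipid (`E_L`) fractions; reproductive tissue has density
#' `E_MR`. Growth overheads distinguish somatic cell division (`E_SSD`),
#' somatic cell enlargement (`E_SSG`) and reproductive synthesis (`E_SR`).
#' All the fraction arguments accept either a constant or a function of body
#' mass, so ontogenetic change in composition or growth strategy can be
#' plugged in.
#'
#' @param E_CP,E_L energy density of carbohydrate/protein and lipid tissue
#'   (J/mg). Defaults 17 and 34 J/mg, the standard constants for animal
#'   tissue.
#' @param E_MR energy density of reproductive tissue (J/mg).
#' @param E_SSD,E_SSG,E_SR specific growth overhead for somatic cell
#'   division, somatic cell enlargement and reproductive tissue (J/mg).
#' @param f_CP,f_L fractions of somatic mass increase that are
#'   carbohydrate/protein and lipid (constants or functions of mass). The
#'   defaults (0.35 and 0.03) describe fresh (wet) tissue and give
#'   `E_M` close to the 7 J/mg typical of fresh animal tissue.
#' @param f_R fraction of total mass increase that is reproductive.
#' @param f_G fraction of somatic growth achieved by cell enlargement
#'   (rather than division).
#' @param p_R proportion of standing body mass that is reproductive tissue.
#' @return an object of class `composition_params`.
#' @export
composition_params <- function(E_CP = 17, E_L = 34, E_MR = 7,
                               E_SSD = 2, E_SSG = 2, E_SR = 2,
                               f_CP = 0.35, f_L = 0.03,
                               f_R = 0, f_G = 0.5, p_R = 0) {
  for (nm in c("E_CP", "E_L", "E_MR", "E_SSD", "E_SSG", "E_SR")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop(sprintf("energy density '%s' must be a nonnegative scalar", nm),
           call. = FALSE)
  }
  structure(list(E_CP = E_CP, E_L = E_L, E_MR = E_MR,
                 E_SSD = E_SSD, E_SSG = E_SSG, E_SR = E_SR,
                 f_CP = .as_mass_fn(f_CP, "f_CP"),
                 f_L = .as_mass_fn(f_L, "f_L"),
                 f_R = .as_mass_fn(f_R, "f_R"),
                 f_G = .as_mass_fn(f_G, "f_G"),
                 p_R = .as_mass_fn(p_R, "p_R")),
            class = "composition_params")
}

#' Energy density of newly synthesized tissue
#'
#' `E_M(W) = (E_CP f_CP + E_L f_L) (1 - f_R) + E_MR f_R`: the energy that
#' becomes bound per mg of new tissue, given its composition at mass `W`.
#'
#' @param W body mass (mg); may be a vector.
#' @param comp a [composition_params()] object.
#' @return energy density (J/mg).
#' @export
energy_density_EM <- function(W, comp) {
  stopifnot(inherits(comp, "composition_params"))
  f_CP <- .check_fraction(comp$f_CP(W), "f_CP")
  f_L <- .check_fraction(comp$f_L(W), "f_L")
  f_R <- .check_fraction(comp$f_R(W), "f_R")
  if (any(f_CP + f_L > 1 + 1e-12))
    stop("invalid composition: f_CP + f_L exceeds 1", call. = FALSE)
  (comp$E_CP * f_CP + comp$E_L * f_L) * (1 - f_R) + comp$E_MR * f_R
}

#' Specific growth overhead cost
#'
#' `E_S(W) = [E_SSD (1 - f_G) + E_SSG f_G] (1 - f_R) + E_SR f_R`: the
#' metabolic cost per mg of new tissue, over and above the energy bound in
#' it. Moulting costs, not modelled separately, can be folded into the
#' somatic overheads.
#'
#' @inheritParams energy_density_EM
#' @return overhead cost (J/mg).
#' @export
growth_overhead_ES <- function(W, comp) {
  stopifnot(inherits(comp, "composition_params"))
  f_G <- .check_fraction(comp$f_G(W), "f_G")
  f_R <- .check_fraction(comp$f_R(W), "f_R")
  (comp$E_SSD * (1 - f_G) + comp$E_SSG * f_G) * (1 - f_R) + comp$E_SR * f_R
}

#' Feeding-cost parameters
#'
#' Feeding costs (foraging plus digestion/assimilation) increase with the
#' ingestion rate. The default is the proportional form `R_F = k_F * S`;
#' `cost_fn` supplies an arbitrary monotone alternative, validated on a grid
#' at construction.
#'
#' @param k_F proportional feeding-cost coefficient, in \[0, 1).
#' @param cost_fn optional function of ingestion rate `S` (J/day) returning
#'   the feeding cost (J/day); must satisfy `cost_fn(0) == 0` and be
#'   non-decreasing on `validation_grid`.
#' @param validation_grid ingestion rates used to check monotonicity of
#'   `cost_fn`.
#' @return an object of class `feeding_params`.
#' @export
feeding_params <- function(k_F = 0.1, cost_fn = NULL,
                           validation_grid = seq(0, 1000, length.out = 101L)) {
  stopifnot(is.numeric(k_F), length(k_F) == 1L)
  if (is.null(cost_fn) && (k_F < 0 || k_F >= 1))
    stop("'k_F' must lie in [0, 1) for the proportional feeding-cost form",
         call. = FALSE)
  if (!is.null(cost_fn)) {
    stopifnot(is.function(cost_fn))
    v <- vapply(validation_grid, cost_fn, numeric(1))
    if (abs(v[1L]) > 1e-12 || any(diff(v) < -1e-12))
      stop(paste("custom feeding-cost function must vanish at S = 0 and be",
                 "non-decreasing on the validation grid"), call. = FALSE)
  }
  structure(list(k_F = k_F, cost_fn = cost_fn), class = "feeding_params")
}

#' Feeding cost at a given ingestion rate
#'
#' @param S ingestion rate (J/day), >= 0; may be a vector.
#' @param p a [feeding_params()] object.
#' @return feeding cost (J/day).
#' @export
feeding_cost <- function(S, p) {
  stopifnot(inherits(p, "feeding_params"))
  if (any(S < 0)) stop("ingestion rate 'S' must be nonnegative", call. = FALSE)
  if (is.null(p$cost_fn)) p$k_F * S else vapply(S, p$cost_fn, numeric(1))
}

#' Maintenance parameters
#'
#' Maintenance is the sum of a non-negotiable basal part, proportional to
#' tissue mass (`gamma_BS`, `gamma_BR` per mg of somatic and reproductive
#' tissue), and a negotiable "defence" part (immune function, buffering)
#' that makes up a fraction `rho` of total tissue maintenance. Under ad
#' libitum feeding the defence fraction scales allometrically with tissue
#' mass, `rho_N = a_N * W^b_N`, and it is downregulated under food
#' restriction as `rho = rho_N * phi^delta`.
#'
#' @param gamma_BS,gamma_BR specific basal maintenance of somatic and
#'   reproductive tissue (J/mg/day), > 0.
#' @param a_NS,a_NR defence-allocation normalisations (mg^-b_N), >= 0.
#' @param b_NS,b_NR relative defence allocation exponents (dimensionless);
#'   `b_N = 0` gives a mass-independent defence fraction (classical linear
#'   maintenance), `b_N > 0` gives hyperallometric maintenance.
#' @param delta defence reduction exponent (>= 0): how fast defence is shed
#'   as `phi` falls.
#' @param gamma_BS_fn optional function of body mass overriding `gamma_BS`,
#'   e.g. to express cell-size-dependent somatic maintenance.
#' @return an object of class `maintenance_params`.
#' @export
maintenance_params <- function(gamma_BS = 0.33, gamma_BR = gamma_BS,
                               a_NS = 0.0011, a_NR = a_NS,
                               b_NS = 1, b_NR = b_NS,
                               delta = 1, gamma_BS_fn = NULL) {
  stopifnot(gamma_BS > 0, gamma_BR > 0, a_NS >= 0, a_NR >= 0, delta >= 0)
  if (!is.null(gamma_BS_fn)) stopifnot(is.function(gamma_BS_fn))
  structure(list(gamma_BS = gamma_BS, gamma_BR = gamma_BR,
                 a_NS = a_NS, a_NR = a_NR, b_NS = b_NS, b_NR = b_NR,
                 delta = delta, gamma_BS_fn = gamma_BS_fn),
            class = "maintenance_params")
}

#' Negotiable (defence) maintenance fraction
#'
#' `rho(phi, W) = a_N * W^b_N * phi^delta`, the fraction of total tissue
#' maintenance allocated to negotiable processes. Values `>= 1` would make
#' maintenance diverge and raise an error rather than being clamped.
#'
#' @param phi relative food acquirement in \[0, 1\].
#' @param W_tissue tissue mass (mg), >= 0; may be a vector.
#' @param a_N normalisation (mg^-b_N).
#' @param b_N allometric exponent.
#' @param delta defence reduction exponent.
#' @return defence fraction(s) in \[0, 1).
#' @export
defence_fraction <- function(phi, W_tissue, a_N, b_N, delta) {
  if (length(phi) != 1L || !is.finite(phi) || phi < 0 || phi > 1)
    stop("'phi' must be a single value in [0, 1]", call. = FALSE)
  if (any(W_tissue < 0)) stop("tissue mass must be nonnegative", call. = FALSE)
  rho <- a_N * W_tissue^b_N * phi^delta
  if (any(rho >= 1)) {
    bad <- W_tissue[which(rho >= 1)[1L]]
    stop(sprintf(paste("defence fraction >= 1 at tissue mass %g mg:",
                       "maintenance would diverge"), bad), call. = FALSE)
  }
  rho
}

#' Total maintenance cost
#'
#' Two-tissue form
#' `R_M = gamma_BS W_S / (1 - rho_S) + gamma_BR W_R / (1 - rho_R)` with
#' `W_S = (1 - p_R) W`, `W_R = p_R W` and defence fractions from
#' [defence_fraction()]. When the two tissues share parameters, or
#' `p_R = 0`, this reduces exactly to the one-tissue form
#' `gamma_B W / (1 - a_N W^b_N phi^delta)`.
#'
#' @inheritParams defence_fraction
#' @param W body mass (mg), > 0; may be a vector.
#' @param m a [maintenance_params()] object.
#' @param p_R proportion of body mass that is reproductive tissue (scalar or
#'   vector matching `W`).
#' @return maintenance cost (J/day).
#' @export
maintenance_cost <- function(phi, W, m, p_R = 0) {
  stopifnot(inherits(m, "maintenance_params"))
  if (any(W <= 0)) stop("body mass 'W' must be positive", call. = FALSE)
  p_R <- .check_fraction(rep_len(p_R, length(W)), "p_R")
  W_S <- (1 - p_R) * W
  W_R <- p_R * W
  gBS <- if (is.null(m$gamma_BS_fn)) m$gamma_BS else m$gamma_BS_fn(W)
  rho_S <- defence_fraction(phi, W_S, m$a_NS, m$b_NS, m$delta)
  out <- gBS * W_S / (1 - rho_S)
  repro <- W_R > 0
  if (any(repro)) {
    rho_R <- defence_fraction(phi, W_R[repro], m$a_NR, m$b_NR, m$delta)
    out[repro] <- out[repro] + m$gamma_BR * W_R[repro] / (1 - rho_R)
  }
  out
}
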
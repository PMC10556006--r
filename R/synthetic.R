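#' Configuration for the synthetic cohort generator
#'
#' Describes a density-manipulation growth experiment to be emulated: a set
#' of starting densities whose competition for a fixed food ration is
#' summarised by a monotone non-increasing map from density to relative
#' food acquirement `phi`, hatchlings of about 0.67 mg weighed at regular
#' ages, multiplicative lognormal individual-scale and measurement
#' variation, optional mortality thinning, and maturation events.
#'
#' Defaults mirror the emulated experimental design: densities
#' 5, 10, 20, 40, 80; `phi(d) = log10(min d) / log10(d)` (the normalised
#' food availability of the lowest, near ad libitum, density); weekly
#' weighing for 18 weeks.
#'
#' @param true_params an [mgm_params()] object driving the deterministic
#'   growth curves.
#' @param densities starting densities (counts > 1).
#' @param n_cohorts replicate cohorts per density.
#' @param phi_of_density function mapping density to `phi` in (0, 1\];
#'   must be non-increasing over `densities`.
#' @param W0_mean mean hatchling mass (mg).
#' @param individual_cv coefficient of variation of the lognormal
#'   individual scale factor (applied to the whole trajectory).
#' @param measurement_cv coefficient of variation of multiplicative
#'   lognormal measurement noise per weighing.
#' @param sampling_ages weighing ages (days).
#' @param mortality_rate per-day mortality hazard (0 disables thinning).
#' @param maturation_fraction individuals mature on reaching this fraction
#'   of the density-specific asymptotic mass (imago emergence near the
#'   growth plateau); ignored when `maturation_mass` is given.
#' @param maturation_mass optional absolute maturation threshold (mg).
#' @param seed integer seed; identical configurations generate identical
#'   tables.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(true_params = mgm_default_params(),
                             densities = c(5, 10, 20, 40, 80),
                             n_cohorts = 1L,
                             phi_of_density = NULL,
                             W0_mean = 0.67,
                             individual_cv = 0.1,
                             measurement_cv = 0.05,
                             sampling_ages = seq(0, 126, by = 7),
                             mortality_rate = 0,
                             maturation_fraction = 0.9,
                             maturation_mass = NULL,
                             seed = 1L) {
  stopifnot(inherits(true_params, "mgm_params"),
            all(densities > 1), n_cohorts >= 1L,
            W0_mean > 0, individual_cv >= 0, measurement_cv >= 0,
            length(sampling_ages) >= 2L, all(diff(sampling_ages) > 0),
            mortality_rate >= 0,
            maturation_fraction > 0, maturation_fraction <= 1)
  if (is.null(phi_of_density)) {
    dmin <- min(densities)
    phi_of_density <- function(d) log10(dmin) / log10(d)
  }
  phis <- vapply(densities[order(densities)], phi_of_density, numeric(1))
  if (any(is.na(phis)) || any(phis <= 0) || any(phis > 1))
    stop("phi_of_density must map every density into (0, 1]", call. = FALSE)
  if (any(diff(phis) > 1e-12))
    stop("phi_of_density must be non-increasing in density", call. = FALSE)
  structure(list(true_params = true_params, densities = densities,
                 n_cohorts = as.integer(n_cohorts),
                 phi_of_density = phi_of_density, W0_mean = W0_mean,
                 individual_cv = individual_cv,
                 measurement_cv = measurement_cv,
                 sampling_ages = sampling_ages,
                 mortality_rate = mortality_rate,
                 maturation_fraction = maturation_fraction,
                 maturation_mass = maturation_mass,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# lognormal with mean 1 and coefficient of variation cv
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic cohort table
#'
#' For each density the deterministic growth curve at `phi(density)` is
#' integrated once; each individual then receives a lognormal scale factor
#' (mean 1, cv `individual_cv`) multiplying the whole curve, multiplicative
#' measurement noise at each weighing, optional exponential mortality
#' thinning, and a maturation record when crossing the maturation
#' threshold (the maturation age is jittered by the same individual cv).
#' Sexes are assigned at random with equal probability.
#'
#' @param cfg a [synthetic_config()] object.
#' @return a cohort data frame (see [read_cohort_csv()] for the schema).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  ages <- cfg$sampling_ages
  t_end <- max(ages)
  rows <- list()
  for (d in sort(cfg$densities)) {
    phi <- cfg$phi_of_density(d)
    dense_ages <- sort(unique(c(ages, seq(0, t_end, length.out = 2001L))))
    traj <- integrate_growth(cfg$true_params, W0 = cfg$W0_mean,
                             t_end = t_end, phi = phi, ages = dense_ages)
    base_mass <- stats::approx(traj$age, traj$mass, xout = ages)$y
    thr <- if (!is.null(cfg$maturation_mass)) cfg$maturation_mass else {
      W_U <- ultimate_mass(cfg$true_params, phi = phi, W0 = cfg$W0_mean)
      cfg$maturation_fraction * W_U
    }
    mat_age_base <- if (max(traj$mass) >= thr)
      stats::approx(traj$mass, traj$age, xout = thr, ties = "ordered")$y
    else NA_real_
    sl_age <- sqrt(log(1 + cfg$individual_cv^2))
    for (coh in seq_len(cfg$n_cohorts)) {
      cohort_id <- sprintf("d%g_c%d", d, coh)
      for (i in seq_len(d)) {
        scale <- .rlnorm_cv(1L, cfg$individual_cv)
        death <- if (cfg$mortality_rate > 0)
          stats::rexp(1L, cfg$mortality_rate) else Inf
        keep <- ages < death | ages == ages[1L]  # hatchlings always weighed once
        obs_ages <- ages[keep]
        noise <- .rlnorm_cv(length(obs_ages), cfg$measurement_cv)
        masses <- scale * base_mass[keep] * noise
        sex <- sample(c("F", "M"), 1L)
        matured <- FALSE
        mat_age <- NA_real_
        mat_mass <- NA_real_
        if (is.finite(mat_age_base)) {
          mat_age <- mat_age_base * exp(stats::rnorm(1L, 0, sl_age))
          if (mat_age < min(death, t_end)) {
            matured <- TRUE
            mat_mass <- scale *
              stats::approx(traj$age, traj$mass, xout = mat_age)$y
          } else {
            mat_age <- NA_real_
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cohort_id = cohort_id, starting_density = d,
          individual_id = sprintf("%s_i%02d", cohort_id, i),
          age = obs_ages, mass = masses, sex = sex, matured = matured,
          maturation_age = mat_age, maturation_mass = mat_mass,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .validate_cohort(out)
}
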
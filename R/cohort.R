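#' Cohort mass-at-age tables
#'
#' Individual-level records from a density-manipulation growth experiment:
#' one row per (individual, weighing age), with the cohort it belongs to,
#' the cohort's starting density, and optional sex and maturation
#' information. Read and written as plain CSV (header row, '.' decimal).
#'
#' Required columns: `cohort_id`, `starting_density`, `individual_id`,
#' `age` (days), `mass` (mg). Optional: `sex` ("F"/"M"), `matured`
#' (logical), `maturation_age` (days), `maturation_mass` (mg).
#'
#' @param path CSV file path.
#' @return a validated cohort data frame.
#' @name cohort-io
NULL

.validate_cohort <- function(tab) {
  req <- c("cohort_id", "starting_density", "individual_id", "age", "mass")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("cohort table lacks required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$mass <= 0)) stop("cohort masses must be positive", call. = FALSE)
  if (any(tab$age < 0)) stop("cohort ages must be nonnegative", call. = FALSE)
  tab
}

#' @rdname cohort-io
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_cohort(tab)
}

#' @rdname cohort-io
#' @param table a cohort data frame.
#' @export
write_cohort_csv <- function(table, path) {
  .validate_cohort(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average cohort masses by density and age
#'
#' For every starting density, the mean body mass at each weighing age over
#' all individuals in all cohorts of that density (a pooled mean across
#' replicate cohorts, not a mean of cohort means). Densities with fewer than
#' two distinct ages are skipped with a warning.
#'
#' @param table a cohort data frame (see [read_cohort_csv()]).
#' @return a data frame with columns `starting_density`, `age`, `mean_mass`
#'   and `n` (individuals averaged), ordered by density then age.
#' @export
average_cohort <- function(table) {
  .validate_cohort(table)
  out <- stats::aggregate(mass ~ starting_density + age, data = table,
                          FUN = mean)
  names(out)[names(out) == "mass"] <- "mean_mass"
  cnt <- stats::aggregate(mass ~ starting_density + age, data = table,
                          FUN = length)
  out$n <- cnt$mass
  keep <- stats::ave(out$age, out$starting_density,
                     FUN = function(a) length(unique(a)))
  if (any(keep < 2)) {
    warning("skipping densities with fewer than two distinct ages: ",
            paste(unique(out$starting_density[keep < 2]), collapse = ", "),
            call. = FALSE)
    out <- out[keep >= 2, , drop = FALSE]
  }
  out <- out[order(out$starting_density, out$age), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Growth rates from difference ratios
#'
#' Forward-difference ratios of a mass-at-age series give rates at interval
#' midpoints; linear interpolation maps them back to the observation ages,
#' with one-sided (nearest-midpoint) values at the two endpoints.
#'
#' @param age strictly increasing ages (days), length >= 3.
#' @param mass masses at those ages (mg).
#' @return rates (mg/day) at the observation ages.
#' @export
diff_ratio_rates <- function(age, mass) {
  if (length(age) < 3L) stop("at least three ages are required", call. = FALSE)
  if (anyDuplicated(age) || any(diff(age) <= 0))
    stop("ages must be strictly increasing without duplicates", call. = FALSE)
  mid_rate <- diff(mass) / diff(age)
  mid_age <- (age[-1L] + age[-length(age)]) / 2
  stats::approx(mid_age, mid_rate, xout = age, rule = 2)$y
}

#' Attach difference-ratio rates to averaged cohort data
#'
#' Applies [diff_ratio_rates()] within each starting density of an
#' [average_cohort()] table.
#'
#' @param avg an [average_cohort()] result.
#' @return `avg` with an additional `rate` column (mg/day).
#' @export
rates_from_differences <- function(avg) {
  stopifnot(all(c("starting_density", "age", "mean_mass") %in% names(avg)))
  parts <- split(avg, avg$starting_density)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$age), , drop = FALSE]
    d$rate <- diff_ratio_rates(d$age, d$mean_mass)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Quadratic smoothing of the growth-rate-vs-mass curve
#'
#' Least-squares degree-2 polynomial of growth rate on body mass. For
#' concave fits the vertex provides the maximum growth rate `Wdot_max` and
#' the mass `W_star` where it occurs; concave-up fits, or vertices outside
#' the observed mass range, are flagged with a warning.
#'
#' @param mass body masses (mg), >= 3 distinct values.
#' @param rate growth rates (mg/day) at those masses.
#' @return an object of class `rate_quadratic`: list with `coef`
#'   (intercept, linear, quadratic), `W_star`, `Wdot_max`, `concave` and
#'   `vertex_in_range`.
#' @export
smooth_rate_curve <- function(mass, rate) {
  stopifnot(length(mass) == length(rate))
  if (length(unique(mass)) < 3L)
    stop("at least three distinct masses are required", call. = FALSE)
  X <- cbind(1, mass, mass^2)
  if (qr(X)$rank < 3L) stop("rank-deficient quadratic design", call. = FALSE)
  cf <- stats::coef(stats::lm(rate ~ mass + I(mass^2)))
  names(cf) <- c("c0", "c1", "c2")
  concave <- cf[["c2"]] < 0
  if (!concave) {
    warning("quadratic fit is concave-up: no interior maximum", call. = FALSE)
    W_star <- NA_real_
    Wdot_max <- NA_real_
    in_range <- NA
  } else {
    W_star <- -cf[["c1"]] / (2 * cf[["c2"]])
    Wdot_max <- cf[["c0"]] + cf[["c1"]] * W_star + cf[["c2"]] * W_star^2
    in_range <- W_star >= min(mass) && W_star <= max(mass)
    if (!in_range)
      warning("quadratic vertex lies outside the observed mass range",
              call. = FALSE)
  }
  structure(list(coef = cf, W_star = W_star, Wdot_max = Wdot_max,
                 concave = concave, vertex_in_range = in_range),
            class = "rate_quadratic")
}

#' @export
print.rate_quadratic <- function(x, ...) {
  cat(sprintf("Quadratic rate curve: %.6g + %.6g W + %.6g W^2\n",
              x$coef[["c0"]], x$coef[["c1"]], x$coef[["c2"]]))
  if (isTRUE(x$concave))
    cat(sprintf("  Wdot_max = %.6g mg/day at W* = %.6g mg\n",
                x$Wdot_max, x$W_star))
  else cat("  concave-up: no interior maximum\n")
  invisible(x)
}

#' Smooth growth curve implied by a quadratic rate curve
#'
#' Integrates `dW/dt = q(W)` from `W0`, where `q` is a fitted quadratic
#' rate-vs-mass curve. The ultimate mass is the upper positive root of `q`
#' and ages at mass fractions are obtained by inverse interpolation of the
#' dense solution; `t95` is the age at `0.95 W_U`.
#'
#' @param q a [smooth_rate_curve()] fit (or a numeric vector of three
#'   quadratic coefficients, constant term first).
#' @param W0 initial mass (mg); must lie below the upper root.
#' @param n_ages number of output ages.
#' @return a list with `curve` (data frame of `age`, `mass`), `W_U`, `t95`
#'   and `t_at_fraction` (function of the mass fraction).
#' @export
smooth_growth_curve <- function(q, W0, n_ages = 2001L) {
  cf <- if (inherits(q, "rate_quadratic")) q$coef else q
  stopifnot(length(cf) == 3L, W0 > 0)
  qfun <- function(W) cf[[1L]] + cf[[2L]] * W + cf[[3L]] * W^2
  roots <- sort(Re(polyroot(cf)[abs(Im(polyroot(cf))) < 1e-8]))
  roots <- roots[roots > W0 * (1 + 1e-9)]
  if (!length(roots) || qfun(W0) <= 0)
    stop("quadratic rate curve has no positive root above W0: no implied W_U",
         call. = FALSE)
  W_U <- roots[1L]
  if ((W_U - W0) / W_U < 1e-9)
    stop("degenerate curve: W_U coincides with W0", call. = FALSE)
  # horizon: expand until 99.9% of W_U is passed
  t_end <- 10 / max(abs(cf[[2L]]), 1e-12)
  for (k in seq_len(60L)) {
    sol <- deSolve::lsoda(c(W = W0), seq(0, t_end, length.out = n_ages),
                          function(t, y, parms)
                            list(if (y[[1L]] >= W_U) 0 else qfun(y[[1L]])),
                          parms = NULL, rtol = 1e-9, atol = 1e-12)
    if (max(sol[, 2L]) >= 0.999 * W_U) break
    t_end <- t_end * 2
    if (k == 60L) stop("failed to approach W_U within the horizon", call. = FALSE)
  }
  curve <- data.frame(age = sol[, 1L], mass = sol[, 2L])
  t_at_fraction <- function(omega_U)
    stats::approx(curve$mass, curve$age, xout = omega_U * W_U,
                  ties = "ordered")$y
  list(curve = curve, W_U = W_U, t95 = t_at_fraction(0.95),
       t_at_fraction = t_at_fraction)
}

#' Normalised food availability from starting densities
#'
#' `min(log10(d)) / log10(d_i)`: a between-zero-and-one measure of food
#' availability implied by the initial cohort size, equal to 1 at the lowest
#' (near ad libitum) density.
#'
#' @param densities starting densities (counts), all > 1.
#' @return fractions in (0, 1].
#' @export
normalized_food_availability <- function(densities) {
  if (any(densities <= 1))
    stop("densities must exceed 1 (log10 must be positive)", call. = FALSE)
  min(log10(densities)) / log10(densities)
}

#' Mean age and mass at maturation by density and sex
#'
#' Group means of maturation age and mass over matured individuals, per
#' (starting density, sex); sexes are never pooled. Groups without matured
#' individuals are omitted with a warning.
#'
#' @param table a cohort data frame with `matured`, `maturation_age`,
#'   `maturation_mass` and `sex` columns.
#' @return a data frame with columns `starting_density`, `sex`,
#'   `mean_maturation_age`, `mean_maturation_mass` and `n`, ordered by
#'   density for plotting restriction arrows.
#' @export
maturation_summary <- function(table) {
  .validate_cohort(table)
  need <- c("matured", "maturation_age", "maturation_mass", "sex")
  if (!all(need %in% names(table)))
    stop("maturation columns are missing: ",
         paste(setdiff(need, names(table)), collapse = ", "), call. = FALSE)
  # one record per individual
  ind <- table[!duplicated(table[c("cohort_id", "individual_id")]),
               c("starting_density", "cohort_id", "individual_id", "sex",
                 "matured", "maturation_age", "maturation_mass")]
  groups <- unique(ind[c("starting_density", "sex")])
  mat <- ind[isTRUE_v(ind$matured), , drop = FALSE]
  if (!nrow(mat)) stop("no matured individuals in the table", call. = FALSE)
  agg_age <- stats::aggregate(maturation_age ~ starting_density + sex,
                              data = mat, FUN = mean)
  agg_mass <- stats::aggregate(maturation_mass ~ starting_density + sex,
                               data = mat, FUN = mean)
  agg_n <- stats::aggregate(individual_id ~ starting_density + sex,
                            data = mat, FUN = length)
  out <- merge(merge(agg_age, agg_mass), agg_n)
  names(out) <- c("starting_density", "sex", "mean_maturation_age",
                  "mean_maturation_mass", "n")
  dropped <- nrow(groups) - nrow(out)
  if (dropped > 0)
    warning(sprintf("%d density-sex group(s) had no matured individuals and were omitted",
                    dropped), call. = FALSE)
  out <- out[order(out$starting_density, out$sex), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorised isTRUE for optional logical columns possibly holding NA
isTRUE_v <- function(x) !is.na(x) & x
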
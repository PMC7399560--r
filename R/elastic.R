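# Frank twist elastic modulus K2, chiral strength kt, equilibrium pitch
# and the chiral pair potential of mean force.
#
# In the laboratory frame the reference nematic director is n = e_x and
# the helical axis e_z. At second-virial level,
#   beta K2 = (rho^2/2) int dr12 dR1 dR2 f-bar psi'(x1) psi'(x2) rz^2 u1y u2y
#   beta kt = (rho^2/2) int dr12 dR1 dR2 f-bar psi(x1) psi'(x2) rz u2y
# with x_i = u_i . e_x and psi' the derivative with respect to cos theta.
# With orientations sampled uniformly on the rotation group and psi
# normalized to unit integral over d cos theta, the estimator carries a
# factor (8 pi^2 / 4 pi^2)^2 = 4 relative to the raw sample mean. The
# equilibrium cholesteric pitch is P = 2 pi K2 / kt, signed: P > 0 means a
# right-handed phase.

# Lookup tables on a fine uniform cos-theta grid: psi (normalized), its
# logarithmic derivative g\'(x) = psi-dot / psi obtained analytically by
# differentiating the fixed-point relation psi = exp(g)/Z through the
# splined exponent (chain rule; far more robust to grid noise than
# differencing psi), and the inverse CDF used to importance-sample
# orientations from psi.
psi_tables <- function(kernel, odf, n_grid = 2001L, n_quantiles = 4097L) {
  gsp <- kernel_exponent_spline(kernel, odf$psi, odf$rho)
  xg <- seq(-1, 1, length.out = n_grid)
  g <- gsp(xg)
  psi <- exp(g - max(g))
  psi <- psi / (sum(psi) * (xg[2] - xg[1]))
  gprime <- gsp(xg, deriv = 1)
  cdf <- cumsum(psi) * (xg[2] - xg[1])
  cdf <- (cdf - cdf[1]) / (cdf[n_grid] - cdf[1])
  uq <- seq(0, 1, length.out = n_quantiles)
  invcdf <- stats::approx(cdf, xg, xout = uq, ties = "ordered",
                          rule = 2)$y
  list(x = xg, psi = psi, gprime = gprime, invcdf = invcdf)
}

# mirror image of a packed body (reflection through the body xy plane)
mirror_body <- function(b) {
  b$sites[, 3] <- -b$sites[, 3]
  b$segc[, 3] <- -b$segc[, 3]
  b
}

#' Twist elastic modulus and chiral strength by Monte Carlo integration
#'
#' Estimates K2 (kT/nm) and kt (kT/nm^2) at the state point of the
#' supplied orientation distribution, with conformational averaging inside
#' the integrand (each sample draws an independent conformation pair).
#' Standard errors come from batch means.
#'
#' @param ensemble a `conformation_ensemble` or [spherocylinder()].
#' @param model an [interaction_model()].
#' @param odf a converged `orientation_distribution` (its `rho` sets the
#'   density).
#' @param kernel the `virial_kernel` used to converge `odf` (needed for
#'   the analytic psi derivative).
#' @param mc_budget Monte Carlo samples.
#' @param seed RNG seed.
#' @param n_batches batches for the error estimate.
#' @param r_max sampling radius (default from circumscribing radii).
#' @param trim_bp end planes dropped for body frames.
#' @param antithetic evaluate every sample against the mirror-image
#'   ensemble as well (common random numbers): the chiral strength keeps
#'   the parity-odd half of the Mayer function, which removes the
#'   dominant achiral noise from kt at twice the cost per sample.
#' @return an object of class `elastic_constants`: `K2`, `kt`, standard
#'   errors, the state point, and sampling metadata.
#' @export
elastic_constants <- function(ensemble, model = interaction_model(), odf,
                              kernel, mc_budget = 1e6, seed = 1L,
                              n_batches = 32L, r_max = NULL, trim_bp = 10L,
                              antithetic = TRUE) {
  stopifnot(inherits(odf, "orientation_distribution"))
  prep <- prepare_bodies(ensemble, trim_bp)
  mp <- model_pars(model, prep)
  r_max <- r_max %||% (2 * prep$radius + mp$cutoff)
  tb <- psi_tables(kernel, odf)
  bodies_m <- if (antithetic && !prep$sph)
    lapply(prep$bodies, mirror_body) else list()
  set.seed(seed)
  res <- cpp_elastic_mc(prep$bodies, bodies_m,
                        isTRUE(antithetic) && !prep$sph, mp$d0, mp$pref,
                        mp$lambda, mp$cutoff, tb$invcdf, tb$gprime,
                        mc_budget, as.integer(n_batches), r_max, prep$sph,
                        prep$L, prep$D)
  rho <- odf$rho
  scale <- rho^2 / 2
  structure(list(
    K2 = scale * res$I_k2, K2_se = scale * res$I_k2_se,
    kt = scale * res$I_kt, kt_se = scale * res$I_kt_se,
    rho = rho, r_max = r_max, mc_budget = res$n, seed = seed,
    mode = if (prep$sph) "spherocylinder" else "sites"
  ), class = "elastic_constants")
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat("<elastic_constants>\n")
  cat(sprintf("  K2 = %.4g +/- %.2g kT/nm\n", x$K2, x$K2_se))
  cat(sprintf("  kt = %.4g +/- %.2g kT/nm^2\n", x$kt, x$kt_se))
  invisible(x)
}

#' Equilibrium cholesteric pitch
#'
#' P = 2 pi K2 / kt, reported in um with the Monte Carlo error
#' propagated. Positive pitch = right-handed phase. When kt is within one
#' standard error of zero the system is flagged achiral-within-error and
#' the pitch reported as unwound (infinite).
#'
#' @param elastic an `elastic_constants` object (or K2 value).
#' @param kt chiral strength, if `elastic` is given as a bare K2 value.
#' @param K2_se,kt_se optional errors for the bare-value form.
#' @return an object of class `cholesteric_solution` with `pitch_um`,
#'   `pitch_se_um`, `inverse_pitch_um`, and flags.
#' @export
pitch <- function(elastic, kt = NULL, K2_se = 0, kt_se = 0) {
  if (inherits(elastic, "elastic_constants")) {
    K2 <- elastic$K2; kt <- elastic$kt
    K2_se <- elastic$K2_se; kt_se <- elastic$kt_se
    rho <- elastic$rho
  } else {
    K2 <- elastic; rho <- NA_real_
  }
  achiral <- is.finite(kt_se) && kt_se > 0 && abs(kt) < kt_se
  unwound <- kt == 0 || achiral
  P_nm <- if (kt == 0) Inf else 2 * pi * K2 / kt
  rel <- if (kt == 0) NA_real_ else
    sqrt((K2_se / K2)^2 + (kt_se / kt)^2)
  structure(list(
    pitch_um = P_nm * 1e-3,
    pitch_se_um = abs(P_nm) * rel * 1e-3,
    inverse_pitch_um = if (is.finite(P_nm)) 1e3 / P_nm else 0,
    K2 = K2, kt = kt, K2_se = K2_se, kt_se = kt_se, rho = rho,
    achiral_within_error = achiral, unwound = unwound
  ), class = "cholesteric_solution")
}

#' @export
print.cholesteric_solution <- function(x, ...) {
  cat("<cholesteric_solution>\n")
  if (x$unwound) {
    cat("  unwound (kt indistinguishable from 0",
        if (x$achiral_within_error) " within MC error", ")\n", sep = "")
  } else {
    cat(sprintf("  P = %.4g +/- %.2g um (%s-handed)\n", x$pitch_um,
                x$pitch_se_um, if (x$pitch_um > 0) "right" else "left"))
  }
  invisible(x)
}

#' Chiral pair potential of mean force versus interaxial angle
#'
#' For each angle gamma, both particles lie with their long axes in the
#' xy plane, separated along e_z, with axis 2 rotated by gamma about e_z
#' relative to axis 1 (gamma > 0 = right-handed pair arrangement). The
#' conformationally averaged pair free energy is
#' W(gamma) = -ln < exp(-beta U) >, averaged over separations (uniform up
#' to `d_max`), spins about each long axis, and conformation pairs;
#' reported relative to gamma = 0. The minimizing gamma* gives the
#' preferred pair handedness.
#'
#' @param ensemble a `conformation_ensemble` or [spherocylinder()].
#' @param model an [interaction_model()].
#' @param gamma_grid angles in degrees, spanning [-90, 90]; 0 is added if
#'   absent.
#' @param mc_budget samples per angle.
#' @param seed RNG seed.
#' @param d_max maximum center separation along e_z (default: sum of the
#'   transverse extents plus the cutoff).
#' @param trim_bp end planes dropped for body frames.
#' @return an object of class `chiral_pmf`: data.frame `gamma_deg`, `W`
#'   (kT, zero at gamma = 0), `se`, plus `gamma_star`.
#' @export
chiral_pmf <- function(ensemble, model = interaction_model(),
                       gamma_grid = seq(-90, 90, by = 7.5), mc_budget = 2e5,
                       seed = 1L, d_max = NULL, trim_bp = 10L) {
  if (!any(gamma_grid == 0)) gamma_grid <- sort(c(0, gamma_grid))
  prep <- prepare_bodies(ensemble, trim_bp)
  mp <- model_pars(model, prep)
  if (is.null(d_max)) {
    if (prep$sph) d_max <- prep$D + mp$cutoff
    else {
      ext <- max(vapply(prep$bodies, function(b) b$rp, numeric(1)))
      d_max <- 2 * ext + mp$cutoff
    }
  }
  res <- lapply(seq_along(gamma_grid), function(i) {
    set.seed(derive_seed(seed, i))
    cpp_pmf_gamma(prep$bodies, mp$d0, mp$pref, mp$lambda,
                  mp$cutoff, gamma_grid[i] * pi / 180, d_max, mc_budget,
                  prep$sph, prep$L, prep$D)
  })
  mw <- vapply(res, `[[`, numeric(1), "mean_weight")
  sw <- vapply(res, `[[`, numeric(1), "se")
  if (any(mw <= 0))
    stop("mc_budget too small: zero Boltzmann weight at gamma = ",
         paste(gamma_grid[mw <= 0], collapse = ", "), " deg")
  W <- -log(mw)
  W0 <- W[gamma_grid == 0]
  out <- data.frame(gamma_deg = gamma_grid, W = W - W0, se = sw / mw)
  structure(list(curve = out,
                 gamma_star = gamma_grid[which.min(out$W)],
                 d_max = d_max, mc_budget = mc_budget, seed = seed),
            class = "chiral_pmf")
}

#' @export
print.chiral_pmf <- function(x, ...) {
  cat("<chiral_pmf> ", nrow(x$curve), " angles, gamma* = ", x$gamma_star,
      " deg\n", sep = "")
  invisible(x)
}

#' Bootstrap dispersion of the pitch
#'
#' Repeats the kernel -> orientation distribution -> elastic constants ->
#' pitch chain on bootstrap resamples of the conformational ensemble and
#' reports the relative dispersion of the pitch across runs, with a
#' pass/fail flag against `threshold` (convergence check for the Monte
#' Carlo stage).
#'
#' @param ensemble a `conformation_ensemble`.
#' @param model an [interaction_model()].
#' @param rho state-point number density (1/nm^3).
#' @param n_runs number of bootstrap runs.
#' @param mc_budget samples per kernel / elastic estimate.
#' @param seed RNG seed.
#' @param n_bins kernel bins.
#' @param threshold relative-dispersion pass threshold.
#' @param trim_bp end planes dropped.
#' @return an object of class `pitch_bootstrap`: per-run pitches,
#'   `dispersion` (sd / |mean|), and `pass`.
#' @export
bootstrap_pitch <- function(ensemble, model = interaction_model(), rho,
                            n_runs = 16L, mc_budget = 2e5, seed = 1L,
                            n_bins = 20L, threshold = 0.1, trim_bp = 10L) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  pitches <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, 100 + r))
    idx <- sample.int(ensemble$count, ensemble$count, replace = TRUE)
    ens_b <- conformation_ensemble(ensemble$conformations[idx],
                                   provenance = list(bootstrap_of = seed,
                                                     run = r))
    kr <- virial_kernel(ens_b, model, n_bins = n_bins, mc_budget = mc_budget,
                        seed = derive_seed(seed, 200 + r), trim_bp = trim_bp)
    od <- solve_odf(kr, rho)
    el <- elastic_constants(ens_b, model, od, kr, mc_budget = mc_budget,
                            seed = derive_seed(seed, 300 + r),
                            trim_bp = trim_bp)
    pitches[r] <- pitch(el)$pitch_um
  }
  disp <- stats::sd(pitches) / abs(mean(pitches))
  structure(list(pitches_um = pitches, dispersion = disp,
                 pass = is.finite(disp) && disp < threshold,
                 threshold = threshold, n_runs = n_runs),
            class = "pitch_bootstrap")
}

#' @export
print.pitch_bootstrap <- function(x, ...) {
  cat(sprintf("<pitch_bootstrap> %d runs, dispersion %.1f%% (threshold %.0f%%): %s\n",
              x$n_runs, 100 * x$dispersion, 100 * x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
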
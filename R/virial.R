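# Second-virial kernel: the conformationally averaged Mayer function
# integrated over separations and azimuthal/spin orientations, binned by
# the polar angles of the two molecular long axes to the nematic director.
#
# Convention: psi(cos theta) is normalized to unit integral over d cos
# theta (isotropic state = 1/2), and kappa(theta, theta') is the
# azimuth/spin-conditional average of integral dr12 f-bar, in nm^3. With
# these choices the self-consistency equation reads
# psi = exp(rho * integral psi kappa) / Z, with no residual angular
# normalization factors; the convention is validated against the classical
# hard-rod coexistence solution.

#' Monte Carlo estimate of the second-virial kernel
#'
#' Samples center separations uniformly in a ball of radius `r_max`
#' (adapted to the circumscribing radii plus the interaction cutoff),
#' orientations uniformly over the rotation group, and conformation pairs
#' uniformly from the ensemble; the Mayer function is accumulated in
#' `n_bins` x `n_bins` bins of (cos theta1, cos theta2).
#'
#' @param ensemble a `conformation_ensemble` or a [spherocylinder()].
#' @param model an [interaction_model()] (ignored for spherocylinders).
#' @param n_bins number of cos-theta bins (>= 20).
#' @param mc_budget number of Monte Carlo samples.
#' @param seed RNG seed.
#' @param r_max sampling radius (nm); default = sum of the circumscribing
#'   radii plus the cutoff.
#' @param trim_bp end planes dropped for body frames.
#' @return an object of class `virial_kernel`: `kappa` (nm^3, negative for
#'   repulsive interactions), `se`, `count`, bin centers `x`, quadrature
#'   weights `w`, and sampling metadata.
#' @export
virial_kernel <- function(ensemble, model = interaction_model(),
                          n_bins = 20L, mc_budget = 1e6, seed = 1L,
                          r_max = NULL, trim_bp = 10L) {
  if (n_bins < 20) stop("theta grid needs >= 20 nodes")
  prep <- prepare_bodies(ensemble, trim_bp)
  mp <- model_pars(model, prep)
  r_max <- r_max %||% (2 * prep$radius + mp$cutoff)
  set.seed(seed)
  res <- cpp_virial_kernel(prep$bodies, mp$d0, mp$pref,
                           mp$lambda, mp$cutoff, as.integer(n_bins),
                           mc_budget, r_max, prep$sph, prep$L, prep$D)
  if (anyNA(res$kappa)) {
    empty <- which(is.na(res$kappa), arr.ind = TRUE)
    stop("mc_budget too small: ", nrow(empty), " empty (cos theta) bins, ",
         "first at bin (", empty[1, 1], ", ", empty[1, 2], ")")
  }
  dx <- 2 / n_bins
  structure(list(
    kappa = res$kappa, se = res$se, count = res$count,
    x = -1 + dx * (seq_len(n_bins) - 0.5), w = rep(dx, n_bins),
    r_max = r_max, volume = res$volume, mc_budget = mc_budget, seed = seed,
    mode = if (prep$sph) "spherocylinder" else "sites", exact = FALSE
  ), class = "virial_kernel")
}

#' @export
print.virial_kernel <- function(x, ...) {
  cat("<virial_kernel> ", length(x$x), "x", length(x$x), " grid, mode '",
      x$mode, "'", if (x$exact) " (exact)", "\n", sep = "")
  cat(sprintf("  kappa range [%.3g, %.3g] nm^3; mean |SE| %.3g\n",
              min(x$kappa), max(x$kappa), mean(abs(x$se))))
  invisible(x)
}

#' Closed-form hard-rod kernel (Onsager reference)
#'
#' The azimuth-averaged excluded-volume kernel of hard spherocylinders,
#' kappa(theta, theta') = -(1/2 pi) integral d phi v_excl(gamma), with
#' cos gamma = cos theta cos theta' + sin theta sin theta' cos phi; the
#' independent analytic counterpart of [virial_kernel()] used to validate
#' the Monte Carlo machinery and the coexistence solver against classical
#' hard-rod results.
#'
#' @param length,diameter spherocylinder dimensions (nm).
#' @param n_nodes number of Gauss-Legendre nodes in cos theta.
#' @param include_end_terms include the 2 pi L D^2 + (4/3) pi D^3 cap
#'   terms (drop them for the needle limit).
#' @param n_phi azimuthal quadrature points.
#' @return a `virial_kernel` with `exact = TRUE`.
#' @export
onsager_rod_kernel <- function(length, diameter, n_nodes = 48L,
                               include_end_terms = TRUE, n_phi = 512L) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  x <- gl$x
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  K <- matrix(0, n_nodes, n_nodes)
  for (a in seq_len(n_nodes)) {
    sa <- sqrt(1 - x[a]^2)
    for (b in a:n_nodes) {
      cg <- x[a] * x[b] + sa * sqrt(1 - x[b]^2) * cos(phi)
      sg <- sqrt(pmax(1 - cg^2, 0))
      v <- 2 * length^2 * diameter * sg
      if (include_end_terms)
        v <- v + 2 * pi * length * diameter^2 + 4 / 3 * pi * diameter^3
      K[a, b] <- K[b, a] <- -mean(v)
    }
  }
  structure(list(
    kappa = K, se = matrix(0, n_nodes, n_nodes), count = NULL,
    x = x, w = gl$w, r_max = NA, volume = NA, mc_budget = NA, seed = NA,
    mode = "spherocylinder_analytic", exact = TRUE,
    length = length, diameter = diameter
  ), class = "virial_kernel")
}

# kernel row interpolated at arbitrary cos theta (natural cubic spline in
# the first argument, used for the analytic psi-dot construction)
kernel_exponent_spline <- function(kernel, psi_vals, rho) {
  g_nodes <- rho * as.vector(kernel$kappa %*% (kernel$w * psi_vals))
  stats::splinefun(kernel$x, g_nodes, method = "natural")
}
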
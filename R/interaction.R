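# Pair interaction model: hard-core sites plus screened Debye-Huckel
# electrostatics with a per-nucleotide effective charge. Energies are in kT.

#' Debye screening length of a 1:1 electrolyte
#'
#' lambda_D = sqrt(eps0 eps_r kB T / (2 NA e^2 I)) with ionic strength
#' I = c_salt for a monovalent salt. At 0.26 M and 293 K this is about
#' 0.6 nm, the experimental screening length of origami liquid-crystal
#' assays; 0.5 M is the typical simulation setting.
#'
#' @param c_salt monovalent salt concentration, mol/L.
#' @param temperature K.
#' @param relative_permittivity of the solvent (water near 293 K: ~80).
#' @return screening length in nm.
#' @export
debye_length <- function(c_salt, temperature = 293,
                         relative_permittivity = 80.1) {
  stopifnot(c_salt > 0)
  ionic <- c_salt * 1000 * .const$avogadro  # ions per m^3 (each of the two species)
  lam <- sqrt(.const$eps0 * relative_permittivity * .const$kB * temperature /
                (2 * .const$e^2 * ionic))
  lam * 1e9
}

#' Bjerrum length
#'
#' e^2 / (4 pi eps0 eps_r kB T), the distance at which two unit charges
#' interact with thermal energy kT.
#'
#' @inheritParams debye_length
#' @return Bjerrum length in nm.
#' @export
bjerrum_length <- function(temperature = 293, relative_permittivity = 80.1) {
  .const$e^2 / (4 * pi * .const$eps0 * relative_permittivity *
                  .const$kB * temperature) * 1e9
}

#' Site-site interaction model
#'
#' Hard spheres of diameter `site_diameter` per nucleotide site plus a
#' screened-Coulomb tail beta U = q^2 lB exp(-r / lambda_D) / r truncated
#' at `cutoff`. The effective per-site charge is the main fidelity knob of
#' the electrostatic stand-in and is deliberately exposed.
#'
#' @param site_diameter hard-core diameter, nm.
#' @param site_charge effective charge per nucleotide, units of e.
#' @param c_salt monovalent salt, mol/L (experimental assays: 0.26).
#' @param temperature K.
#' @param relative_permittivity solvent permittivity.
#' @param debye_length_nm override for the screening length (computed from
#'   the salt when NULL).
#' @param cutoff electrostatic cutoff, nm (>= 3 lambda_D; default 4).
#' @return an object of class `interaction_model`.
#' @export
interaction_model <- function(site_diameter = 0.7, site_charge = 0.5,
                              c_salt = 0.26, temperature = 293,
                              relative_permittivity = 80.1,
                              debye_length_nm = NULL, cutoff = NULL) {
  lam <- debye_length_nm %||%
    debye_length(c_salt, temperature, relative_permittivity)
  cutoff <- cutoff %||% max(4 * lam, site_diameter * 1.5)
  if (cutoff < 3 * lam)
    stop("cutoff must be at least 3 Debye lengths")
  structure(list(
    site_diameter = site_diameter,
    site_charge = site_charge,
    c_salt = c_salt,
    temperature = temperature,
    relative_permittivity = relative_permittivity,
    debye_length = lam,
    bjerrum_length = bjerrum_length(temperature, relative_permittivity),
    cutoff = cutoff,
    prefactor = site_charge^2 *
      bjerrum_length(temperature, relative_permittivity)  # kT nm
  ), class = "interaction_model")
}

#' Hard steric-only model
#'
#' Convenience constructor for pure excluded-volume interactions (no
#' electrostatics), used for the steric branches of pitch curves.
#'
#' @param site_diameter hard-core diameter, nm.
#' @return an `interaction_model` with zero charge.
#' @export
steric_model <- function(site_diameter = 0.7) {
  interaction_model(site_diameter = site_diameter, site_charge = 0,
                    debye_length_nm = 1, cutoff = 3)
}

#' @export
print.interaction_model <- function(x, ...) {
  cat("<interaction_model>\n")
  cat(sprintf("  hard core d0 = %.2f nm, q_eff = %.2f e\n",
              x$site_diameter, x$site_charge))
  cat(sprintf("  lambda_D = %.3f nm (c_salt = %.2f M, T = %g K), cutoff = %.2f nm\n",
              x$debye_length, x$c_salt, x$temperature, x$cutoff))
  invisible(x)
}

#' Hard spherocylinder reference particle
#'
#' An exact hard spherocylinder (cylinder length `length`, diameter
#' `diameter`, hemispherical caps) whose pair overlap is decided by the
#' closed-form segment-segment distance. It is the analytically solvable
#' reference particle of classical Onsager theory: its excluded volume
#' 2 L^2 D sin(gamma) + 2 pi L D^2 + (4/3) pi D^3 validates the Monte
#' Carlo virial machinery, and it is achiral, so its chiral strength must
#' vanish. Accepted everywhere a `conformation_ensemble` is.
#'
#' @param length cylindrical length L, nm.
#' @param diameter D, nm.
#' @return an object of class `spherocylinder`.
#' @export
spherocylinder <- function(length, diameter) {
  stopifnot(length > 0, diameter > 0)
  structure(list(length = length, diameter = diameter, count = 1L),
            class = "spherocylinder")
}

#' @export
print.spherocylinder <- function(x, ...) {
  cat(sprintf("<spherocylinder> L = %g nm, D = %g nm (L/D = %.2f)\n",
              x$length, x$diameter, x$length / x$diameter))
  invisible(x)
}

#' Excluded volume of two hard spherocylinders at fixed interaxial angle
#'
#' @param gamma interaxial angle, radians.
#' @param length,diameter spherocylinder dimensions, nm.
#' @return excluded volume in nm^3.
#' @export
spherocylinder_excluded_volume <- function(gamma, length, diameter) {
  2 * length^2 * diameter * abs(sin(gamma)) +
    2 * pi * length * diameter^2 + 4 / 3 * pi * diameter^3
}

# --- body-frame preparation -------------------------------------------------

#' Molecular body frame and body coordinates of a conformation
#'
#' Rotates all nucleotide sites into the principal frame of the backbone
#' gyration tensor (body x-axis = long axis u) with the backbone center of
#' mass at the origin; the representation used by all virial-stage Monte
#' Carlo sampling.
#'
#' @param conformation a `filament_conformation`.
#' @param trim_bp end planes dropped when computing the frame.
#' @return n x 3 matrix of body coordinates with the frame in attributes.
#' @export
body_frame_sites <- function(conformation, trim_bp = 10L) {
  bb0 <- extract_backbone(conformation, trim_bp = trim_bp)
  # recover the pre-centering backbone center of mass
  planes <- rowsum(conformation$positions,
                   group = conformation$bp_index)
  cnt <- table(conformation$bp_index)
  com <- colMeans(planes / as.vector(cnt))
  fr <- gyration_frame(bb0)
  R <- cbind(fr$u, fr$v, fr$w)
  X <- sweep(conformation$positions, 2, com) %*% R
  attr(X, "frame") <- fr
  attr(X, "com") <- com
  X
}

# Pack one conformation for the Monte Carlo core: body-frame sites ordered
# by bp plane, a bounding capsule (axial half-length, radial extent), and
# bounding spheres over short contour segments (the culling hierarchy that
# replaces a cell list for thin filaments).
body_pack <- function(conformation, trim_bp = 10L, planes_per_segment = 5L) {
  X <- body_frame_sites(conformation, trim_bp = trim_bp)
  attributes(X)[c("frame", "com")] <- NULL
  ord <- order(conformation$bp_index, conformation$duplex_id,
               conformation$strand_id)
  X <- X[ord, , drop = FALSE]
  bp <- conformation$bp_index[ord]
  planes <- sort(unique(bp))
  n_seg <- max(1L, ceiling(length(planes) / planes_per_segment))
  seg_of_plane <- rep(seq_len(n_seg), each = planes_per_segment,
                      length.out = length(planes))
  seg <- seg_of_plane[match(bp, planes)]
  s0 <- integer(n_seg); s1 <- integer(n_seg)
  segc <- matrix(0, n_seg, 3); segr <- numeric(n_seg)
  for (k in seq_len(n_seg)) {
    idx <- which(seg == k)
    s0[k] <- idx[1] - 1L; s1[k] <- idx[length(idx)]
    segc[k, ] <- colMeans(X[idx, , drop = FALSE])
    segr[k] <- sqrt(max(rowSums(sweep(X[idx, , drop = FALSE], 2,
                                      segc[k, ])^2)))
  }
  list(sites = X, segc = segc, segr = segr, s0 = s0, s1 = s1,
       hl = max(abs(X[, 1])), rp = sqrt(max(X[, 2]^2 + X[, 3]^2)))
}

# list of packed bodies for an ensemble (or a spherocylinder descriptor)
prepare_bodies <- function(ensemble, trim_bp = 10L) {
  if (inherits(ensemble, "spherocylinder"))
    return(list(sph = TRUE, L = ensemble$length, D = ensemble$diameter,
                bodies = list(),
                radius = ensemble$length / 2 + ensemble$diameter / 2))
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  bodies <- lapply(ensemble$conformations, body_pack, trim_bp = trim_bp)
  radius <- max(vapply(bodies, function(b)
    sqrt(max(rowSums(b$sites^2))), numeric(1)))
  list(sph = FALSE, L = 0, D = 0, bodies = bodies, radius = radius)
}

model_pars <- function(model, prep) {
  if (prep$sph) list(d0 = 0, pref = 0, lambda = 1, cutoff = 0)
  else list(d0 = model$site_diameter, pref = model$prefactor,
            lambda = model$debye_length, cutoff = model$cutoff)
}

#' Pair interaction energy of two conformations
#'
#' Energy (kT) of conformation `conf_a` held in orientation `R1` at the
#' origin and `conf_b` in orientation `R2` at center-of-mass separation
#' `r12`: the sum over inter-filament site pairs of the hard-core plus
#' screened-Coulomb model (infinite on overlap). Cell-list acceleration
#' engages automatically for large site counts.
#'
#' @param conf_a,conf_b `filament_conformation` objects, or a
#'   `spherocylinder` for both.
#' @param r12 length-3 center separation (nm).
#' @param R1,R2 3x3 rotation matrices applied to the body frames.
#' @param model an `interaction_model`.
#' @param trim_bp end planes dropped for the body frame.
#' @return energy in kT (`Inf` on hard overlap).
#' @export
pair_energy <- function(conf_a, conf_b, r12, R1 = diag(3), R2 = diag(3),
                        model = interaction_model(), trim_bp = 10L) {
  if (inherits(conf_a, "spherocylinder")) {
    u1 <- R1[, 1]; u2 <- R2[, 1]
    d <- segment_pair_distance(c(0, 0, 0), u1, conf_a$length,
                               r12, u2, conf_b$length)
    return(if (d < (conf_a$diameter + conf_b$diameter) / 2) Inf else 0)
  }
  cpp_pair_energy(body_pack(conf_a, trim_bp), body_pack(conf_b, trim_bp),
                  as.numeric(r12), R1, R2, model$site_diameter,
                  model$prefactor, model$debye_length, model$cutoff)
}

# R-level segment-segment distance (mirror of the C++ routine, for the
# spherocylinder path of pair_energy)
segment_pair_distance <- function(c1, u1, L1, c2, u2, L2) {
  p1 <- c1 - L1 / 2 * u1; d1 <- L1 * u1
  p2 <- c2 - L2 / 2 * u2; d2 <- L2 * u2
  r <- p1 - p2
  a <- sum(d1^2); e <- sum(d2^2); f <- sum(d2 * r)
  cc <- sum(d1 * r); b <- sum(d1 * d2)
  den <- a * e - b^2
  s <- if (den > 1e-14 * a * e) (b * f - cc * e) / den else 0
  s <- min(max(s, 0), 1)
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
  else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
  sqrt(sum((r + s * d1 - t * d2)^2))
}

#' Conformationally averaged Mayer function at a fixed pair configuration
#'
#' Estimates f-bar(r12, R1, R2) = <<exp(-beta U) - 1>> by uniform random
#' draws of conformation pairs from the ensemble. Bounded in [-1, 0] for
#' purely repulsive interactions.
#'
#' @param ensemble a `conformation_ensemble` (or `spherocylinder`).
#' @param r12 center separation (nm).
#' @param R1,R2 orientations.
#' @param model an `interaction_model`.
#' @param n_samples number of conformation-pair draws.
#' @param seed optional RNG seed.
#' @param trim_bp end planes dropped for body frames.
#' @return list with `mean` and `se`.
#' @export
mayer_average <- function(ensemble, r12, R1 = diag(3), R2 = diag(3),
                          model = interaction_model(), n_samples = 100L,
                          seed = NULL, trim_bp = 10L) {
  if (!is.null(seed)) set.seed(seed)
  prep <- prepare_bodies(ensemble, trim_bp)
  mp <- model_pars(model, prep)
  cpp_mayer_average(prep$bodies, as.numeric(r12), R1, R2,
                    mp$d0, mp$pref, mp$lambda, mp$cutoff,
                    as.integer(n_samples), prep$sph, prep$L, prep$D)
}
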
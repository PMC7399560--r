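# Synthetic conformation generator.
#
# Stands in for molecular-dynamics sampling of six-helix-bundle origami
# filaments: a discrete wormlike chain supplies the backbone bending
# statistics, an optional intrinsic curvature/torsion pair supplies a
# solenoidal (super-helical) bias, and the bundle decoration winds six
# duplexes (two strands each) around the centerline at a prescribed helical
# repeat and axial twist. The designed duplex overtwist is partitioned
# between residual duplex twist and backbone writhe through an explicit
# twist-writhe conversion rule, emulating the linking balance that origami
# crossovers enforce.

#' Wormlike-chain parameters for the backbone sampler
#'
#' @param contour_length l_c in nm (default 420, a six-helix bundle design).
#' @param segment_length discretization step in nm.
#' @param persistence_length l_p in nm; the default gives l_p/l_c = 8.
#' @param intrinsic_curvature kappa0 in 1/nm (solenoidal ground state).
#' @param intrinsic_torsion tau0 in 1/nm; positive = right-handed solenoid.
#' @param axial_twist_rate designed rotation of the bundle cross section
#'   about the centerline, in turns/um (signed, + = right-handed).
#' @param seed integer seed recorded in provenance.
#' @return an object of class `chain_parameters`.
#' @export
chain_parameters <- function(contour_length = 420, segment_length = 0.34,
                             persistence_length = 8 * 420,
                             intrinsic_curvature = 0, intrinsic_torsion = 0,
                             axial_twist_rate = 0, seed = 1L) {
  n_seg <- round(contour_length / segment_length)
  if (persistence_length <= 0) stop("persistence_length must be positive")
  if (segment_length <= 0 || segment_length >= contour_length)
    stop("segment_length must satisfy 0 < segment_length << contour_length")
  if (n_seg < 10) stop("discretization too coarse: need >= 10 segments")
  structure(list(
    contour_length = contour_length,
    segment_length = segment_length,
    persistence_length = persistence_length,
    intrinsic_curvature = intrinsic_curvature,
    intrinsic_torsion = intrinsic_torsion,
    axial_twist_rate = axial_twist_rate,
    seed = as.integer(seed),
    n_segments = n_seg
  ), class = "chain_parameters")
}

#' Six-helix bundle cross-section geometry
#'
#' Defaults place the six duplex axes on a hexagon of radius 2 nm with the
#' strands 1 nm off each duplex axis, so the bundle circumscribes the stated
#' 6 nm diameter; duplexes are wound at the relaxed B-DNA repeat of 10.5 bp
#' per turn with a 0.34 nm/bp rise.
#'
#' @param n_duplex number of duplexes (6).
#' @param hex_radius duplex-axis distance from the centerline, nm.
#' @param duplex_radius strand distance from the duplex axis, nm.
#' @param rise nm per base pair.
#' @param bp_per_turn helical repeat in bp/turn.
#' @param bp_count number of bp planes along each duplex.
#' @param diameter bundle diameter sigma, nm.
#' @return an object of class `bundle_geometry`.
#' @export
bundle_geometry <- function(n_duplex = 6L, hex_radius = 2.0,
                            duplex_radius = 1.0, rise = 0.34,
                            bp_per_turn = 10.5, bp_count = 1235L,
                            diameter = 6) {
  if (2 * (hex_radius + duplex_radius) > 1.1 * diameter)
    stop("geometry violates the bundle envelope: 2*(hex_radius + duplex_radius)",
         " must not exceed the diameter by more than 10%")
  g <- structure(list(
    n_duplex = as.integer(n_duplex), hex_radius = hex_radius,
    duplex_radius = duplex_radius, rise = rise, bp_per_turn = bp_per_turn,
    bp_count = as.integer(bp_count), diameter = diameter,
    duplex_twist_density = 1 / (bp_per_turn * rise)  # turns/nm, built winding
  ), class = "bundle_geometry")
  g
}

#' Designed overtwist and its twist-writhe partition
#'
#' `design_overtwist` is the duplex overtwist the design would carry if the
#' filament were held straight and untwisted (set by the crossover spacing:
#' deletions overwind, insertions underwind). In thermal ensembles part of
#' this stress is absorbed by solenoidal backbone writhe of the same sign;
#' the `thermal` partition rule converts a fraction `partition_fraction` of
#' the designed overtwist into a solenoidal bias of the centerline, using
#' `twist_writhe_conversion` (turns/um of relieved overtwist per turns/um of
#' centerline writhe density) as the coupling constant.
#'
#' @param design_overtwist turns/um if held straight and untwisted.
#' @param partition_fraction fraction of the designed overtwist absorbed by
#'   writhe in the generated ensembles.
#' @param twist_writhe_conversion dimensionless conversion between writhe
#'   density and relieved overtwist density.
#' @param bias_mode `"fixed"` (same solenoidal bias for every conformation)
#'   or `"none"` (no bias; the designed overtwist stays in the duplexes).
#' @param solenoid_turns number of solenoid turns over the contour used to
#'   realize the bias (long-wavelength mode).
#' @return an object of class `linking_target`.
#' @export
linking_target <- function(design_overtwist = 0, partition_fraction = 0.5,
                           twist_writhe_conversion = 100,
                           bias_mode = c("fixed", "none"),
                           solenoid_turns = 1) {
  structure(list(
    design_overtwist = design_overtwist,
    partition_fraction = partition_fraction,
    twist_writhe_conversion = twist_writhe_conversion,
    bias_mode = match.arg(bias_mode),
    solenoid_turns = solenoid_turns
  ), class = "linking_target")
}

#' Curvature/torsion of an ideal solenoid with a prescribed writhe density
#'
#' For a circular helix of `m` turns over contour `l_c` and pitch angle
#' alpha (angle between tangent and long axis), the local polar writhe
#' density is m (1 - cos alpha) / l_c; inverting this fixes alpha, and the
#' Frenet relations then give kappa0 = 2 pi m sin(alpha) / l_c and
#' tau0 = +/- 2 pi m cos(alpha) / l_c (sign = handedness).
#'
#' @param writhe_density signed target writhe density, turns/nm.
#' @param contour_length l_c in nm.
#' @param m number of solenoid turns over the contour.
#' @return list with `kappa0`, `tau0` (1/nm) and `pitch_angle` (radians).
#' @export
solenoid_bias <- function(writhe_density, contour_length, m = 2) {
  x <- abs(writhe_density) * contour_length / m
  if (x >= 1) stop("target writhe density too large for ", m, " solenoid turns")
  alpha <- acos(1 - x)
  s <- if (writhe_density >= 0) 1 else -1
  list(kappa0 = 2 * pi * m * sin(alpha) / contour_length,
       tau0 = s * 2 * pi * m * cos(alpha) / contour_length,
       pitch_angle = alpha)
}

# Propagate an orthonormal frame along given tangents by parallel transport
# (minimal rotation between consecutive tangents; no spurious twist).
transport_frames <- function(tangents, m1_init = NULL) {
  n <- nrow(tangents)
  m1 <- matrix(0, n, 3); m2 <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  if (is.null(m1_init)) {
    ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    m1_init <- unit3(cross3(ref, t1))
  }
  m1[1, ] <- m1_init
  m2[1, ] <- cross3(t1, m1[1, ])
  for (j in seq_len(n - 1)) {
    a <- tangents[j, ]; b <- tangents[j + 1, ]
    ax <- cross3(a, b)
    s <- sqrt(sum(ax^2)); c0 <- sum(a * b)
    if (s < 1e-14) {
      m1[j + 1, ] <- m1[j, ]; m2[j + 1, ] <- m2[j, ]
    } else {
      R <- rotation_about(ax, atan2(s, c0))
      m1[j + 1, ] <- drop(R %*% m1[j, ])
      m2[j + 1, ] <- drop(R %*% m2[j, ])
    }
  }
  list(m1 = m1, m2 = m2)
}

#' Sample a wormlike-chain centerline with material frame
#'
#' Discrete chain of fixed segment length. Each successive tangent is tilted
#' by a polar angle drawn from the exact wormlike-chain distribution
#' p(cos beta) proportional to exp((l_p / ds) cos beta) (azimuth uniform),
#' after an optional deterministic rotation encoding intrinsic curvature and
#' torsion (a helical ground state when both are nonzero). The material
#' frame is propagated with the same rotations, so it is twist-free
#' (parallel-transported) up to the intrinsic torsion.
#'
#' @param params a [chain_parameters()] object.
#' @return an object of class `centerline`: node `positions`
#'   ((n_segments + 1) x 3, nm), per-segment `tangents`, frame vectors `m1`,
#'   `m2`, midpoint abscissas `s_mid`, step `ds`, and the end-to-end unit
#'   vector `u_e2e`.
#' @export
sample_centerline <- function(params) {
  stopifnot(inherits(params, "chain_parameters"))
  n <- params$n_segments
  ds <- params$contour_length / n
  k <- params$persistence_length / ds
  if (k < 1) stop("discretization too coarse: l_p / segment_length < 1")

  thermal <- k < 1e5  # treat effectively rigid chains exactly as rigid
  kap <- params$intrinsic_curvature
  tau <- params$intrinsic_torsion
  om <- sqrt(kap^2 + tau^2)

  tg <- matrix(0, n, 3); m1 <- matrix(0, n, 3); m2 <- matrix(0, n, 3)
  tg[1, ] <- c(0, 0, 1); m1[1, ] <- c(1, 0, 0); m2[1, ] <- c(0, 1, 0)

  if (thermal) {
    u <- stats::runif(n)
    # inverse CDF of p(x) ~ exp(k x) on [-1, 1]
    cb <- 1 + log(u + (1 - u) * exp(-2 * k)) / k
    cb <- pmax(pmin(cb, 1), -1)
    zeta <- stats::runif(n, 0, 2 * pi)
    beta <- acos(cb)
  } else {
    beta <- numeric(n); zeta <- numeric(n)
  }

  for (j in seq_len(n - 1)) {
    t0 <- tg[j, ]; a1 <- m1[j, ]; a2 <- m2[j, ]
    if (om > 0) {  # intrinsic curvature kappa about m2-axis + torsion about t
      R <- rotation_about(tau * t0 + kap * a2, om * ds)
      t0 <- drop(R %*% t0); a1 <- drop(R %*% a1); a2 <- drop(R %*% a2)
    }
    if (thermal && beta[j] > 0) {
      ax <- cos(zeta[j]) * a1 + sin(zeta[j]) * a2
      R <- rotation_about(ax, beta[j])
      t0 <- drop(R %*% t0); a1 <- drop(R %*% a1); a2 <- drop(R %*% a2)
    }
    tg[j + 1, ] <- t0; m1[j + 1, ] <- a1; m2[j + 1, ] <- a2
  }

  pos <- rbind(c(0, 0, 0), apply(tg * ds, 2, cumsum))
  e2e <- pos[n + 1, ] - pos[1, ]
  structure(list(
    positions = pos, tangents = tg, m1 = m1, m2 = m2,
    s_mid = (seq_len(n) - 0.5) * ds, ds = ds,
    u_e2e = unit3(e2e), params = params
  ), class = "centerline")
}

# Local polar writhe density (turns/nm) of a discrete centerline about axis
# u, one value per segment (last repeated); used by the decoration stage to
# redistribute designed overtwist into writhe.
local_writhe_density <- function(cl, u = cl$u_e2e) {
  tg <- cl$tangents
  n <- nrow(tg)
  w <- numeric(n)
  for (j in seq_len(n - 1)) {
    dt <- (tg[j + 1, ] - tg[j, ]) / cl$ds
    tm <- unit3(tg[j, ] + tg[j + 1, ])
    w[j] <- sum(u * cross3(tm, dt)) / (1 + sum(u * tm)) / (2 * pi)
  }
  w[n] <- w[max(n - 1, 1)]
  w
}

#' Decorate a centerline as a six-helix DNA bundle
#'
#' Places `n_duplex` duplex axes on a hexagon in the material frame, rotated
#' along the contour at the designed axial twist rate, and winds two
#' antipodal strands around each duplex axis. The strand winding rate is the
#' relaxed repeat plus the designed overtwist, minus the local writhe
#' contribution scaled by the twist-writhe conversion (so generated
#' ensembles balance designed overtwist between residual duplex twist and
#' backbone writhe).
#'
#' @param centerline a `centerline` from [sample_centerline()] or a fixture.
#' @param geometry a [bundle_geometry()]; `bp_count` must match the number
#'   of centerline segments.
#' @param linking a [linking_target()] (or NULL for a relaxed bundle).
#' @param axial_twist_rate turns/um of cross-section rotation; defaults to
#'   the value in the centerline's chain parameters.
#' @param design_label label stored on the conformation.
#' @param diameter bundle diameter, nm.
#' @return a `filament_conformation`.
#' @export
decorate_bundle <- function(centerline, geometry, linking = NULL,
                            axial_twist_rate = NULL, design_label = "synthetic",
                            diameter = NULL) {
  stopifnot(inherits(centerline, "centerline"),
            inherits(geometry, "bundle_geometry"))
  n <- nrow(centerline$tangents)
  if (n != geometry$bp_count)
    stop("centerline has ", n, " segments but geometry expects bp_count = ",
         geometry$bp_count)
  lc <- centerline$params$contour_length %||% (n * centerline$ds)
  if (abs(geometry$rise * geometry$bp_count - lc) > 0.02 * lc)
    stop("geometry violates rise * bp_count = contour length within 2% (",
         signif(geometry$rise * geometry$bp_count, 4), " vs ", signif(lc, 4),
         " nm)")
  linking <- linking %||% linking_target(0)
  omega0 <- (axial_twist_rate %||%
               (centerline$params$axial_twist_rate %||% 0)) * 1e-3  # turns/nm
  d_rate <- linking$design_overtwist * 1e-3                         # turns/nm
  conv <- linking$twist_writhe_conversion

  ds <- centerline$ds
  s <- centerline$s_mid
  wloc <- if (conv != 0 && linking$bias_mode != "none")
    local_writhe_density(centerline) else numeric(n)
  # accumulated strand winding (turns) at each bp plane
  tw_rate <- geometry$duplex_twist_density + d_rate - conv * wloc
  cum_tw <- cumsum(tw_rate * ds) - 0.5 * tw_rate * ds
  phi_b <- 2 * pi * omega0 * s  # bundle cross-section rotation (radians)

  mid <- (centerline$positions[seq_len(n), , drop = FALSE] +
            centerline$positions[seq_len(n) + 1, , drop = FALSE]) / 2
  tg <- centerline$tangents
  # decorate in a twist-free (parallel-transported) frame: the centerline's
  # material frame carries the intrinsic torsion, which must not leak into
  # the built duplex winding
  ptf <- transport_frames(tg, m1_init = centerline$m1[1, ])
  m1 <- ptf$m1; m2 <- ptf$m2

  nd <- geometry$n_duplex
  n_sites <- 2L * nd * n
  P <- matrix(0, n_sites, 3); BV <- matrix(0, n_sites, 3)
  NV <- matrix(0, n_sites, 3)
  did <- integer(n_sites); sid <- integer(n_sites); bpi <- integer(n_sites)

  row <- 1L
  for (d in seq_len(nd) - 1L) {
    phi_d <- 2 * pi * d / nd
    ca <- cos(phi_d + phi_b); sa <- sin(phi_d + phi_b)
    axis_pts <- mid + geometry$hex_radius * (ca * m1 + sa * m2)
    theta <- 2 * pi * cum_tw + phi_d + phi_b
    ct <- cos(theta); st <- sin(theta)
    off <- geometry$duplex_radius * (ct * m1 + st * m2)
    for (strand in 1:2) {
      sgn <- if (strand == 1) 1 else -1
      idx <- row:(row + n - 1L)
      P[idx, ] <- axis_pts + sgn * off
      BV[idx, ] <- -sgn * (ct * m1 + st * m2)  # base points toward duplex axis
      NV[idx, ] <- tg
      did[idx] <- d; sid[idx] <- strand; bpi[idx] <- seq_len(n) - 1L
      row <- row + n
    }
  }
  filament_conformation(
    positions = P, base_vectors = BV, normal_vectors = NV,
    strand_id = sid, duplex_id = did, bp_index = bpi,
    n_duplex = nd,
    contour_length = centerline$params$contour_length %||% (n * ds),
    diameter = diameter %||% geometry$diameter,
    design_label = design_label
  )
}

#' Generate a synthetic conformation ensemble
#'
#' Draws `n` independent wormlike-chain conformations and decorates each as
#' a six-helix bundle. When the linking target carries a nonzero designed
#' overtwist and `bias_mode = "fixed"`, the chain acquires an intrinsic
#' solenoidal bias whose writhe density absorbs `partition_fraction` of the
#' designed overtwist (same sign: overwound duplexes bias toward
#' right-handed writhe, underwound toward left-handed).
#'
#' @param params [chain_parameters()]; `segment_length` is overridden to
#'   match `geometry$bp_count`.
#' @param geometry [bundle_geometry()].
#' @param linking [linking_target()].
#' @param n number of conformations.
#' @param seed integer seed; the run is bitwise reproducible given the seed.
#' @param design_label label for the variant.
#' @return a `conformation_ensemble` with full provenance.
#' @export
generate_ensemble <- function(params, geometry, linking = linking_target(0),
                              n = 100L, seed = params$seed,
                              design_label = "synthetic") {
  stopifnot(n >= 1)
  params$segment_length <- params$contour_length / geometry$bp_count
  params$n_segments <- geometry$bp_count

  if (linking$bias_mode == "fixed" && linking$design_overtwist != 0 &&
      params$intrinsic_curvature == 0 && params$intrinsic_torsion == 0) {
    w_target <- linking$partition_fraction * linking$design_overtwist * 1e-3 /
      linking$twist_writhe_conversion
    sb <- solenoid_bias(w_target, params$contour_length,
                        m = linking$solenoid_turns)
    params$intrinsic_curvature <- sb$kappa0
    params$intrinsic_torsion <- sb$tau0
  }

  set.seed(seed)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- sample_centerline(params)
    confs[[i]] <- decorate_bundle(cl, geometry, linking,
                                  design_label = design_label)
  }
  conformation_ensemble(confs, provenance = list(
    generator = "wormlike_bundle",
    params = unclass(params), geometry = unclass(geometry),
    linking = unclass(linking), n = n, seed = seed,
    package_version = as.character(utils::packageVersion("origamiLC"))
  ))
}

# Build a centerline object from explicit node positions (fixtures).
centerline_from_positions <- function(pos, contour_length) {
  n <- nrow(pos) - 1L
  seg <- pos[seq_len(n) + 1L, , drop = FALSE] - pos[seq_len(n), , drop = FALSE]
  ds_all <- sqrt(rowSums(seg^2))
  tg <- seg / ds_all
  fr <- transport_frames(tg)
  structure(list(
    positions = pos, tangents = tg, m1 = fr$m1, m2 = fr$m2,
    s_mid = (cumsum(ds_all) - ds_all / 2), ds = mean(ds_all),
    u_e2e = unit3(pos[n + 1L, ] - pos[1L, ]),
    params = list(contour_length = contour_length, axial_twist_rate = 0)
  ), class = "centerline")
}

#' Ideal circular-helix and straight-rod fixtures
#'
#' `make_ideal_helix` builds a filament whose backbone is the ideal
#' circular helical deformation mode
#' r_perp(s) = a (cos(2 pi m s / l_c) v + h sin(2 pi m s / l_c) w)
#' about a straight long axis: the extreme for which the helicity order
#' parameter is exactly +/-1 at wave number m / l_c. `make_straight_rod`
#' has no transverse displacement at all (H identically 0).
#'
#' @param contour_length axial length l_c in nm.
#' @param amplitude helix amplitude a in nm (should be << l_c).
#' @param mode_number integer number of helical periods m over the contour.
#' @param handedness +1 (right-handed) or -1 (left-handed).
#' @param n_points number of bp planes; defaults to one per 0.34 nm of
#'   contour. Coarser fixtures get a proportionally larger plane spacing
#'   (rise), keeping the decoration geometry self-consistent.
#' @param geometry optional [bundle_geometry()]; defaults to a six-helix
#'   decoration with `bp_count = n_points` and
#'   `rise = contour_length / n_points`.
#' @return a `filament_conformation`.
#' @export
make_ideal_helix <- function(contour_length = 420, amplitude = 8,
                             mode_number = 3L, handedness = 1L,
                             n_points = NULL, geometry = NULL) {
  n_points <- n_points %||% round(contour_length / 0.34)
  stopifnot(mode_number >= 1, abs(handedness) == 1,
            amplitude < contour_length)
  N <- n_points
  j <- 0:N
  z <- j * contour_length / N
  phi <- 2 * pi * mode_number * j / N
  pos <- cbind(amplitude * cos(phi),
               handedness * amplitude * sin(phi),
               z)
  cl <- centerline_from_positions(pos, contour_length)
  geometry <- geometry %||%
    bundle_geometry(bp_count = N, rise = contour_length / N)
  if (geometry$bp_count != N) stop("geometry bp_count must equal n_points")
  decorate_bundle(cl, geometry, design_label = sprintf(
    "ideal_helix_m%d_%s", mode_number, if (handedness > 0) "rh" else "lh"))
}

#' @rdname make_ideal_helix
#' @export
make_straight_rod <- function(contour_length = 420, n_points = NULL,
                              geometry = NULL) {
  N <- n_points %||% round(contour_length / 0.34)
  pos <- cbind(0, 0, (0:N) * contour_length / N)
  cl <- centerline_from_positions(pos, contour_length)
  geometry <- geometry %||%
    bundle_geometry(bp_count = N, rise = contour_length / N)
  if (geometry$bp_count != N) stop("geometry bp_count must equal n_points")
  decorate_bundle(cl, geometry, design_label = "straight_rod")
}

#' Ideal solenoid centerline fixture
#'
#' A noiseless circular helix of `m` turns with pitch angle `alpha` about
#' the z axis, sampled at `n_points` uniform arclength steps; the reference
#' curve for the closed-form local polar writhe m (1 - cos alpha) / l_c.
#'
#' @param contour_length arclength in nm.
#' @param m number of helical turns.
#' @param pitch_angle_deg angle between tangent and long axis, degrees.
#' @param handedness +1 right-handed, -1 left-handed.
#' @param n_points number of sampled points.
#' @return a `backbone_curve` (see [extract_backbone()]).
#' @export
make_solenoid_backbone <- function(contour_length = 420, m = 2,
                                   pitch_angle_deg = 10, handedness = 1L,
                                   n_points = 1000L) {
  alpha <- pitch_angle_deg * pi / 180
  s <- (seq_len(n_points) - 1) * contour_length / n_points
  c0 <- 2 * pi * m / contour_length    # phase rate per arclength
  r <- sin(alpha) / c0
  phi <- handedness * c0 * s
  pos <- cbind(r * cos(phi), r * sin(phi), s * cos(alpha))
  pos <- sweep(pos, 2, colMeans(pos))
  structure(list(positions = pos, ds = contour_length / n_points,
                 contour_length = contour_length, n = n_points),
            class = "backbone_curve")
}
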
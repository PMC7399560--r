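# Differential-geometry measurements on bundle conformations: per-duplex
# twist density, overtwist relative to relaxed B-DNA, and the local polar
# writhe of the filament centerline.
#
# Units follow common usage for origami mechanics: twist densities in
# turns/um, writhe densities in 1/mm (all internal geometry in nm).

#' Reference twist density of relaxed B-DNA
#'
#' Tw0 = 1 / (bp_per_turn * rise), returned in turns/nm. The default
#' 10.5 bp/turn with a 0.34 nm/bp rise gives 0.2801 turns/nm
#' (280.1 turns/um); it is exposed because the equilibrium repeat of DNA
#' constrained inside origami bundles may differ slightly.
#'
#' @param bp_per_turn helical repeat, bp per turn.
#' @param rise nm per bp.
#' @return turns/nm.
#' @export
reference_twist_density <- function(bp_per_turn = 10.5, rise = 0.34) {
  1 / (bp_per_turn * rise)
}

# Interpolants for the two strands of one duplex: positions ordered by
# bp_index, trimmed, splined against the centerline arclength.
duplex_strand_matrices <- function(conf, duplex, trim_bp) {
  sel <- conf$duplex_id == duplex
  s1 <- sel & conf$strand_id == min(conf$strand_id[sel])
  s2 <- sel & conf$strand_id == max(conf$strand_id[sel])
  r1 <- conf$positions[s1, , drop = FALSE][order(conf$bp_index[s1]), , drop = FALSE]
  r2 <- conf$positions[s2, , drop = FALSE][order(conf$bp_index[s2]), , drop = FALSE]
  if (nrow(r1) != nrow(r2)) stop("strands of duplex ", duplex, " differ in length")
  n <- nrow(r1)
  if (trim_bp > 0) {
    if (2 * trim_bp >= n - 4) stop("trim_bp leaves fewer than 4 bp")
    keep <- (trim_bp + 1):(n - trim_bp)
    r1 <- r1[keep, , drop = FALSE]; r2 <- r2[keep, , drop = FALSE]
  }
  list(r1 = r1, r2 = r2)
}

#' Per-duplex twist densities of a bundle conformation
#'
#' For each duplex, cubic splines interpolate the two strands' nucleotide
#' centers of mass; with centerline r = (r1 + r2)/2, tangent t = dr/ds and
#' normal n = (r1 - r2)/|r1 - r2|, the twist is the rotation of n about t,
#' Tw = (1/2 pi l) integral t . (n x dn/ds) ds, evaluated by composite
#' Simpson quadrature on a grid oversampled `oversample`-fold relative to
#' the bp planes. The last `trim_bp` planes at each extremity are excluded
#' beforehand.
#'
#' @param conformation a `filament_conformation`.
#' @param trim_bp end planes excluded (default 10).
#' @param oversample quadrature oversampling factor (default 4).
#' @return numeric vector of twist densities, one per duplex, in turns/um.
#' @export
duplex_twist <- function(conformation, trim_bp = 10L, oversample = 4L) {
  vapply(seq_len(conformation$n_duplex) - 1L, function(d) {
    st <- duplex_strand_matrices(conformation, d, trim_bp)
    one_duplex_twist(st$r1, st$r2, oversample)
  }, numeric(1)) * 1e3
}

# twist density (turns/nm) of one duplex given strand position matrices
one_duplex_twist <- function(r1, r2, oversample = 4L) {
  n <- nrow(r1)
  if (n < 4) stop("need >= 4 bp for cubic interpolation")
  mid <- (r1 + r2) / 2
  seg <- sqrt(rowSums((mid[-1, , drop = FALSE] - mid[-n, , drop = FALSE])^2))
  sa <- c(0, cumsum(seg))
  # guard against degenerate geometry: consecutive normals near-antiparallel
  d <- r1 - r2
  dn <- d / sqrt(rowSums(d^2))
  dots <- rowSums(dn[-1, , drop = FALSE] * dn[-n, , drop = FALSE])
  if (any(dots < -0.99))
    stop("degenerate geometry: consecutive base-pair normals are antiparallel")

  sp1 <- lapply(1:3, function(j) stats::splinefun(sa, r1[, j], method = "fmm"))
  sp2 <- lapply(1:3, function(j) stats::splinefun(sa, r2[, j], method = "fmm"))
  sg <- seq(0, sa[n], length.out = oversample * n)
  h <- sg[2] - sg[1]
  P1 <- sapply(sp1, function(f) f(sg)); P1d <- sapply(sp1, function(f) f(sg, deriv = 1))
  P2 <- sapply(sp2, function(f) f(sg)); P2d <- sapply(sp2, function(f) f(sg, deriv = 1))
  rm <- (P1 + P2) / 2; rmd <- (P1d + P2d) / 2
  tv <- rmd / sqrt(rowSums(rmd^2))
  dd <- P1 - P2; ddd <- P1d - P2d
  dl <- sqrt(rowSums(dd^2))
  nv <- dd / dl
  # dn/ds = (d' - n (n . d')) / |d|
  ndot <- rowSums(nv * ddd)
  nd <- (ddd - nv * ndot) / dl
  integrand <- tv[, 1] * (nv[, 2] * nd[, 3] - nv[, 3] * nd[, 2]) +
    tv[, 2] * (nv[, 3] * nd[, 1] - nv[, 1] * nd[, 3]) +
    tv[, 3] * (nv[, 1] * nd[, 2] - nv[, 2] * nd[, 1])
  total_turns <- simpson_uniform(integrand, h) / (2 * pi)
  total_turns / sa[n]
}

#' Mean overtwist of a conformation
#'
#' Average of the per-duplex twist densities minus the reference Tw0.
#'
#' @inheritParams duplex_twist
#' @param tw0 reference twist density in turns/nm
#'   (see [reference_twist_density()]).
#' @return overtwist Delta-Tw in turns/um.
#' @export
overtwist <- function(conformation, tw0 = reference_twist_density(),
                      trim_bp = 10L, oversample = 4L) {
  mean(duplex_twist(conformation, trim_bp, oversample)) - tw0 * 1e3
}

#' Local polar writhe of a backbone curve
#'
#' Wr = (1 / 2 pi l_c) integral u . (t x dt/ds) / (1 + u . t) ds, the local
#' contribution to the polar writhe of a curve that is monotone along its
#' long axis u (dr_u/ds > 0 everywhere; violated turning points raise an
#' error naming the abscissa). Wr > 0 when the tangent winds right-handedly
#' about u. A Savitzky-Golay filter is applied to the backbone coordinates
#' first to remove short-wavelength contour noise arising from the
#' geometric centerline definition.
#'
#' @param backbone a `backbone_curve`.
#' @param frame optional `molecular_frame`; its u is the long axis
#'   (computed from the backbone when omitted).
#' @param presmooth list with Savitzky-Golay `order` and `window`, or NULL
#'   to skip smoothing.
#' @param oversample quadrature oversampling factor.
#' @return writhe density in 1/mm (multiply by l_c in mm for total turns).
#' @export
polar_writhe <- function(backbone, frame = NULL,
                         presmooth = list(order = 9, window = 15),
                         oversample = 4L) {
  u <- (frame %||% gyration_frame(backbone))$u
  P <- backbone$positions
  n <- nrow(P)
  if (!is.null(presmooth)) {
    win <- min(presmooth$window %||% 15, n - (1 - n %% 2))
    if (win %% 2 == 0) win <- win - 1
    ord <- min(presmooth$order %||% 9, win - 1)
    if (win > ord && win >= 3)
      P <- apply(P, 2, signal::sgolayfilt, p = ord, n = win)
  }
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-n, , drop = FALSE])^2))
  sa <- c(0, cumsum(seg))
  sp <- lapply(1:3, function(j) stats::splinefun(sa, P[, j], method = "fmm"))
  sg <- seq(0, sa[n], length.out = oversample * n)
  h <- sg[2] - sg[1]
  R1 <- sapply(sp, function(f) f(sg, deriv = 1))
  R2 <- sapply(sp, function(f) f(sg, deriv = 2))
  speed <- sqrt(rowSums(R1^2))
  tv <- R1 / speed
  ru_d <- drop(tv %*% u)
  if (any(ru_d <= 0)) {
    bad <- sg[which(ru_d <= 0)[1]]
    stop(sprintf(
      "polar writhe undefined: turning point in u at arclength s = %.3f nm",
      bad))
  }
  # dt/ds = (r'' - t (t . r'')) / |r'|
  td <- (R2 - tv * rowSums(tv * R2)) / speed
  cx <- cbind(tv[, 2] * td[, 3] - tv[, 3] * td[, 2],
              tv[, 3] * td[, 1] - tv[, 1] * td[, 3],
              tv[, 1] * td[, 2] - tv[, 2] * td[, 1])
  integrand <- drop(cx %*% u) / (1 + drop(tv %*% u))
  wr_per_nm <- simpson_uniform(integrand, h) / (2 * pi) / sa[n]
  wr_per_nm * 1e6  # 1/mm
}

#' Ensemble twist-writhe statistics
#'
#' Per-conformation overtwist and polar writhe, their ensemble means with
#' standard errors, and the across-ensemble correlation between overtwist
#' and writhe (the twist-writhe coupling diagnostic). Conformations whose
#' centerline violates the polar-writhe turning-point precondition are
#' excluded and counted; an error is raised if they exceed
#' `max_failure_fraction`.
#'
#' @param ensemble a `conformation_ensemble` with count >= 2.
#' @param tw0 reference twist density, turns/nm.
#' @param trim_bp end planes excluded.
#' @param presmooth Savitzky-Golay settings for the writhe pre-smoothing.
#' @param max_failure_fraction tolerated fraction of writhe failures.
#' @return an object of class `ensemble_twist_writhe`: data.frame
#'   `records` (columns `overtwist_turns_um`, `writhe_mm`), means, standard
#'   errors, `coupling` (Pearson correlation), and `n_writhe_failed`.
#' @export
ensemble_twist_writhe <- function(ensemble, tw0 = reference_twist_density(),
                                  trim_bp = 10L,
                                  presmooth = list(order = 9, window = 15),
                                  max_failure_fraction = 0.05) {
  if (ensemble$count < 2) stop("need count >= 2")
  n <- ensemble$count
  dtw <- numeric(n); wr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cf <- ensemble$conformations[[i]]
    dtw[i] <- overtwist(cf, tw0 = tw0, trim_bp = trim_bp)
    bb <- extract_backbone(cf, trim_bp = trim_bp)
    fr <- gyration_frame(bb)
    wr[i] <- tryCatch(polar_writhe(bb, fr, presmooth = presmooth),
                      error = function(e) NA_real_)
  }
  failed <- sum(is.na(wr))
  if (failed / n > max_failure_fraction)
    stop(failed, " of ", n, " conformations violate the polar-writhe ",
         "precondition (max_failure_fraction = ", max_failure_fraction, ")")
  ok <- !is.na(wr)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    records = data.frame(overtwist_turns_um = dtw, writhe_mm = wr),
    overtwist_mean = mean(dtw), overtwist_se = se(dtw),
    writhe_mean = mean(wr[ok]), writhe_se = se(wr[ok]),
    coupling = if (sum(ok) > 2) stats::cor(dtw[ok], wr[ok]) else NA_real_,
    n_writhe_failed = failed, count = n, tw0 = tw0
  ), class = "ensemble_twist_writhe")
}

#' @export
print.ensemble_twist_writhe <- function(x, ...) {
  cat("<ensemble_twist_writhe> ", x$count, " conformations\n", sep = "")
  cat(sprintf("  <dTw> = %.3f +/- %.3f turns/um\n",
              x$overtwist_mean, x$overtwist_se))
  cat(sprintf("  <Wr>  = %.2f +/- %.2f 1/mm\n", x$writhe_mean, x$writhe_se))
  cat(sprintf("  dTw-Wr coupling (r) = %.3f; writhe failures: %d\n",
              x$coupling, x$n_writhe_failed))
  invisible(x)
}

#' Tabulate twist-writhe statistics for several designs
#'
#' @param ... named `ensemble_twist_writhe` objects (names = design labels).
#' @param initial_overtwist optional numeric vector of designed overtwists
#'   (turns/um) to include as the straight-and-untwisted reference column.
#' @return data.frame with one row per design; units in the column names.
#' @export
twist_writhe_table <- function(..., initial_overtwist = NULL) {
  objs <- list(...)
  out <- data.frame(
    design = names(objs) %||% paste0("design", seq_along(objs)),
    overtwist_mean_turns_um = vapply(objs, `[[`, numeric(1), "overtwist_mean"),
    overtwist_se_turns_um = vapply(objs, `[[`, numeric(1), "overtwist_se"),
    writhe_mean_mm = vapply(objs, `[[`, numeric(1), "writhe_mean"),
    writhe_se_mm = vapply(objs, `[[`, numeric(1), "writhe_se")
  )
  if (!is.null(initial_overtwist))
    out <- cbind(out[1], initial_overtwist_turns_um = initial_overtwist,
                 out[-1])
  rownames(out) <- NULL
  out
}
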
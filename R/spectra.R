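# Backbone extraction, molecular frame, transverse fluctuation spectra and
# the helicity order parameter H(k).
#
# H(k) = 2 Im{c_vw(k)} / (c_vv(k) + c_ww(k)), where c_vw is the
# Fourier-transformed cross-correlation of the two transverse displacement
# components in the gyration-tensor principal frame. |H| <= 1 always
# (Cauchy-Schwarz); H = +1 (-1) exactly for an ideal right- (left-) handed
# circular helical mode, whose transverse components have equal amplitude
# and perfect phase quadrature; H(0) = 0 since zero-frequency components
# are real.

#' Extract the discretized backbone of a bundle conformation
#'
#' One backbone point per base-pair plane: the mean of the duplex midpoint
#' positions (two strands averaged) over all duplexes at that plane.
#' `trim_bp` planes are removed at each end to suppress fraying end
#' effects, the curve is re-parameterized to uniform arclength steps by
#' cubic-spline interpolation (skipped when the chords are already
#' uniform), and the center of mass is moved to the origin.
#'
#' @param conformation a `filament_conformation`.
#' @param trim_bp number of planes dropped at each extremity (default 10).
#' @return an object of class `backbone_curve` with fields `positions`
#'   (n x 3, nm), `ds` (nm), `contour_length` (= n * ds) and `n`.
#' @export
extract_backbone <- function(conformation, trim_bp = 10L) {
  stopifnot(trim_bp >= 0)
  cf <- conformation
  planes <- sort(unique(cf$bp_index))
  nd <- cf$n_duplex
  key <- interaction(cf$duplex_id, cf$bp_index, drop = FALSE)
  # mean position over all sites in each (duplex, plane) cell = duplex midpoint
  sums <- rowsum(cf$positions, group = paste(cf$duplex_id, cf$bp_index))
  cnt <- as.vector(table(paste(cf$duplex_id, cf$bp_index)))
  if (any(cnt != 2L))
    stop("missing bp planes: every (duplex, bp_index) needs both strands")
  lab <- rownames(sums)
  parts <- do.call(rbind, strsplit(lab, " "))
  dup <- as.integer(parts[, 1]); bp <- as.integer(parts[, 2])
  mids <- sums / 2
  # average duplex midpoints within each plane
  bb <- rowsum(mids, group = bp) / nd
  bb <- bb[order(as.integer(rownames(bb))), , drop = FALSE]
  per_plane <- table(bp)
  if (any(per_plane != nd))
    stop("missing bp planes: some planes lack one or more duplexes")

  n0 <- nrow(bb)
  if (trim_bp > 0) {
    if (2 * trim_bp >= n0 - 3) stop("trim_bp leaves too few planes")
    bb <- bb[(trim_bp + 1):(n0 - trim_bp), , drop = FALSE]
  }
  n <- nrow(bb)

  seg <- bb[-1, , drop = FALSE] - bb[-n, , drop = FALSE]
  chord <- sqrt(rowSums(seg^2))
  if (max(abs(chord - mean(chord))) > 1e-9 * mean(chord)) {
    sa <- c(0, cumsum(chord))
    su <- seq(0, sa[n], length.out = n)
    bb <- cbind(stats::spline(sa, bb[, 1], xout = su, method = "natural")$y,
                stats::spline(sa, bb[, 2], xout = su, method = "natural")$y,
                stats::spline(sa, bb[, 3], xout = su, method = "natural")$y)
  }
  ds <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  bb <- sweep(bb, 2, colMeans(bb))
  structure(list(positions = bb, ds = ds, contour_length = n * ds, n = n),
            class = "backbone_curve")
}

#' @export
print.backbone_curve <- function(x, ...) {
  cat("<backbone_curve> ", x$n, " points, ds = ", signif(x$ds, 4),
      " nm, l_c = ", signif(x$contour_length, 5), " nm\n", sep = "")
  invisible(x)
}

#' Principal frame of the backbone gyration tensor
#'
#' u is the direction of maximum dispersion (the filament long axis), v the
#' direction of minimum dispersion, and w = u x v completes a right-handed
#' frame. Principal axes are defined only up to sign, so the frame is made
#' reproducible by fixing u along the first-to-last-point vector and v
#' along the first non-negligible transverse displacement; only relative
#' handedness matters for every chirality measure downstream.
#'
#' @param backbone a `backbone_curve`.
#' @return an object of class `molecular_frame` with unit vectors `u`,
#'   `v`, `w` and the gyration eigenvalues.
#' @export
gyration_frame <- function(backbone) {
  P <- backbone$positions
  if (nrow(P) < 3) stop("need >= 3 points for a gyration frame")
  G <- crossprod(P) / nrow(P)
  eg <- eigen(G, symmetric = TRUE)
  u <- eg$vectors[, 1]; v <- eg$vectors[, 3]
  degenerate <- (abs(eg$values[1] - eg$values[2]) < 1e-12 * max(eg$values[1], 1)) ||
    (abs(eg$values[2] - eg$values[3]) < 1e-12 * max(eg$values[1], 1))
  if (sum(u * (P[nrow(P), ] - P[1, ])) < 0) u <- -u
  rp <- P - outer(drop(P %*% u), u)
  nn <- sqrt(rowSums(rp^2))
  i0 <- which(nn > 1e-9 * max(nn, backbone$ds))[1]
  if (!is.na(i0) && sum(v * rp[i0, ]) < 0) v <- -v
  w <- cross3(u, v)
  structure(list(u = u, v = v, w = w, eigenvalues = eg$values,
                 degenerate = degenerate),
            class = "molecular_frame")
}

#' @export
print.molecular_frame <- function(x, ...) {
  cat("<molecular_frame>\n")
  cat("  u:", sprintf("% .4f", x$u), "\n")
  cat("  v:", sprintf("% .4f", x$v), "\n")
  cat("  w:", sprintf("% .4f", x$w), "\n")
  invisible(x)
}

#' Transverse displacement of a backbone
#'
#' r_perp(s) = r(s) - (r(s) . u) u, the component of each backbone point
#' perpendicular to the filament long axis.
#'
#' @param backbone a `backbone_curve` (center of mass at the origin).
#' @param frame a `molecular_frame`.
#' @return n x 3 matrix of transverse displacements.
#' @export
transverse_displacement <- function(backbone, frame) {
  P <- backbone$positions
  P - outer(drop(P %*% frame$u), frame$u)
}

#' Helicity spectrum of a transverse displacement sequence
#'
#' Computes the one-sided discrete transform
#' r_hat(k_n) = sum_j ds r_perp(s_j) exp(-2 pi i k_n s_j) at wave numbers
#' k_n = n / l_c for n = 0..floor(N/2) (evaluated by FFT, which is exactly
#' this sum on the uniform grid), the auto- and cross-spectra of the v and
#' w components, and H(k) = 2 Im{c_vw} / (c_vv + c_ww). H is set to 0 where
#' the denominator underflows. H > 0 marks right-handed displacement modes
#' about +u with the right-handed frame convention of [gyration_frame()].
#'
#' @param rperp n x 3 matrix from [transverse_displacement()].
#' @param frame the `molecular_frame` used to compute it.
#' @param ds uniform arclength step (nm).
#' @param contour_length l_c = n * ds (nm).
#' @return an object of class `helicity_spectrum`: data.frame columns `k`
#'   (1/nm), `c_vv`, `c_ww` (nm^4), `re_cvw`, `im_cvw`, `H`.
#' @export
helicity_spectrum <- function(rperp, frame, ds, contour_length) {
  n <- nrow(rperp)
  if (abs(contour_length - n * ds) > 1e-6 * contour_length)
    stop("non-uniform sampling: contour_length must equal n * ds")
  pv <- drop(rperp %*% frame$v)
  pw <- drop(rperp %*% frame$w)
  fv <- ds * stats::fft(pv)
  fw <- ds * stats::fft(pw)
  m <- floor(n / 2)
  idx <- seq_len(m + 1)
  cvv <- Mod(fv[idx])^2
  cww <- Mod(fw[idx])^2
  cvw <- fv[idx] * Conj(fw[idx])
  den <- cvv + cww
  # scale-aware underflow guard: spectral power below the square of the
  # floating-point noise floor of the coordinates (~1e-9 of the filament
  # scale) carries no geometric information, so H is defined as 0 there
  # (exact fixtures would otherwise report ratios of rounding residue)
  floor_pow <- max(1e-300, (1e-9 * contour_length * ds)^2)
  H <- ifelse(den > floor_pow, 2 * Im(cvw) / den, 0)
  out <- data.frame(k = (idx - 1) / contour_length,
                    c_vv = cvv, c_ww = cww,
                    re_cvw = Re(cvw), im_cvw = Im(cvw), H = H)
  attr(out, "ds") <- ds
  attr(out, "contour_length") <- contour_length
  attr(out, "full_power") <- sum(Mod(fv)^2 + Mod(fw)^2)
  class(out) <- c("helicity_spectrum", "data.frame")
  out
}

#' Construct a molecular frame from known axes
#'
#' For ideal fixtures whose long axis is known by construction (the
#' gyration axis of any finite helix is slightly tilted from the true
#' helix axis, an end effect of order a / l_c). w is completed as u x v.
#'
#' @param u long axis (unit 3-vector).
#' @param v transverse axis orthogonal to u.
#' @return a `molecular_frame`.
#' @export
molecular_frame <- function(u = c(0, 0, 1), v = c(1, 0, 0)) {
  u <- unit3(u); v <- unit3(v)
  if (abs(sum(u * v)) > 1e-9) stop("u and v must be orthogonal")
  structure(list(u = u, v = v, w = cross3(u, v),
                 eigenvalues = NULL, degenerate = FALSE),
            class = "molecular_frame")
}

#' Helicity spectrum of a single conformation
#'
#' Convenience chain: backbone extraction, gyration frame (or a supplied
#' frame), transverse displacement, spectrum.
#'
#' @param conformation a `filament_conformation`.
#' @param trim_bp end planes to drop.
#' @param frame optional `molecular_frame`; computed from the gyration
#'   tensor when NULL.
#' @return a `helicity_spectrum`.
#' @export
conformation_helicity <- function(conformation, trim_bp = 10L, frame = NULL) {
  bb <- extract_backbone(conformation, trim_bp = trim_bp)
  fr <- frame %||% gyration_frame(bb)
  rp <- transverse_displacement(bb, fr)
  helicity_spectrum(rp, fr, bb$ds, bb$contour_length)
}

#' Ensemble-averaged helicity and transverse power spectra
#'
#' H(k) is computed per conformation and averaged pointwise (the mean of
#' per-conformation helicities; averaging the cross-spectra first is a
#' different, inequivalent estimator available via `average = "spectra"`).
#' Optional Savitzky-Golay smoothing (presentation only) is applied to the
#' mean curve, never to the raw per-conformation spectra.
#'
#' @param ensemble a `conformation_ensemble` with count >= 2.
#' @param trim_bp end planes to drop.
#' @param smoothing list with `order` and `window` for the Savitzky-Golay
#'   filter applied to the mean helicity, or NULL for none.
#' @param average `"per_conformation"` (default) or `"spectra"`.
#' @return an `ensemble_spectrum` data.frame: `k`, `H_mean`, `H_se`,
#'   `power_mean` (c_vv + c_ww), `power_se`, and `H_smooth` if smoothing
#'   was applied.
#' @export
ensemble_helicity <- function(ensemble, trim_bp = 10L,
                              smoothing = list(order = 9, window = 15),
                              average = c("per_conformation", "spectra")) {
  average <- match.arg(average)
  if (ensemble$count < 2) stop("ensemble averaging needs count >= 2")
  specs <- lapply(ensemble$conformations, conformation_helicity,
                  trim_bp = trim_bp)
  # conformations share the mode count; their contour lengths (and hence
  # absolute k) fluctuate by <1%, so spectra are aligned by mode index and
  # reported on the ensemble-mean k grid
  same <- vapply(specs, function(s) length(s$k) == length(specs[[1]]$k),
                 logical(1))
  if (!all(same)) stop("inconsistent k-grids across the ensemble")
  k0 <- rowMeans(vapply(specs, function(s) s$k,
                        numeric(length(specs[[1]]$k))))
  Hm <- vapply(specs, function(s) s$H, numeric(length(k0)))
  Pm <- vapply(specs, function(s) s$c_vv + s$c_ww, numeric(length(k0)))
  nconf <- length(specs)
  if (average == "per_conformation") {
    H_mean <- rowMeans(Hm)
  } else {
    ivw <- vapply(specs, function(s) s$im_cvw, numeric(length(k0)))
    H_mean <- 2 * rowMeans(ivw) / rowMeans(Pm)
  }
  out <- data.frame(
    k = k0,
    H_mean = H_mean,
    H_se = apply(Hm, 1, stats::sd) / sqrt(nconf),
    power_mean = rowMeans(Pm),
    power_se = apply(Pm, 1, stats::sd) / sqrt(nconf)
  )
  if (!is.null(smoothing)) {
    win <- min(smoothing$window %||% 15, length(k0) - (1 - length(k0) %% 2))
    if (win %% 2 == 0) win <- win - 1
    ord <- min(smoothing$order %||% 9, win - 1)
    if (win > ord && win >= 3) {
      out$H_smooth <- signal::sgolayfilt(out$H_mean, p = ord, n = win)
      attr(out, "smoothing") <- c(order = ord, window = win)
    }
  }
  attr(out, "count") <- nconf
  attr(out, "average") <- average
  class(out) <- c("ensemble_spectrum", "data.frame")
  out
}

#' Equipartition reference spectrum of a semiflexible filament
#'
#' For a free wormlike chain of persistence length l_p, expanding the
#' bending energy (l_p / 2) integral |r_perp''|^2 ds in Fourier modes
#' r_perp(s) = sum_q a_q exp(i q s) gives the quadratic form
#' (l_p l_c / 2) sum_q q^4 |a_q|^2 per transverse component, so
#' equipartition assigns <|a_q|^2> = 1 / (l_p l_c q^4) and, with the
#' transform convention r_hat(k) = sum ds r_perp exp(-2 pi i k s) (so
#' r_hat = l_c a_q at q = 2 pi k), the two-component transverse power is
#' <|r_hat_perp|^2>(k) = 2 l_c / (l_p (2 pi k)^4). The 1/k^4 low-k scaling
#' is the fingerprint of bending-dominated fluctuations.
#'
#' @param k wave numbers (1/nm); k = 0 yields NA.
#' @param persistence_length l_p (nm).
#' @param contour_length l_c (nm).
#' @param amplitude_norm optional multiplicative normalization.
#' @return numeric vector of reference power values (nm^4).
#' @export
wlc_reference_spectrum <- function(k, persistence_length, contour_length,
                                   amplitude_norm = 1) {
  stopifnot(persistence_length > 0, contour_length > 0)
  out <- amplitude_norm * 2 * contour_length /
    (persistence_length * (2 * pi * k)^4)
  out[k == 0] <- NA_real_
  out
}

#' Write a spectrum as a tab-separated table
#'
#' @param spectrum a `helicity_spectrum` or `ensemble_spectrum`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(as.data.frame(spectrum), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
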
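# Backbone extraction, gyration frame, transverse spectra and H(k)

backbone_from_centerline <- function(cl) {
  P <- cl$positions[-1, , drop = FALSE]
  P <- sweep(P, 2, colMeans(P))
  n <- nrow(P)
  structure(list(positions = P, ds = cl$ds, contour_length = n * cl$ds,
                 n = n), class = "backbone_curve")
}

test_that("backbone extraction recovers centerlines and counts planes", {
  rod <- make_straight_rod(contour_length = 420)
  bb <- extract_backbone(rod, trim_bp = 10L)
  expect_equal(bb$n, 1235 - 20)
  rp <- bb$positions[, 1:2]
  expect_lt(max(abs(rp)), 1e-6)  # collinear with the axis
  h <- make_ideal_helix(contour_length = 420, amplitude = 8,
                        mode_number = 3L, n_points = 512L)
  bh <- extract_backbone(h, trim_bp = 0L)
  amp <- sqrt(bh$positions[, 1]^2 + bh$positions[, 2]^2)
  expect_lt(abs(max(amp) - 8) / 8, 0.01)
})

test_that("missing base-pair planes are detected", {
  rod <- make_straight_rod(contour_length = 20.4, n_points = 60L)
  keep <- !(rod$duplex_id == 3 & rod$bp_index == 30)
  broken <- rod
  for (f in c("positions", "base_vectors", "normal_vectors"))
    broken[[f]] <- broken[[f]][keep, , drop = FALSE]
  for (f in c("strand_id", "duplex_id", "bp_index"))
    broken[[f]] <- broken[[f]][keep]
  expect_error(extract_backbone(broken, 0L), "missing")
})

test_that("the gyration frame is oriented, right-handed, and equivariant", {
  rod <- make_straight_rod(contour_length = 420)
  bb <- extract_backbone(rod, 10L)
  fr <- gyration_frame(bb)
  expect_gt(abs(fr$u[3]), 1 - 1e-9)           # principal axis of a rod
  expect_gt(sum(fr$u * (bb$positions[bb$n, ] - bb$positions[1, ])), 0)
  expect_equal(cross3_helper(fr$u, fr$v), fr$w, tolerance = 1e-12)
  # rotating all positions rotates the frame identically
  th <- fx_lh_ensemble()$conformations[[1]]
  b0 <- extract_backbone(th, 10L)
  f0 <- gyration_frame(b0)
  set.seed(4)
  Q <- random_rotation()
  b1 <- b0
  b1$positions <- b0$positions %*% t(Q)
  f1 <- gyration_frame(b1)
  expect_equal(f1$u, drop(Q %*% f0$u), tolerance = 1e-9)
  expect_equal(f1$v, drop(Q %*% f0$v), tolerance = 1e-9)
  expect_equal(f1$w, drop(Q %*% f0$w), tolerance = 1e-9)
  # a planar arc has its minimum-dispersion axis normal to the plane
  s <- seq(0, pi / 3, length.out = 200)
  arc <- cbind(100 * sin(s), 0, 100 * (1 - cos(s)))
  arc <- sweep(arc, 2, colMeans(arc))
  barc <- structure(list(positions = arc, ds = 1, contour_length = 200,
                         n = 200L), class = "backbone_curve")
  farc <- gyration_frame(barc)
  expect_gt(abs(farc$v[2]), 1 - 1e-9)
})

test_that("transverse displacements are orthogonal to u and complete the norm", {
  th <- fx_lh_ensemble()$conformations[[2]]
  bb <- extract_backbone(th, 10L)
  fr <- gyration_frame(bb)
  rp <- transverse_displacement(bb, fr)
  expect_lt(max(abs(rp %*% fr$u)), 1e-9)
  ru <- drop(bb$positions %*% fr$u)
  expect_equal(rowSums(bb$positions^2), ru^2 + rowSums(rp^2),
               tolerance = 1e-12)
})

test_that("H(0) vanishes and |H| <= 1 over random displacement fields", {
  fr <- molecular_frame(u = c(0, 0, 1), v = c(1, 0, 0))
  set.seed(7)
  worst <- 0
  for (i in 1:200) {
    n <- sample(32:128, 1)
    rp <- cbind(rnorm(n), rnorm(n), 0)
    sp <- helicity_spectrum(rp, fr, ds = 1, contour_length = n)
    expect_identical(sp$H[1], 0)
    worst <- max(worst, max(abs(sp$H)))
  }
  expect_lte(worst, 1)
})

test_that("the transform satisfies Parseval consistency", {
  th <- fx_lh_ensemble()$conformations[[3]]
  bb <- extract_backbone(th, 10L)
  fr <- gyration_frame(bb)
  rp <- transverse_displacement(bb, fr)
  sp <- helicity_spectrum(rp, fr, bb$ds, bb$contour_length)
  # sum over the full two-sided grid equals N ds^2 sum |r_perp|^2 (projected)
  pv <- drop(rp %*% fr$v); pw <- drop(rp %*% fr$w)
  lhs <- attr(sp, "full_power")
  rhs <- bb$n * bb$ds^2 * sum(pv^2 + pw^2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("H is invariant under proper rigid motions", {
  th <- fx_lh_ensemble()$conformations[[4]]
  bb <- extract_backbone(th, 10L)
  sp0 <- helicity_spectrum(transverse_displacement(bb, gyration_frame(bb)),
                           gyration_frame(bb), bb$ds, bb$contour_length)
  set.seed(5)
  Q <- random_rotation()
  br <- bb
  br$positions <- bb$positions %*% t(Q)
  frr <- gyration_frame(br)
  spr <- helicity_spectrum(transverse_displacement(br, frr), frr, br$ds,
                           br$contour_length)
  expect_equal(spr$H, sp0$H, tolerance = 1e-9)
})

test_that("ensemble helicity is positive at low k for overwound designs and smoothing is presentation-only", {
  es <- fx_lh_helicity()
  # statistical bias toward right-handed modes at the solenoid wavelength
  expect_gt(es$H_mean[2], 3 * es$H_se[2])
  # the |<H>| peak sits at the smallest accessible wave number 1/l_c
  expect_equal(which.max(abs(es$H_mean)), 2L)
  expect_true("H_smooth" %in% names(es))
  # smoothing never touches the raw mean
  es2 <- ensemble_helicity(fx_lh_ensemble(), smoothing = NULL)
  expect_equal(es2$H_mean, es$H_mean)
  # per-conformation and spectra-first averages are distinct estimators
  es3 <- ensemble_helicity(fx_lh_ensemble(), average = "spectra",
                           smoothing = NULL)
  expect_false(isTRUE(all.equal(es3$H_mean, es$H_mean)))
})

test_that("generated chains follow the discrete equipartition spectrum and its low-k asymptote", {
  p <- chain_parameters(contour_length = 420, segment_length = 1.05,
                        persistence_length = 8 * 420)
  set.seed(101)
  nconf <- 300
  pw <- NULL
  for (i in seq_len(nconf)) {
    bb <- backbone_from_centerline(sample_centerline(p))
    fr <- gyration_frame(bb)
    sp <- helicity_spectrum(transverse_displacement(bb, fr), fr, bb$ds,
                            bb$contour_length)
    pw <- cbind(pw, sp$c_vv + sp$c_ww)
  }
  meas <- rowMeans(pw)
  oracle <- oracle_wlc_spectrum(n = 400L, ds = 1.05, lp = 8 * 420)
  # modes 1..10: exact harmonic-chain oracle, mode by mode
  ratio <- meas[2:11] / oracle[2:11]
  expect_lt(max(abs(log(ratio))), 0.25)
  # the 2 l_c / (l_p (2 pi k)^4) asymptote describes the lowest mode within
  # a factor 2 (boundary leakage of the open filament grows at higher k)
  k1 <- 1 / (400 * 1.05)
  expect_lt(abs(log(meas[2] / wlc_reference_spectrum(k1, 8 * 420, 420))),
            log(2))
  # reference scaling: doubling l_p halves the predicted power
  kk <- (1:10) / 420
  expect_equal(wlc_reference_spectrum(kk, 2 * 3360, 420),
               wlc_reference_spectrum(kk, 3360, 420) / 2)
})
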
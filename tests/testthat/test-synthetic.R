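# Wormlike-chain sampler, bundle decoration, linking balance, fixtures

test_that("the rigid-rod limit recovers a straight chain of full contour length", {
  p <- chain_parameters(contour_length = 100, segment_length = 0.5,
                        persistence_length = 1e6 * 100)
  set.seed(1)
  cl <- sample_centerline(p)
  tg <- cl$tangents
  dev <- max(sqrt(rowSums((tg - matrix(tg[1, ], nrow(tg), 3,
                                       byrow = TRUE))^2)))
  expect_lt(dev, 1e-3)
  e2e <- sqrt(sum((cl$positions[nrow(cl$positions), ] - cl$positions[1, ])^2))
  expect_equal(e2e, 100, tolerance = 1e-6)
})

test_that("tangent correlations recover the persistence length within 10%", {
  p <- chain_parameters(contour_length = 420, segment_length = 1,
                        persistence_length = 8 * 420)
  set.seed(42)
  lags <- seq(20, 360, by = 40)
  acc <- matrix(0, 500, length(lags))
  for (i in 1:500) {
    tg <- sample_centerline(p)$tangents
    acc[i, ] <- sapply(lags, function(L)
      mean(rowSums(tg[1:(nrow(tg) - L), ] * tg[(1 + L):nrow(tg), ])))
  }
  fit <- stats::lm(log(colMeans(acc)) ~ lags)
  lp_hat <- -1 / coef(fit)[2]
  expect_lt(abs(lp_hat - 3360) / 3360, 0.10)
})

test_that("an intrinsic right-handed solenoid has positive polar writhe matching the closed form", {
  lc <- 420
  for (h in c(1, -1)) {
    sb <- solenoid_bias(h * 2 * (1 - cos(10 * pi / 180)) / lc, lc, m = 2)
    p <- chain_parameters(contour_length = lc, segment_length = 0.42,
                          persistence_length = 1e9,
                          intrinsic_curvature = sb$kappa0,
                          intrinsic_torsion = sb$tau0)
    set.seed(1)
    cl <- sample_centerline(p)
    bb <- structure(list(positions = sweep(cl$positions[-1, ], 2,
                                           colMeans(cl$positions[-1, ])),
                         ds = cl$ds, contour_length = nrow(cl$positions) - 1,
                         n = nrow(cl$positions) - 1L),
                    class = "backbone_curve")
    bb$contour_length <- bb$n * bb$ds
    wr <- polar_writhe(bb, frame = NULL, presmooth = NULL)
    closed <- h * 2 * (1 - cos(sb$pitch_angle)) / lc * 1e6
    expect_equal(sign(wr), h)
    expect_lt(abs(wr - closed) / abs(closed), 0.02)
  }
})

test_that("decoration reproduces designed overtwist in closed form", {
  lc <- 1235 * 0.34
  rod <- make_straight_rod(contour_length = lc)
  # relaxed repeat: zero overtwist within 0.05 turns/um
  expect_lt(abs(overtwist(rod, trim_bp = 10)), 0.05)
  # 10.0 bp/turn: dTw = (1/10 - 1/10.5) / rise, converted to turns/um
  g10 <- bundle_geometry(bp_count = 1235L, bp_per_turn = 10.0, rise = 0.34)
  rod10 <- make_straight_rod(contour_length = lc, n_points = 1235L,
                             geometry = g10)
  expected <- (1 / 10 - 1 / 10.5) / 0.34 * 1e3
  expect_equal(overtwist(rod10, trim_bp = 10), expected, tolerance = 0.004)
})

test_that("mirror reflection flips every chirality measure of a decorated bundle", {
  h <- make_ideal_helix(contour_length = 60, amplitude = 3, mode_number = 2,
                        n_points = 176L)
  hm <- mirror_conformation(h)
  H1 <- conformation_helicity(h, trim_bp = 0)$H
  H2 <- conformation_helicity(hm, trim_bp = 0)$H
  expect_equal(H2, -H1, tolerance = 1e-9)
  tw1 <- duplex_twist(h, trim_bp = 5)
  tw2 <- duplex_twist(hm, trim_bp = 5)
  expect_equal(tw2, -tw1, tolerance = 1e-9)
  bb1 <- extract_backbone(h, 0); bb2 <- extract_backbone(hm, 0)
  expect_equal(polar_writhe(bb2), -polar_writhe(bb1), tolerance = 1e-9)
})

test_that("generation is bitwise deterministic under a fixed seed", {
  g <- standin_geometry()
  p <- chain_parameters(contour_length = 60, segment_length = 60 / g$bp_count,
                        persistence_length = 480)
  e1 <- generate_ensemble(p, g, linking_target(7), n = 3L, seed = 123L)
  e2 <- generate_ensemble(p, g, linking_target(7), n = 3L, seed = 123L)
  expect_identical(e1$conformations[[3]]$positions,
                   e2$conformations[[3]]$positions)
  expect_identical(e1$provenance$seed, 123L)
})

test_that("generated ensembles balance designed overtwist between twist and writhe", {
  ens <- fx_lh_ensemble()  # design_overtwist = +7 turns/um
  tw <- fx_lh_twistwrithe()
  conv <- ens$provenance$linking$twist_writhe_conversion
  balance <- tw$overtwist_mean + conv * tw$writhe_mean * 1e-3
  se <- sqrt(tw$overtwist_se^2 + (conv * tw$writhe_se * 1e-3)^2)
  expect_lt(abs(balance - 7), 3 * se)
  # overwound (left-handed design convention) duplexes bias the backbone
  # toward right-handed writhe
  expect_gt(tw$writhe_mean, 3 * tw$writhe_se)
})

test_that("achiral ensembles show no helicity beyond noise", {
  es <- ensemble_helicity(fx_achiral_ensemble())
  z <- es$H_mean[-1] / es$H_se[-1]
  # the z-scores are correlated across k within one finite ensemble, so a
  # common O(1) offset is expected; the null holds as no k resolves a bias
  expect_gt(mean(abs(z) < 2), 0.85)
  expect_gt(mean(abs(z) < 3), 0.98)
})

test_that("ideal helix and rod fixtures realize the helicity extremes", {
  fr <- molecular_frame(u = c(0, 0, 1), v = c(1, 0, 0))
  h <- make_ideal_helix(mode_number = 3L, amplitude = 8, n_points = 512L)
  sp <- conformation_helicity(h, trim_bp = 0, frame = fr)
  expect_equal(sp$H[4], 1, tolerance = 1e-6)
  hl <- make_ideal_helix(mode_number = 3L, amplitude = 8, n_points = 512L,
                         handedness = -1L)
  spl <- conformation_helicity(hl, trim_bp = 0, frame = fr)
  # swapping handedness changes the sign of H only
  expect_equal(spl$H, -sp$H, tolerance = 1e-9)
  expect_equal(spl$c_vv + spl$c_ww, sp$c_vv + sp$c_ww, tolerance = 1e-9)
  rod <- make_straight_rod(contour_length = 420, n_points = 512L)
  spr <- conformation_helicity(rod, trim_bp = 0)
  expect_true(all(spr$H == 0))
})

test_that("coarse discretization and inconsistent geometry are rejected", {
  expect_error(chain_parameters(contour_length = 10, segment_length = 2),
               "coarse")
  p <- chain_parameters(contour_length = 100, segment_length = 1,
                        persistence_length = 0.5)
  expect_error(sample_centerline(p), "coarse")
  expect_error(bundle_geometry(hex_radius = 3, duplex_radius = 1,
                               diameter = 6), "envelope")
  # rise * bp_count must match the centerline contour within 2%
  p2 <- chain_parameters(contour_length = 60, segment_length = 60 / 100,
                         persistence_length = 480)
  set.seed(1)
  cl <- sample_centerline(p2)
  g_bad <- bundle_geometry(bp_count = 100L, rise = 0.34)
  expect_error(decorate_bundle(cl, g_bad), "rise")
})
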
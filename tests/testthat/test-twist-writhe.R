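# Duplex twist densities, polar writhe, ensemble statistics

test_that("a relaxed straight duplex measures the B-DNA reference twist", {
  rod <- make_straight_rod(contour_length = 1235 * 0.34)
  tw <- duplex_twist(rod, trim_bp = 10L)
  expect_length(tw, 6L)
  expect_equal(mean(tw), 1 / (10.5 * 0.34) * 1e3, tolerance = 2e-4)
  expect_lt(abs(overtwist(rod)), 0.05)  # turns/um
  # parity: mirroring flips the twist sign
  expect_equal(duplex_twist(mirror_conformation(rod), 10L), -tw,
               tolerance = 1e-9)
})

test_that("quadrature converges: halving the evaluation step moves Tw by < 0.1%", {
  cf <- fx_lh_ensemble()$conformations[[5]]
  t4 <- mean(duplex_twist(cf, 10L, oversample = 4L))
  t8 <- mean(duplex_twist(cf, 10L, oversample = 8L))
  expect_lt(abs(t8 - t4) / abs(t4), 1e-3)
  bb <- extract_backbone(cf, 10L)
  w4 <- polar_writhe(bb, oversample = 4L)
  w8 <- polar_writhe(bb, oversample = 8L)
  expect_lt(abs(w8 - w4) / abs(w4), 1e-3)
})

test_that("polar writhe matches the ideal-solenoid closed form and flips under reflection", {
  bb <- make_solenoid_backbone(contour_length = 420, m = 2,
                               pitch_angle_deg = 10, n_points = 1000L)
  wr <- polar_writhe(bb)
  closed <- 2 * (1 - cos(10 * pi / 180)) / 420 * 1e6  # 1/mm
  expect_lt(abs(wr - closed) / closed, 0.005)
  bl <- make_solenoid_backbone(contour_length = 420, m = 2,
                               pitch_angle_deg = 10, handedness = -1L,
                               n_points = 1000L)
  expect_equal(polar_writhe(bl), -wr, tolerance = 1e-9)
  # straight rod: zero writhe
  rod <- extract_backbone(make_straight_rod(contour_length = 102,
                                            n_points = 300L), 0L)
  expect_lt(abs(polar_writhe(rod, presmooth = NULL)), 1e-9)
})

test_that("a turning point in u raises an error naming the abscissa", {
  s <- seq(0, pi, length.out = 400)
  hook <- cbind(50 * sin(s), 0.5 * s, 50 * (1 - cos(s)))  # folds back in z
  hook <- sweep(hook, 2, colMeans(hook))
  bb <- structure(list(positions = hook, ds = 1, contour_length = 400,
                       n = 400L), class = "backbone_curve")
  expect_error(polar_writhe(bb, frame = molecular_frame(u = c(0, 0, 1),
                                                        v = c(1, 0, 0))),
               "turning point.*s = ")
})

test_that("degenerate duplex geometry (antiparallel normals) is rejected", {
  g <- bundle_geometry(bp_count = 60L, rise = 0.34, bp_per_turn = 150)
  rod <- make_straight_rod(contour_length = 20.4, n_points = 60L,
                           geometry = g)
  sel <- rod$duplex_id == 0 & rod$strand_id == 1 & rod$bp_index == 30
  sel2 <- rod$duplex_id == 0 & rod$strand_id == 2 & rod$bp_index == 30
  p1 <- rod$positions[sel, ]; p2 <- rod$positions[sel2, ]
  rod$positions[sel, ] <- p2; rod$positions[sel2, ] <- p1  # swap -> n flips
  expect_error(duplex_twist(rod, trim_bp = 0L), "antiparallel")
})

test_that("ensemble statistics reproduce the overwound-design pattern", {
  tw <- fx_lh_twistwrithe()  # designed +7 turns/um
  expect_gt(tw$writhe_mean, 3 * tw$writhe_se)
  expect_gt(tw$overtwist_mean, 0)
  expect_lt(tw$overtwist_mean, 7)
  expect_equal(tw$n_writhe_failed, 0L)
  # twist-writhe coupling: conformations with more writhe carry less twist
  expect_lt(tw$coupling, 0)
  # cross-module sign consistency with the helicity bias at low k
  es <- fx_lh_helicity()
  expect_equal(sign(es$H_mean[2]), sign(tw$writhe_mean))
  tab <- twist_writhe_table(overwound = tw, initial_overtwist = 7)
  expect_equal(tab$design, "overwound")
  expect_equal(tab$initial_overtwist_turns_um, 7)
})

test_that("achiral ensembles are null in both twist and writhe", {
  tw <- ensemble_twist_writhe(fx_achiral_ensemble())
  expect_lt(abs(tw$writhe_mean), 2 * tw$writhe_se)
  expect_lt(abs(tw$overtwist_mean), 2 * tw$overtwist_se)
})
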
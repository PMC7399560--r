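# Debye screening, pair energies, Mayer averages

test_that("the Debye length matches the experimental salt conditions", {
  expect_equal(debye_length(0.26, 293), 0.6, tolerance = 0.02)
  # inverse-square-root law
  expect_equal(debye_length(4 * 0.26, 293), debye_length(0.26, 293) / 2,
               tolerance = 1e-12)
  # the 0.5 M simulation setting screens harder than the 0.26 M assay
  expect_lt(debye_length(0.5, 293), debye_length(0.26, 293))
})

test_that("pair energies vanish beyond reach, diverge on overlap, and match a brute-force sum", {
  mod <- interaction_model()
  rod <- make_straight_rod(contour_length = 20.4, n_points = 60L)
  # far apart: exactly zero
  e_far <- pair_energy(rod, rod, r12 = c(0, 0, 500), model = mod,
                       trim_bp = 2L)
  expect_identical(e_far, 0)
  # coincident copies: hard overlap
  e_on <- pair_energy(rod, rod, r12 = c(0, 0, 0), model = mod, trim_bp = 2L)
  expect_identical(e_on, Inf)
  # near-contact crossed pair: C++ (hierarchy-culled) energy equals a plain
  # R double sum over all site pairs
  set.seed(8)
  R2 <- rotation_about(c(0, 0, 1), pi / 3)
  r12 <- c(1.2, 0.8, 6.6)
  e_cpp <- pair_energy(rod, rod, r12 = r12, R2 = R2, model = mod,
                       trim_bp = 2L)
  A <- body_frame_sites(rod, 2L)
  B <- sweep(body_frame_sites(rod, 2L) %*% t(R2), 2, r12, `+`)
  dd <- sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B))
  if (any(dd < mod$site_diameter)) {
    e_ref <- Inf
  } else {
    sel <- dd < mod$cutoff
    e_ref <- sum(mod$prefactor * exp(-dd[sel] / mod$debye_length) / dd[sel])
  }
  expect_equal(e_cpp, e_ref, tolerance = 1e-10)
})

test_that("screened-Coulomb prefactor reproduces a hand-computed value", {
  mod <- interaction_model(site_charge = 1)
  # two unit charges at one Debye length: q^2 lB exp(-1) / lambda_D
  expect_equal(mod$prefactor * exp(-1) / mod$debye_length,
               bjerrum_length(293, 80.1) * exp(-1) / debye_length(0.26, 293),
               tolerance = 1e-12)
})

test_that("Mayer averages behave at their limits", {
  sc <- spherocylinder(5, 1)
  # guaranteed overlap at touching-perpendicular: f = -1
  m1 <- mayer_average(sc, r12 = c(0, 0, 0.5),
                      R2 = rotation_about(c(0, 0, 1), pi / 2),
                      n_samples = 10L, seed = 1L)
  expect_equal(m1$mean, -1)
  # infinite separation: f = 0
  m0 <- mayer_average(sc, r12 = c(0, 0, 100), n_samples = 10L, seed = 1L)
  expect_equal(m0$mean, 0)
  # single-conformation ensemble reduces to the single-pair Mayer function
  rod <- make_straight_rod(contour_length = 20.4, n_points = 60L)
  ens1 <- conformation_ensemble(list(rod))
  mod <- interaction_model()
  r12 <- c(1, 0.4, 6.8)
  mm <- mayer_average(ens1, r12 = r12, model = mod, n_samples = 25L,
                      seed = 2L, trim_bp = 2L)
  e <- pair_energy(rod, rod, r12 = r12, model = mod, trim_bp = 2L)
  expect_equal(mm$mean, if (is.infinite(e)) -1 else expm1(-e),
               tolerance = 1e-12)
  expect_equal(mm$se, 0, tolerance = 1e-12)
  # purely repulsive interactions keep f in [-1, 0]
  expect_gte(mm$mean, -1)
  expect_lte(mm$mean, 0)
})
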
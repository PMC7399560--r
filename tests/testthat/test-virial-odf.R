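# Monte Carlo kernel vs the closed-form excluded-volume oracle, the
# self-consistent orientation distribution, and coexistence

test_that("the MC kernel of hard spherocylinders matches the excluded-volume formula", {
  kr <- fx_sph_kernel()
  Kan <- bin_averaged_rod_kernel(5, 1, 20L)
  d_mc <- diag(kr$kappa); d_an <- diag(Kan); d_se <- diag(kr$se)
  # diagonal agrees with the closed form within the ~2% MC error
  expect_lt(max(abs(d_mc - d_an) / pmax(abs(d_an), 1)), 0.08)
  expect_lt(mean(abs(d_mc - d_an) / abs(d_an)), 0.02)
  expect_true(all(abs(d_mc - d_an) < 3.5 * d_se))
  # exchange symmetry within joint MC error
  z_sym <- abs(kr$kappa - t(kr$kappa)) /
    (sqrt(kr$se^2 + t(kr$se)^2) + 1e-12)
  expect_lt(max(z_sym[upper.tri(z_sym)]), 4)
  # repulsion only: every entry negative, on the excluded-volume scale
  expect_true(all(kr$kappa < 0))
})

test_that("doubling the MC budget shrinks the kernel error like 1/sqrt(2)", {
  sc <- spherocylinder(5, 1)
  k1 <- virial_kernel(sc, n_bins = 20L, mc_budget = 4e5, seed = 3L)
  k2 <- virial_kernel(sc, n_bins = 20L, mc_budget = 8e5, seed = 3L)
  ratio <- mean(k2$se) / mean(k1$se)
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 0.82)
  # an impossibly small budget leaves empty bins and errors out
  expect_error(virial_kernel(sc, n_bins = 20L, mc_budget = 200, seed = 1L),
               "empty")
})

test_that("the orientation distribution solves its own fixed point", {
  kn <- onsager_rod_kernel(100, 1, n_nodes = 48L, include_end_terms = FALSE)
  b <- pi / 4 * 100^2
  od <- solve_odf(kn, 4.5 / b)
  expect_gt(od$S, 0.7)  # classical strongly nematic branch
  # psi is a probability density, even in cos theta
  expect_equal(sum(od$w * od$psi), 1, tolerance = 1e-10)
  expect_equal(od$psi, rev(od$psi), tolerance = 1e-8)
  expect_true(all(od$psi >= 0))
  # substituting psi back into the right-hand side reproduces it
  g <- od$rho * as.vector(kn$kappa %*% (kn$w * od$psi))
  rhs <- exp(g - max(g)); rhs <- rhs / sum(kn$w * rhs)
  expect_lt(max(abs(rhs - od$psi)), 1e-8)
  # ideal-gas limit: isotropic
  od0 <- solve_odf(kn, 1e-12)
  expect_lt(max(abs(od0$psi - 0.5)), 1e-8)
})

test_that("Picard and direct free-energy minimization agree", {
  kn <- onsager_rod_kernel(100, 1, n_nodes = 40L, include_end_terms = FALSE)
  b <- pi / 4 * 100^2
  rho <- 4.5 / b
  od <- solve_odf(kn, rho)
  oracle <- oracle_minimize_f(kn, rho)
  expect_equal(od$S, oracle$S, tolerance = 0.01)
  f_picard <- virial_thermodynamics(kn, rho, od)$f
  expect_lt(abs(f_picard - oracle$f) / abs(oracle$f), 1e-4)
})

test_that("the chemical potential is the exact density derivative of the free energy", {
  kn <- onsager_rod_kernel(100, 1, n_nodes = 40L, include_end_terms = FALSE)
  b <- pi / 4 * 100^2
  rho <- 4.3 / b
  h <- 1e-4 * rho
  f <- function(r) {
    o <- solve_odf(kn, r, tolerance = 1e-13)
    virial_thermodynamics(kn, r, o)$f
  }
  mu_num <- (f(rho + h) - f(rho - h)) / (2 * h)
  o <- solve_odf(kn, rho, tolerance = 1e-13)
  th <- virial_thermodynamics(kn, rho, o)
  expect_lt(abs(mu_num - th$mu) / abs(th$mu), 1e-6)
  # Gibbs-Duhem closure: Pi = rho mu - f at the self-consistent solution
  expect_equal(th$Pi, rho * th$mu - th$f, tolerance = 1e-10)
})

test_that("needle-limit coexistence reproduces the classical hard-rod solution", {
  kn <- onsager_rod_kernel(100, 1, n_nodes = 48L, include_end_terms = FALSE)
  b <- pi / 4 * 100^2
  bn <- binodal(kn, bp_count = 1000L)
  # classical dimensionless coexistence concentrations 3.290 / 4.191
  expect_equal(bn$rho_iso * b, 3.290, tolerance = 0.01)
  expect_equal(bn$rho_chol * b, 4.191, tolerance = 0.01)
  expect_equal(bn$S_chol, 0.792, tolerance = 0.01)
  expect_gt(bn$rho_chol, bn$rho_iso)
  expect_lt(max(abs(bn$residuals)), 1e-8)
  expect_equal(bn$c_iso, mass_concentration(bn$rho_iso, 1000L))
  # independent oracle: common-tangent construction on direct grid
  # minimization of the functional
  oc <- oracle_coexistence(kn, seq(2.8, 5.0, length.out = 25) / b)
  expect_equal(bn$rho_iso, oc[1], tolerance = 0.02)
  expect_equal(bn$rho_chol, oc[2], tolerance = 0.02)
})

test_that("finite-aspect spherocylinders order and phase-separate sensibly", {
  sc <- spherocylinder(5, 1)
  kr <- virial_kernel(sc, n_bins = 24L, mc_budget = 4e6, seed = 2L)
  bn <- binodal(kr)
  expect_gt(bn$rho_chol, bn$rho_iso)
  expect_gt(bn$S_chol, 0.5)
  expect_lt(max(abs(bn$residuals)), 1e-8)
})
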
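# Elastic constants, pitch, chiral PMF

test_that("achiral hard rods have positive K2 and vanishing chiral strength", {
  sc <- spherocylinder(5, 1)
  kr <- virial_kernel(sc, n_bins = 24L, mc_budget = 3e6, seed = 2L)
  bn <- binodal(kr)
  od <- solve_odf(kr, 1.15 * bn$rho_chol)
  el <- elastic_constants(sc, odf = od, kernel = kr, mc_budget = 3e6,
                          seed = 3L)
  expect_gt(el$K2, 2 * el$K2_se)                # twist rigidity is real
  expect_lt(abs(el$kt), 2 * el$kt_se)           # parity forbids kt
  # K2 grows with density across the nematic branch (common random numbers)
  od2 <- solve_odf(kr, 1.35 * bn$rho_chol)
  el2 <- elastic_constants(sc, odf = od2, kernel = kr, mc_budget = 3e6,
                           seed = 3L)
  expect_gt(el2$K2, el$K2)
})

test_that("pitch arithmetic, signs and flags follow P = 2 pi K2 / kt", {
  p <- pitch(1, kt = 2 * pi * 1e-6)
  expect_equal(p$pitch_um, 1000)  # 1 mm
  pn <- pitch(1, kt = -2 * pi * 1e-6)
  expect_equal(pn$pitch_um, -1000)
  p0 <- pitch(1, kt = 0)
  expect_true(p0$unwound)
  pa <- pitch(1, kt = 1e-9, kt_se = 1e-6)
  expect_true(pa$achiral_within_error)
})

test_that("mirroring a chiral ensemble flips kt and the pitch but not K2", {
  el <- fx_standin_elastic()
  elm <- fx_standin_mirror_elastic()
  kr <- fx_standin_kernel(); krm <- fx_standin_mirror_kernel()
  # kt is a pseudoscalar; K2 and the achiral kernel are parity-even
  expect_lt(abs(el$kt + elm$kt), 3 * sqrt(el$kt_se^2 + elm$kt_se^2))
  expect_lt(abs(el$K2 - elm$K2), 3 * sqrt(el$K2_se^2 + elm$K2_se^2))
  expect_lt(max(abs(kr$kappa - krm$kappa) /
                  (sqrt(kr$se^2 + krm$se^2) + 1e-12)), 4.5)
  expect_gt(abs(el$kt), 2 * el$kt_se)  # the chirality itself is resolved
  expect_equal(sign(pitch(el)$pitch_um), -sign(pitch(elm)$pitch_um))
})

test_that("the chiral PMF scan is even for achiral particles and normalized at zero", {
  sc <- spherocylinder(5, 1)
  pm <- chiral_pmf(sc, gamma_grid = seq(-60, 60, by = 15), mc_budget = 2e5,
                   seed = 4L, d_max = 2)
  expect_equal(pm$curve$W[pm$curve$gamma_deg == 0], 0)
  Wp <- pm$curve$W[pm$curve$gamma_deg > 0]
  Wm <- rev(pm$curve$W[pm$curve$gamma_deg < 0])
  expect_lt(max(abs(Wp - Wm)), 4 * max(pm$curve$se) * sqrt(2))
})

test_that("a right-handed solenoid ensemble prefers opposite-handed pair arrangements", {
  ens <- fx_standin_thermal()  # overwound -> right-handed writhe
  mod <- steric_model()
  pm <- chiral_pmf(ens, mod, gamma_grid = c(-30, 0, 30), mc_budget = 1.2e5,
                   seed = 6L, trim_bp = 5L)
  iL <- which(pm$curve$gamma_deg == -30)
  iR <- which(pm$curve$gamma_deg == 30)
  dW <- pm$curve$W[iR] - pm$curve$W[iL]
  se <- sqrt(pm$curve$se[iR]^2 + pm$curve$se[iL]^2)
  expect_gt(dW, 2 * se)  # left-handed crossing is cheaper
  expect_lt(pm$gamma_star, 0)
})

test_that("bootstrap pitch dispersion reporting honours its threshold contract", {
  ens <- fx_standin_thermal()
  small <- conformation_ensemble(ens$conformations[1:4])
  bs <- bootstrap_pitch(small, steric_model(), rho = 4.5e-4, n_runs = 3L,
                        mc_budget = 4e5, seed = 9L, trim_bp = 5L)
  expect_length(bs$pitches_um, 3L)
  expect_true(is.finite(bs$dispersion))
  expect_identical(bs$pass, is.finite(bs$dispersion) &&
                     bs$dispersion < bs$threshold)
})
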
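# Shared fixtures (memoized per test session) and independent oracles.
# All fixture sizes are deliberately scaled down from the full 420-nm,
# 1235-bp study filaments so the whole suite runs on one core; seeds are
# fixed so every statistic below is reproducible bit-for-bit.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

# full-geometry ensembles (420 nm, bp-true rise) for twist-writhe and
# helicity statistics
full_geometry <- function() bundle_geometry(bp_count = 1235L, rise = 420 / 1235)

full_params <- function() chain_parameters(
  contour_length = 420, segment_length = 420 / 1235,
  persistence_length = 8 * 420)

fx_lh_ensemble <- function() memo("lh_full", generate_ensemble(
  full_params(), full_geometry(), linking_target(design_overtwist = 7),
  n = 60L, seed = 5L, design_label = "overwound"))

fx_achiral_ensemble <- function() memo("achiral_full", generate_ensemble(
  full_params(), full_geometry(), linking_target(0),
  n = 40L, seed = 9L, design_label = "relaxed"))

# desk-scale chiral stand-in for the virial stage: 60 nm contour at
# bp-true rise; designed overtwist = the 1x design's total overtwist
# (~2.9 turns over the contour) mapped onto the shorter filament
standin_geometry <- function() {
  nbp <- round(60 / 0.34)
  bundle_geometry(bp_count = nbp, rise = 60 / nbp)
}

fx_standin_thermal <- function() memo("standin_thermal", {
  g <- standin_geometry()
  p <- chain_parameters(contour_length = 60, segment_length = 60 / g$bp_count,
                        persistence_length = 8 * 60)
  generate_ensemble(p, g, linking_target(design_overtwist = 49),
                    n = 10L, seed = 11L, design_label = "standin-1x-lh")
})

fx_standin_ground <- function() memo("standin_ground", {
  g <- standin_geometry()
  p <- chain_parameters(contour_length = 60, segment_length = 60 / g$bp_count,
                        persistence_length = 1e9)
  gs <- decorate_bundle(sample_centerline(p), g,
                        linking = linking_target(design_overtwist = 49),
                        design_label = "standin-1x-lh-ground")
  conformation_ensemble(list(gs, gs))
})

# ---- independent oracles ---------------------------------------------------

# Direct minimization of the discretized Onsager functional over psi grid
# values (L-BFGS on unconstrained log-weights): the brute-force counterpart
# of the Picard fixed point.
oracle_minimize_f <- function(kernel, rho) {
  x <- kernel$x; w <- kernel$w; M <- -kernel$kappa
  nf <- function(theta) {
    p <- exp(theta - max(theta))
    p <- p / sum(w * p)
    sig <- sum(w * p * log(pmax(2 * p, 1e-300)))
    E <- as.numeric(t(w * p) %*% M %*% (w * p))
    rho * (log(rho) - 1) + rho * sig + rho^2 / 2 * E
  }
  opt <- list(par = 10 * x^2, value = Inf)
  for (restart in 1:3) {
    opt2 <- stats::optim(opt$par, nf, method = "BFGS",
                         control = list(maxit = 5000, reltol = 1e-15))
    if (opt2$value <= opt$value) opt <- opt2
  }
  p <- exp(opt$par - max(opt$par))
  p <- p / sum(w * p)
  list(psi = p, f = opt$value, S = sum(w * p * p2_legendre_helper(x)))
}

p2_legendre_helper <- function(x) 0.5 * (3 * x^2 - 1)

# free energy at fixed psi (matches the package convention)
oracle_free_energy <- function(kernel, rho, psi) {
  w <- kernel$w; M <- -kernel$kappa
  sig <- sum(w * psi * log(pmax(2 * psi, 1e-300)))
  E <- as.numeric(t(w * psi) %*% M %*% (w * psi))
  rho * (log(rho) - 1) + rho * sig + rho^2 / 2 * E
}

# Coexistence by direct construction: minimize F on a density grid for both
# branches and find the common tangent (equal slope and intercept of F(rho)),
# independent of the package's Newton solver.
oracle_coexistence <- function(kernel, rho_grid) {
  f_iso <- vapply(rho_grid, function(r)
    oracle_free_energy(kernel, r, rep(0.5, length(kernel$x))), numeric(1))
  f_nem <- vapply(rho_grid, function(r)
    oracle_minimize_f(kernel, r)$f, numeric(1))
  mu_iso <- splinefun(rho_grid, f_iso)
  mu_nem <- splinefun(rho_grid, f_nem)
  res <- function(p) {
    m1 <- mu_iso(p[1], deriv = 1); m2 <- mu_nem(p[2], deriv = 1)
    pi1 <- p[1] * m1 - mu_iso(p[1]); pi2 <- p[2] * m2 - mu_nem(p[2])
    c(m1 - m2, pi1 - pi2)
  }
  p <- c(rho_grid[which.min(abs(rho_grid - 0.9 * mean(rho_grid)))],
         mean(rho_grid))
  for (it in 1:200) {
    r0 <- res(p)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      dp <- p; dp[j] <- dp[j] * (1 + 1e-6)
      J[, j] <- (res(dp) - r0) / (p[j] * 1e-6)
    }
    step <- solve(J, r0)
    p <- p - pmin(pmax(step, -0.1 * p), 0.1 * p)
    if (max(abs(r0)) < 1e-10) break
  }
  p
}

# Exact equipartition spectrum of the discrete harmonic chain: transverse
# displacement = ds * double cumulative sum of iid bending angles
# (variance ds / l_p per transverse component), with the mean and best-fit
# linear trend removed (the discrete analogue of centering the backbone
# and projecting out the adapted long axis), then the same exponential-sum
# transform the package uses. Pure linear algebra; no sampling.
oracle_wlc_spectrum <- function(n, ds, lp) {
  m <- n - 1L
  A <- matrix(0, n, m)
  for (i in 2:n) {
    j <- 1:(i - 1)
    A[i, j] <- ds * (i - j)
  }
  s <- (1:n) * ds
  X <- cbind(1, s)
  Q <- diag(n) - X %*% solve(crossprod(X)) %*% t(X)
  B <- Q %*% A
  FT <- exp(-2i * pi * outer(0:(n %/% 2), (0:(n - 1)) / n))
  C <- (FT %*% B) * ds
  2 * rowSums(Mod(C)^2) * (ds / lp)  # both transverse components
}

# ---- memoized virial-stage products (shared across test files) -------------

fx_standin_model <- function() steric_model()

fx_standin_kernel <- function() memo("standin_kernel",
  virial_kernel(fx_standin_thermal(), fx_standin_model(), n_bins = 20L,
                mc_budget = 1e6, seed = 2L, trim_bp = 5L))

fx_standin_odf <- function() memo("standin_odf",
  solve_odf(fx_standin_kernel(), 4.5e-4))

fx_standin_elastic <- function() memo("standin_elastic",
  elastic_constants(fx_standin_thermal(), fx_standin_model(),
                    fx_standin_odf(), fx_standin_kernel(),
                    mc_budget = 8e6, seed = 3L, trim_bp = 5L))

fx_standin_mirror <- function() memo("standin_mirror",
  mirror_ensemble(fx_standin_thermal()))

fx_standin_mirror_kernel <- function() memo("standin_mirror_kernel",
  virial_kernel(fx_standin_mirror(), fx_standin_model(), n_bins = 20L,
                mc_budget = 1e6, seed = 2L, trim_bp = 5L))

fx_standin_mirror_elastic <- function() memo("standin_mirror_elastic", {
  odm <- solve_odf(fx_standin_mirror_kernel(), 4.5e-4)
  elastic_constants(fx_standin_mirror(), fx_standin_model(), odm,
                    fx_standin_mirror_kernel(), mc_budget = 8e6, seed = 3L,
                    trim_bp = 5L)
})

fx_ground_kernel <- function() memo("ground_kernel",
  virial_kernel(fx_standin_ground(), fx_standin_model(), n_bins = 20L,
                mc_budget = 1e6, seed = 2L, trim_bp = 5L))

fx_ground_elastic <- function() memo("ground_elastic", {
  odg <- solve_odf(fx_ground_kernel(), 4.5e-4)
  elastic_constants(fx_standin_ground(), fx_standin_model(), odg,
                    fx_ground_kernel(), mc_budget = 1.2e7, seed = 3L,
                    trim_bp = 5L)
})

fx_sph_kernel <- function() memo("sph_kernel",
  virial_kernel(spherocylinder(5, 1), n_bins = 20L, mc_budget = 1.6e7,
                seed = 2L))

fx_lh_twistwrithe <- function() memo("lh_twistwrithe",
  ensemble_twist_writhe(fx_lh_ensemble()))

fx_lh_helicity <- function() memo("lh_helicity",
  ensemble_helicity(fx_lh_ensemble()))

cross3_helper <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# analytic kernel averaged over each equal-width cos-theta bin (so the MC
# estimate, which is a bin average, is compared like for like)
bin_averaged_rod_kernel <- function(length, diameter, n_bins, n_sub = 8L,
                                    n_phi = 256L) {
  dx <- 2 / n_bins
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  centers <- -1 + dx * (seq_len(n_bins) - 0.5)
  sub <- seq(-dx / 2, dx / 2, length.out = n_sub + 1)
  sub <- (sub[-1] + sub[-length(sub)]) / 2
  K <- matrix(0, n_bins, n_bins)
  for (a in seq_len(n_bins)) for (b in seq_len(n_bins)) {
    acc <- 0
    for (xa in centers[a] + sub) for (xb in centers[b] + sub) {
      cg <- xa * xb + sqrt(1 - xa^2) * sqrt(1 - xb^2) * cos(phi)
      cg <- pmax(pmin(cg, 1), -1)
      acc <- acc + mean(spherocylinder_excluded_volume(acos(cg), length,
                                                      diameter))
    }
    K[a, b] <- -acc / n_sub^2
  }
  K
}


# larger draw of the same stand-in conditions, used where ensemble-level
# statistics (not the virial stage) need tighter standard errors
fx_standin_big <- function() memo("standin_big", {
  g <- standin_geometry()
  p <- chain_parameters(contour_length = 60, segment_length = 60 / g$bp_count,
                        persistence_length = 8 * 60)
  generate_ensemble(p, g, linking_target(design_overtwist = 49),
                    n = 36L, seed = 17L, design_label = "standin-1x-lh")
})
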
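# Self-consistent orientation distribution, second-virial free energy and
# isotropic-cholesteric coexistence.
#
# Free energy per volume (kT units, densities in 1/nm^3):
#   beta F / V = rho (ln rho - 1) + rho * integral psi ln(2 psi) dx
#                + (rho^2 / 2) * E[psi],
#   E[psi] = - integral integral psi(x) psi(x') kappa(x, x') dx dx'
# with x = cos theta. Functional minimization at fixed rho gives the
# fixed-point equation psi = exp(rho * integral psi kappa) / Z, solved by
# Picard iteration with under-relaxation. Chemical potential and osmotic
# pressure follow by differentiation at the self-consistent psi:
#   beta mu = ln rho + integral psi ln(2 psi) + rho E,
#   beta Pi = rho + (rho^2 / 2) E.

#' Solve the self-consistent orientation distribution
#'
#' @param kernel a `virial_kernel`.
#' @param rho number density, 1/nm^3.
#' @param tolerance convergence threshold on max |psi change|.
#' @param mixing Picard under-relaxation factor in (0, 1].
#' @param init `"nematic"` (anisotropic seed, returns the nematic branch
#'   when it exists) or `"isotropic"`, or a numeric vector of initial psi
#'   values on the kernel grid.
#' @param max_iter iteration cap.
#' @return an object of class `orientation_distribution`: grid `x`,
#'   weights `w`, `psi`, normalization `Z`, `rho`, order parameter `S`,
#'   iteration count and final residual.
#' @export
solve_odf <- function(kernel, rho, tolerance = 1e-10, mixing = 0.5,
                      init = c("nematic", "isotropic"), max_iter = 20000L) {
  stopifnot(inherits(kernel, "virial_kernel"), rho >= 0)
  x <- kernel$x; w <- kernel$w; K <- kernel$kappa
  psi <- if (is.numeric(init)) {
    init / sum(w * init)
  } else {
    init <- match.arg(init)
    if (init == "nematic") {
      p <- exp(5 * x^2); p / sum(w * p)
    } else rep(1 / 2, length(x))
  }
  residual <- Inf
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    g <- rho * as.vector(K %*% (w * psi))
    g <- g - max(g)  # overflow guard; absorbed in Z
    pnew <- exp(g)
    pnew <- pnew / sum(w * pnew)
    residual <- max(abs(pnew - psi))
    psi <- (1 - mixing) * psi + mixing * pnew
    hist <- c(hist, residual)
    if (residual < tolerance) break
  }
  if (residual >= tolerance)
    stop("orientation distribution did not converge in ", max_iter,
         " iterations; last residuals: ",
         paste(signif(utils::tail(hist, 5), 3), collapse = ", "))
  g <- rho * as.vector(K %*% (w * psi))
  Z <- sum(w * exp(g - max(g))) * exp(max(g))
  structure(list(
    x = x, w = w, psi = psi, Z = Z, rho = rho,
    S = sum(w * psi * p2_legendre(x)),
    iterations = it, residual = residual, kernel_mode = kernel$mode
  ), class = "orientation_distribution")
}

#' @export
print.orientation_distribution <- function(x, ...) {
  cat(sprintf(
    "<orientation_distribution> rho = %.4g nm^-3, S = %.4f (%d iterations)\n",
    x$rho, x$S, x$iterations))
  invisible(x)
}

#' Nematic order parameter
#'
#' <P2(cos theta)> under an orientation distribution.
#'
#' @param odf an `orientation_distribution`.
#' @return scalar order parameter S.
#' @export
order_parameter <- function(odf) odf$S

# E[psi] (nm^3): minus the double kernel average
pair_excess <- function(kernel, psi) {
  -as.numeric(t(kernel$w * psi) %*% kernel$kappa %*% (kernel$w * psi))
}

#' Second-virial thermodynamics at a state point
#'
#' Free-energy density, chemical potential and osmotic pressure (all in
#' kT units) of either the isotropic state or a converged nematic
#' solution.
#'
#' @param kernel a `virial_kernel`.
#' @param rho number density, 1/nm^3.
#' @param odf optional `orientation_distribution`; isotropic when NULL.
#' @return list with `f`, `mu`, `Pi`, `S`, `E`.
#' @export
virial_thermodynamics <- function(kernel, rho, odf = NULL) {
  if (is.null(odf)) {
    psi <- rep(1 / 2, length(kernel$x)); S <- 0; sig <- 0
  } else {
    psi <- odf$psi; S <- odf$S
    sig <- sum(kernel$w * psi * log(pmax(2 * psi, 1e-300)))
  }
  E <- pair_excess(kernel, psi)
  list(f = rho * (log(rho) - 1) + rho * sig + rho^2 / 2 * E,
       mu = log(rho) + sig + rho * E,
       Pi = rho + rho^2 / 2 * E,
       S = S, E = E)
}

#' Convert number density to mass concentration
#'
#' Assumes 650 Da per base pair.
#'
#' @param rho number density in 1/nm^3.
#' @param bp_count base pairs per filament (all duplexes summed).
#' @return concentration in g/L.
#' @export
mass_concentration <- function(rho, bp_count) {
  rho * bp_count * .const$bp_mass_da / .const$avogadro * 1e24
}

#' Isotropic-nematic/cholesteric coexistence
#'
#' Solves the coupled coexistence conditions mu_iso(rho_i) =
#' mu_nem(rho_n), Pi_iso(rho_i) = Pi_nem(rho_n) by Newton iteration with a
#' numeric Jacobian, bracketing the nematic branch from a density scan.
#' The chiral contribution to the free energy (kt^2 / 2 K2 per volume) is
#' many orders of magnitude below f0 at typical pitches and is neglected
#' in the coexistence conditions, so the cholesteric binodal coincides
#' with the nematic one at second-virial level.
#'
#' @param kernel a `virial_kernel`.
#' @param bp_count base pairs per filament, for g/L conversion.
#' @param rho_bracket optional c(lo, hi) density bracket (1/nm^3); scanned
#'   automatically from the kernel scale when NULL.
#' @param tolerance residual tolerance on (mu, Pi) mismatch.
#' @param max_iter Newton iteration cap.
#' @return an object of class `phase_boundary`: `rho_iso`, `rho_chol`,
#'   `c_iso`, `c_chol` (g/L), order parameter at coexistence, chemical
#'   potential/pressure and residuals.
#' @export
binodal <- function(kernel, bp_count = NULL, rho_bracket = NULL,
                    tolerance = 1e-9, max_iter = 100L) {
  iso_E <- pair_excess(kernel, rep(1 / 2, length(kernel$x)))
  if (is.null(rho_bracket)) {
    # scan upward from the classical Onsager scale until the nematic branch
    # is clearly stable
    rho0 <- 3 / iso_E * 2 / 2  # ~ c = 3 in units of the iso excess
    rho_bracket <- c(0.3 * rho0, 6 * rho0)
  }
  scan <- exp(seq(log(rho_bracket[1]), log(rho_bracket[2]), length.out = 40))
  odf_prev <- "nematic"
  branch <- lapply(scan, function(r) {
    o <- tryCatch(solve_odf(kernel, r, init = odf_prev),
                  error = function(e) NULL)
    o
  })
  Sv <- vapply(branch, function(o) if (is.null(o)) 0 else o$S, numeric(1))
  nem_idx <- which(Sv > 0.45)
  if (!length(nem_idx))
    stop("no nematic branch found in the scanned bracket [",
         signif(rho_bracket[1], 3), ", ", signif(rho_bracket[2], 3),
         "] nm^-3; order parameters: ", paste(signif(Sv, 2), collapse = " "))
  i0 <- min(nem_idx[1] + 1, length(scan))
  rho_n <- scan[i0]
  rho_floor <- 0.85 * scan[nem_idx[1]]
  rho_i <- 0.85 * rho_n
  psi_prev <- branch[[i0]]$psi

  nem_thermo <- function(r) {
    o <- tryCatch(solve_odf(kernel, r, init = psi_prev),
                  error = function(e) solve_odf(kernel, r, init = "nematic"))
    if (o$S < 0.2) {  # fell back to isotropic; retry with a sharper seed
      p0 <- exp(20 * kernel$x^2)
      o <- solve_odf(kernel, r, init = p0 / sum(kernel$w * p0))
    }
    if (o$S < 0.2)
      stop("nematic branch lost at rho = ", signif(r, 4))
    psi_prev <<- o$psi
    virial_thermodynamics(kernel, r, o)
  }
  resid <- function(p) {
    ti <- virial_thermodynamics(kernel, p[1])
    tn <- nem_thermo(p[2])
    c(ti$mu - tn$mu, ti$Pi - tn$Pi)
  }
  p <- c(rho_i, rho_n)
  for (it in seq_len(max_iter)) {
    r0 <- resid(p)
    if (max(abs(r0)) < tolerance) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      dp <- p; h <- 1e-6 * p[j]
      dp[j] <- dp[j] + h
      J[, j] <- (resid(dp) - r0) / h
    }
    step <- tryCatch(solve(J, r0), error = function(e)
      stop("singular Jacobian in coexistence solve at rho = (",
           signif(p[1], 4), ", ", signif(p[2], 4), ")"))
    lam <- 1
    repeat {
      pn <- p - lam * step
      if (all(pn > 0) && pn[2] > pn[1] && pn[2] > rho_floor) break
      lam <- lam / 2
      if (lam < 1e-6) stop("coexistence solve collapsed: densities crossed")
    }
    p <- pn
  }
  r0 <- resid(p)
  if (max(abs(r0)) >= tolerance)
    stop("coexistence equations not converged: residuals ",
         paste(signif(r0, 3), collapse = ", "))
  on <- solve_odf(kernel, p[2], init = "nematic")
  ti <- virial_thermodynamics(kernel, p[1])
  structure(list(
    rho_iso = p[1], rho_chol = p[2],
    c_iso = if (is.null(bp_count)) NA_real_ else mass_concentration(p[1], bp_count),
    c_chol = if (is.null(bp_count)) NA_real_ else mass_concentration(p[2], bp_count),
    S_chol = on$S, mu = ti$mu, Pi = ti$Pi,
    residuals = r0, iterations = it
  ), class = "phase_boundary")
}

#' @export
print.phase_boundary <- function(x, ...) {
  cat("<phase_boundary>\n")
  cat(sprintf("  rho_iso = %.5g nm^-3, rho_chol = %.5g nm^-3 (S = %.3f)\n",
              x$rho_iso, x$rho_chol, x$S_chol))
  if (!is.na(x$c_iso))
    cat(sprintf("  c_iso = %.2f g/L, c_chol = %.2f g/L\n", x$c_iso, x$c_chol))
  cat(sprintf("  residuals: %.2e (mu), %.2e (Pi)\n",
              x$residuals[1], x$residuals[2]))
  invisible(x)
}
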
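#' Mean-field configuration
#'
#' Parameters of the Bragg-Williams mean-field treatment of the raft
#' lattice gas with receptor binding entering through the membrane
#' contact probability Pb (the equilibrium fraction of patches inside the
#' binding well in the homogeneous reference system).
#'
#' @param x Raft area fraction in (0, 1).
#' @param cR,cL Receptor and ligand concentrations, um^-2.
#' @param u Raft-raft contact energy, kBT.
#' @param ua Raft-receptor affinity, kBT.
#' @param ub Binding-well depth, kBT.
#' @param Pb Contact probability in `[0, 1]`.
#' @param z Lattice coordination number (4 for the square lattice).
#' @param a Lattice constant, nm (for concentration conversion).
#' @return An `mf_config`.
#' @export
mf_config <- function(x = 0.2, cR = 0, cL = 1000, u = 1, ua = 3, ub = 6,
                      Pb = 0.1, z = 4, a = 10) {
  stopifnot(x > 0, x < 1, cR >= 0, cL >= 0, u >= 0, Pb >= 0, Pb <= 1,
            z == 4)
  structure(list(x = x, cR = cR, cL = cL, u = u, ua = ua, ub = ub,
                 Pb = Pb, z = z, a = a), class = "mf_config")
}

# Grand-canonical receptor sector: per-patch receptor density r and
# ligand density rhoL; binding enters through the excess Boltzmann
# weight b = Pb * rhoL * (e^ub - 1); the receptor fugacity A is fixed so
# that the homogeneous phase at the global raft fraction x carries
# receptor occupancy r.
mf_aux <- function(cfg) {
  patch <- cfg$a^2 * 1e-6  # um^2 per patch
  r <- cfg$cR * patch
  b <- cfg$Pb * cfg$cL * patch * (exp(cfg$ub) - 1)
  A <- if (r > 0) r / ((1 - r) * (1 + b) * exp(cfg$ua * cfg$x)) else 0
  list(r = r, rhoL = cfg$cL * patch, b = b, A = A, B = A * (1 + b))
}

#' Mean-field free energy per lattice site
#'
#' Bragg-Williams raft lattice gas plus the grand-canonical receptor
#' binding excess:
#' \deqn{f(\phi) = \tfrac{z}{2} u \phi(1-\phi) + \phi\ln\phi +
#'   (1-\phi)\ln(1-\phi) -
#'   \ln\frac{1 + A(1+b)e^{u_a\phi}}{1 + A e^{u_a\phi}},}
#' (the regular-solution form of the contact attraction, equal to
#' \eqn{-\tfrac{z}{2}u\phi^2} up to a linear term that does not affect
#' coexistence, and exactly symmetric under \eqn{\phi \to 1-\phi} at
#' `cR = 0`)
#' where a receptor on a patch feels the mean raft coupling
#' \eqn{-u_a\phi}, forms a complex with excess weight
#' \eqn{b = P_b \rho_L (e^{u_b}-1)} (\eqn{\rho_L} the per-patch ligand
#' density, \eqn{P_b} the membrane contact probability), and the
#' fugacity A is fixed so the homogeneous phase at the global raft
#' fraction x has receptor occupancy \eqn{r = c_R a^2}. The binding term
#' is the excess over the binding-free reference, so it vanishes as
#' \eqn{P_b \to 0} or \eqn{u_b \to 0} and the phase line collapses onto
#' the receptor-free one; at `cR = 0` the free energy is the symmetric
#' lattice gas with critical contact energy exactly 1 kBT. At dilute
#' receptor occupancy the excess is concave in \eqn{\phi}, so binding
#' lowers the transition; near receptor saturation the trend reverses.
#'
#' @param phi Raft density in (0, 1) (vectorized).
#' @param cfg An [mf_config()].
#' @return Free energy per site, kBT.
#' @export
mf_free_energy <- function(phi, cfg) {
  stopifnot(inherits(cfg, "mf_config"))
  if (any(phi <= 0 | phi >= 1)) stop("phi must lie strictly in (0, 1)")
  ax <- mf_aux(cfg)
  e <- exp(cfg$ua * phi)
  cfg$z / 2 * cfg$u * phi * (1 - phi) + phi * log(phi) +
    (1 - phi) * log(1 - phi) -
    (log1p(ax$B * e) - log1p(ax$A * e))
}

mf_fprime <- function(phi, cfg) {
  ax <- mf_aux(cfg)
  e <- exp(cfg$ua * phi)
  sB <- ax$B * e / (1 + ax$B * e)
  sA <- ax$A * e / (1 + ax$A * e)
  cfg$z / 2 * cfg$u * (1 - 2 * phi) + log(phi / (1 - phi)) -
    cfg$ua * (sB - sA)
}

mf_fpp <- function(phi, cfg) {
  ax <- mf_aux(cfg)
  e <- exp(cfg$ua * phi)
  sB <- ax$B * e / (1 + ax$B * e)
  sA <- ax$A * e / (1 + ax$A * e)
  -cfg$z * cfg$u + 1 / (phi * (1 - phi)) -
    cfg$ua^2 * (sB * (1 - sB) - sA * (1 - sA))
}

# Spinodal interval [s1, s2] where f'' < 0, or NULL if none.
mf_spinodal <- function(cfg) {
  grid <- sort(unique(c(seq(1e-4, 1 - 1e-4, length.out = 4001),
                        0.5, cfg$x)))
  neg <- which(mf_fpp(grid, cfg) < 0)
  if (length(neg) == 0) return(NULL)
  lo <- grid[min(neg)]
  hi <- grid[max(neg)]
  s1 <- if (min(neg) == 1) lo else
    stats::uniroot(mf_fpp, c(grid[min(neg) - 1], lo), cfg = cfg,
                   tol = 1e-14)$root
  s2 <- if (max(neg) == length(grid)) hi else
    stats::uniroot(mf_fpp, c(hi, grid[max(neg) + 1]), cfg = cfg,
                   tol = 1e-14)$root
  c(s1, s2)
}

# Common-tangent (equal chemical potential and grand potential)
# coexistence densities, or NULL for a convex free energy.
mf_coexistence <- function(cfg) {
  sp <- mf_spinodal(cfg)
  if (is.null(sp)) return(NULL)
  s1 <- sp[1]; s2 <- sp[2]
  eps <- 1e-12
  mu_lo <- mf_fprime(s2, cfg)
  mu_hi <- mf_fprime(s1, cfg)
  if (!(mu_hi > mu_lo + 1e-12 * (abs(mu_lo) + 1)))
    return(list(phi_low = s1, phi_high = s2, mu = mf_fprime(s1, cfg),
                degenerate = TRUE))
  phi_at <- function(mu, side) {
    if (side == "low")
      stats::uniroot(function(z) mf_fprime(z, cfg) - mu,
                     c(1e-13, s1), tol = 1e-15)$root
    else
      stats::uniroot(function(z) mf_fprime(z, cfg) - mu,
                     c(s2, 1 - 1e-13), tol = 1e-15)$root
  }
  omega_gap <- function(mu) {
    pl <- phi_at(mu, "low")
    ph <- phi_at(mu, "high")
    (mf_free_energy(pl, cfg) - mu * pl) -
      (mf_free_energy(ph, cfg) - mu * ph)
  }
  span <- mu_hi - mu_lo
  lo <- mu_lo + eps * max(1, abs(mu_lo)) + 1e-14 * span
  hi <- mu_hi - eps * max(1, abs(mu_hi)) - 1e-14 * span
  glo <- omega_gap(lo)
  ghi <- omega_gap(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0)
    return(list(phi_low = s1, phi_high = s2, mu = mf_fprime(s1, cfg),
                degenerate = TRUE))
  mu <- stats::uniroot(omega_gap, c(lo, hi), tol = 1e-15)$root
  list(phi_low = phi_at(mu, "low"), phi_high = phi_at(mu, "high"),
       mu = mu, degenerate = FALSE)
}

#' Solve the self-consistent mean-field equations
#'
#' Finds the coexisting raft densities by the common-tangent construction
#' on the mean-field free energy (equal chemical potentials and equal
#' tangent intercepts). For the configured raft fraction x the system is
#' phase-separated when `phi_low < x < phi_high`; `u_transition` is the
#' smallest contact energy at which x enters the coexistence region,
#' located by bisection in u (tolerance 1e-7 kBT).
#'
#' @param cfg An [mf_config()].
#' @return An `mf_solution`: `phi_low`, `phi_high` (NA when the free
#'   energy is convex at `cfg$u`), `separated` flag for the configured
#'   (x, u), and `u_transition`.
#' @export
solve_self_consistent <- function(cfg) {
  stopifnot(inherits(cfg, "mf_config"))
  cx <- mf_coexistence(cfg)
  separated <- !is.null(cx) && cx$phi_low < cfg$x && cfg$x < cx$phi_high
  sep_at <- function(u) {
    c2 <- cfg
    c2$u <- u
    cc <- mf_coexistence(c2)
    !is.null(cc) && cc$phi_low < cfg$x && cfg$x < cc$phi_high
  }
  lo <- 1e-6
  if (sep_at(lo)) stop("system phase-separated at u ~ 0: check inputs")
  hi <- max(2 * cfg$u, 2)
  it <- 0
  while (!sep_at(hi)) {
    hi <- hi * 2
    it <- it + 1
    if (it > 12) stop("no phase separation found up to u = ", hi,
                      " kBT: solver cannot bracket the transition")
  }
  while (hi - lo > 1e-7) {
    mid <- (lo + hi) / 2
    if (sep_at(mid)) hi <- mid else lo <- mid
  }
  structure(list(phi_low = if (is.null(cx)) NA_real_ else cx$phi_low,
                 phi_high = if (is.null(cx)) NA_real_ else cx$phi_high,
                 separated = separated,
                 u_transition = (lo + hi) / 2,
                 x = cfg$x, cR = cfg$cR),
            class = "mf_solution")
}

#' @export
print.mf_solution <- function(x, ...) {
  cat(sprintf("mf_solution: u_transition = %.6f kBT at x = %g, cR = %g\n",
              x$u_transition, x$x, x$cR))
  if (!is.na(x$phi_low))
    cat(sprintf("  coexistence at configured u: phi in [%.4f, %.4f]%s\n",
                x$phi_low, x$phi_high,
                if (x$separated) " (separated)" else ""))
  invisible(x)
}

#' Mean-field phase-transition line over receptor concentration
#'
#' The mean-field counterpart of the Monte Carlo phase diagram:
#' u_transition(cR) at fixed raft fraction, normalized by the mean-field
#' critical value \eqn{u_0^* = 1} kBT. Mobile-ligand systems only; no
#' mean-field treatment exists for immobile-ligand scenarios.
#'
#' @param x Raft area fraction.
#' @param cR_grid Receptor concentrations, um^-2.
#' @param cL Ligand concentration, um^-2.
#' @param ua,ub Couplings, kBT.
#' @param Pb Contact probability (see [estimate_contact_probability()]).
#' @param a Lattice constant, nm.
#' @return A data frame (x, cR, u_transition, u_normalized).
#' @export
mf_phase_line <- function(x, cR_grid, cL = 1000, ua = 3, ub = 6,
                          Pb = 0.1, a = 10) {
  rows <- lapply(cR_grid, function(cr) {
    cfg <- mf_config(x = x, cR = cr, cL = cL, ua = ua, ub = ub, Pb = Pb,
                     a = a)
    sol <- solve_self_consistent(cfg)
    data.frame(x = x, cR = cr, u_transition = sol$u_transition,
               u_normalized = sol$u_transition / 1.0)
  })
  do.call(rbind, rows)
}

#' Theoretical membrane roughness of the discretized bending Hamiltonian
#'
#' Equipartition result for the tensionless discretized membrane: the
#' per-site variance of the separation about its spatial mean is
#' \deqn{\sigma^2 = \frac{k_B T a^2}{\kappa L^2}
#'   \sum_{q \ne 0} \lambda_q^{-2}},
#' with stencil eigenvalues
#' \eqn{\lambda_q = 4 - 2\cos q_x - 2\cos q_y}. Grows as \eqn{L^2/\kappa}:
#' the reference contact probability is therefore lattice-size dependent.
#'
#' @param L Lattice size.
#' @param kappa Bending rigidity, kBT.
#' @param a Lattice constant, nm.
#' @return Variance in nm^2.
#' @export
membrane_roughness <- function(L, kappa, a = 10) {
  q <- 2 * pi * (0:(L - 1)) / L
  lam <- outer(2 - 2 * cos(q), 2 - 2 * cos(q), "+")
  lam[1, 1] <- Inf  # zero mode excluded (free vertical translation)
  a^2 / kappa * sum(1 / lam^2) / L^2
}

#' Closed-form contact probability of the fluctuating reference membrane
#'
#' Gaussian prediction \eqn{P_b = P(|\delta l| < l_b/2)} with
#' \eqn{\delta l} the separation fluctuation about the mean, using
#' [membrane_roughness()]. Oracle for [estimate_contact_probability()].
#'
#' @param p A `model_params`.
#' @param L Lattice size.
#' @return Contact probability in (0, 1).
#' @export
contact_probability_theory <- function(p, L) {
  s <- sqrt(membrane_roughness(L, p$kappa, p$a))
  2 * stats::pnorm(p$l_b / 2, mean = 0, sd = s) - 1
}

#' Estimate the contact probability Pb by Monte Carlo
#'
#' Simulates the homogeneous reference system (a bare fluctuating
#' membrane, no rafts or binders) initialized at the well centre
#' \eqn{l_c} and returns the time-averaged fraction of patches whose
#' separation lies inside the binding well. Centre-of-mass drift relative
#' to the initial mean is removed before the well test: the unconstrained
#' vertical zero mode of the reference has no counterpart in the adhered
#' system, where binding pins the mean separation at \eqn{l_c}.
#'
#' @param p A `model_params`.
#' @param L Lattice size of the reference membrane.
#' @param run A [run_config()].
#' @param l0 Initial uniform separation (default `l_c`).
#' @param rigid If `TRUE` the membrane is clamped at `l0` and the exact
#'   static fraction is returned.
#' @return Estimated Pb in `[0, 1]`.
#' @export
estimate_contact_probability <- function(p, L = 32,
                                         run = run_preset("desk"),
                                         l0 = NULL, rigid = FALSE) {
  stopifnot(inherits(p, "model_params"))
  if (is.null(l0)) l0 <- p$l_c
  if (rigid)
    return(as.numeric(l0 > p$l_c - p$l_b / 2 & l0 < p$l_c + p$l_b / 2))
  st <- lattice_state(L, l0 = l0, ligands_mobile = FALSE)
  ser <- run_simulation(st, p, run, mix = move_mix(L^2, 0, 0))
  mean(ser$samples$n_in_well) / L^2
}
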
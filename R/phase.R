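#' Sweep the raft-raft contact energy u
#'
#' Runs independent simulations (fresh engine seeds per replicate) at each
#' value of a strictly increasing u grid and aggregates the heat capacity
#' per site and, when both binder species are present, the binding
#' constant K.
#'
#' @param scenario A [scenario_config()].
#' @param p A `model_params` (its `u` is overridden along the grid).
#' @param u_grid Strictly increasing contact energies, kBT.
#' @param run A [run_config()]; replicate r at grid point j uses engine
#'   seed `seed + 1000 * j + r`.
#' @param n_replicates Independent runs per grid point.
#' @param rigid Disable height moves (rigid-membrane limit).
#' @param vary_initial If `TRUE` each replicate also uses a different
#'   initial placement seed.
#' @return A `sweep_result`: `u_grid`, per-replicate matrices `cv_rep`,
#'   `k_rep` (replicates x grid) and aggregated `cv`, `cv_sd`, `k`,
#'   `k_sd`.
#' @export
sweep_u <- function(scenario, p, u_grid, run, n_replicates = 3,
                    rigid = FALSE, vary_initial = TRUE) {
  stopifnot(length(u_grid) >= 1, !is.unsorted(u_grid, strictly = TRUE))
  nu <- length(u_grid)
  cv <- matrix(NA_real_, n_replicates, nu)
  kk <- matrix(NA_real_, n_replicates, nu)
  for (j in seq_len(nu)) {
    pj <- p
    pj$u <- u_grid[j]
    for (r in seq_len(n_replicates)) {
      scen <- scenario
      if (vary_initial) scen$seed <- scenario$seed + r
      rr <- run
      rr$seed <- run$seed + 1000L * j
      rr$replicate_id <- r
      ser <- run_simulation(scen, pj, rr, rigid = rigid)
      cv[r, j] <- heat_capacity(ser)
      if (ser$n_receptors > 0 && ser$n_ligands > 0)
        kk[r, j] <- tryCatch(binding_constant(ser),
                             error = function(e) NA_real_)
    }
  }
  structure(list(u_grid = u_grid,
                 cv_rep = cv, k_rep = kk,
                 cv = colMeans(cv), cv_sd = apply(cv, 2, sd_pop),
                 k = colMeans(kk), k_sd = apply(kk, 2, sd_pop),
                 n_replicates = n_replicates,
                 scenario = scenario),
            class = "sweep_result")
}

sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Locate the phase transition from a CV sweep
#'
#' u* is the argmax of the mean CV curve, refined by quadratic
#' interpolation through the peak and its two neighbours; ties take the
#' lower u (first maximum). The SD comes from replicate-wise peak
#' locations. A maximum on the grid boundary is inconclusive and raises
#' an error (widen the grid).
#'
#' @param sweep A `sweep_result` (or a list with `u_grid` and `cv`).
#' @param cR,x,scenario_tag Optional annotations stored in the result.
#' @return A `phase_point`: `u_star`, `u_star_sd`, annotations.
#' @export
locate_transition <- function(sweep, cR = NA_real_, x = NA_real_,
                              scenario_tag = NA_character_) {
  u <- sweep$u_grid
  cv <- sweep$cv
  if (length(u) < 3)
    stop("need at least 3 grid points to locate an interior maximum")
  j <- which.max(cv)  # ties -> lowest u
  if (j == 1 || j == length(u))
    stop("CV maximum on grid boundary: sweep inconclusive, widen the grid")
  # exact plateau (tied maxima): keep the lower-u grid point unrefined
  u_star <- if (sum(cv == cv[j]) > 1) u[j] else
    quad_peak(u[(j - 1):(j + 1)], cv[(j - 1):(j + 1)])
  sd <- NA_real_
  if (!is.null(sweep$cv_rep) && nrow(sweep$cv_rep) > 1) {
    reps <- apply(sweep$cv_rep, 1, function(cvr) {
      jr <- which.max(cvr)
      if (jr == 1 || jr == length(u)) return(NA_real_)
      quad_peak(u[(jr - 1):(jr + 1)], cvr[(jr - 1):(jr + 1)])
    })
    sd <- sd_pop(reps)
  }
  structure(list(u_star = u_star, u_star_sd = sd, cR = cR, x = x,
                 scenario = scenario_tag), class = "phase_point")
}

# Vertex of the parabola through three points; falls back to the middle
# point for a degenerate (flat) triple.
quad_peak <- function(u3, c3) {
  denom <- c3[1] - 2 * c3[2] + c3[3]
  if (abs(denom) < .Machine$double.eps * max(abs(c3), 1)) return(u3[2])
  h1 <- u3[2] - u3[1]
  h2 <- u3[3] - u3[2]
  # general (possibly uneven) spacing: vertex of Lagrange parabola
  d1 <- (c3[2] - c3[1]) / h1
  d2 <- (c3[3] - c3[2]) / h2
  a2 <- (d2 - d1) / (h1 + h2)
  if (a2 >= 0) return(u3[2])  # not concave: keep grid argmax
  0.5 * (u3[1] + u3[2] + d1 / (-a2))
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf("phase_point: u* = %.4f kBT (sd %.4f)", x$u_star,
              x$u_star_sd))
  if (!is.na(x$cR)) cat(sprintf(", cR = %g um^-2", x$cR))
  if (!is.na(x$x)) cat(sprintf(", x = %g", x$x))
  cat("\n")
  invisible(x)
}

#' Build a phase diagram u*(cR)
#'
#' One transition point per receptor concentration, reported raw and
#' normalized by the reference critical coupling
#' \eqn{u_0^* = 2\ln(1+\sqrt2)} kBT (Monte Carlo reference value).
#'
#' @param scenario Base [scenario_config()] (its `cR` is overridden).
#' @param p A `model_params`.
#' @param cR_grid Receptor concentrations, um^-2.
#' @param u_grid Contact-energy grid spanning the expected transitions.
#' @param run A [run_config()].
#' @param n_replicates Replicates per sweep point.
#' @param rigid Passed to [sweep_u()].
#' @return A data frame (scenario, x, cR, u_star, u_star_sd,
#'   u_star_normalized).
#' @export
build_phase_diagram <- function(scenario, p, cR_grid, u_grid, run,
                                n_replicates = 3, rigid = FALSE) {
  u0 <- onsager_critical_coupling()
  rows <- lapply(seq_along(cR_grid), function(i) {
    scen <- scenario
    scen$cR <- cR_grid[i]
    scen$seed <- scenario$seed + 97L * i
    rr <- run
    rr$seed <- run$seed + 100000L * i
    sw <- sweep_u(scen, p, u_grid, rr, n_replicates, rigid = rigid)
    pp <- locate_transition(sw, cR = cR_grid[i], x = scenario$x,
                            scenario_tag = scenario$ligand_mode)
    data.frame(scenario = scenario$ligand_mode, x = scenario$x,
               cR = cR_grid[i], u_star = pp$u_star,
               u_star_sd = pp$u_star_sd,
               u_star_normalized = pp$u_star / u0)
  })
  do.call(rbind, rows)
}

#' Binding constant versus normalized contact energy
#'
#' Extracts the K(u) curve of a sweep with u normalized by the scenario's
#' transition point u*.
#'
#' @param sweep A `sweep_result` with K columns.
#' @param u_star Transition coupling used for normalization (e.g. from
#'   [locate_transition()]).
#' @return A data frame (u, u_over_ustar, K, K_sd).
#' @export
k_vs_u_curve <- function(sweep, u_star) {
  stopifnot(inherits(sweep, "sweep_result"), u_star > 0)
  data.frame(u = sweep$u_grid,
             u_over_ustar = sweep$u_grid / u_star,
             K = sweep$k, K_sd = sweep$k_sd)
}
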
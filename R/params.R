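#' Physical parameters of the adhesion model
#'
#' Bundles all constants of the Hamiltonian
#' \eqn{H_{ad} = H_{me} + H_{R-L} + H_{r-p} + H_{r-r}} in internal units
#' (energies in kBT with kT = 1, lengths in nm). Defaults follow the studied
#' system: a stiff cell membrane (\eqn{\kappa = 10} kBT) discretized at the
#' protein exclusion size a = 10 nm, a square-well receptor-ligand bond of
#' depth \eqn{u_b} (4 or 6 kBT), width \eqn{l_b} = 1 nm centred at the
#' complex length \eqn{l_c} = 15 nm, a raft-receptor affinity
#' \eqn{u_a} = 3 kBT, and a nearest-neighbour raft-raft contact energy u.
#'
#' @param kappa Membrane bending rigidity, kBT.
#' @param a Lattice constant, nm (one patch is `a^2` nm^2).
#' @param u_b Binding-well depth, kBT.
#' @param l_b Binding-well width, nm; must be `< l_c`.
#' @param l_c Receptor-ligand complex length (well centre), nm.
#' @param u_a Raft-receptor coupling energy, kBT.
#' @param u Raft-raft contact energy per nearest-neighbour pair, kBT.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(u = 1.5)
#' p$u
#' @export
model_params <- function(kappa = 10, a = 10, u_b = 6, l_b = 1, l_c = 15,
                         u_a = 3, u = 1) {
  stopifnot(is.numeric(kappa), is.numeric(a), is.numeric(u_b),
            is.numeric(l_b), is.numeric(l_c), is.numeric(u_a),
            is.numeric(u))
  if (kappa <= 0) stop("kappa must be > 0")
  if (a <= 0) stop("a must be > 0")
  if (l_b <= 0 || l_c <= 0) stop("l_b and l_c must be > 0")
  if (l_b >= l_c) stop("binding-well width l_b must be smaller than l_c")
  if (u_b < 0 || u_a < 0 || u < 0)
    stop("coupling energies u_b, u_a, u must be >= 0 (attractive model)")
  structure(list(kappa = kappa, a = a, u_b = u_b, l_b = l_b, l_c = l_c,
                 u_a = u_a, u = u, kT = 1),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Adhesion model parameters (kBT / nm units):\n")
  cat(sprintf("  kappa = %g kBT, a = %g nm\n", x$kappa, x$a))
  cat(sprintf("  binding: u_b = %g kBT, l_b = %g nm, l_c = %g nm\n",
              x$u_b, x$l_b, x$l_c))
  cat(sprintf("  raft couplings: u_a = %g kBT, u = %g kBT\n", x$u_a, x$u))
  invisible(x)
}

as_param_list <- function(p) {
  stopifnot(inherits(p, "model_params"))
  p[c("kappa", "a", "u_b", "l_b", "l_c", "u_a", "u")]
}

#' Exact critical contact energy of the reference lattice gas
#'
#' In the rigid-membrane, receptor-free limit the raft sector is the 2D
#' square-lattice gas; its exact critical coupling is
#' \eqn{u_0^* = 2\ln(1+\sqrt 2) \approx 1.763} kBT. This is the reference
#' value used to normalize Monte Carlo phase diagrams. The mean-field
#' counterpart is 1 kBT (see [solve_self_consistent()]).
#'
#' @return The critical contact energy in kBT.
#' @export
onsager_critical_coupling <- function() 2 * log(1 + sqrt(2))
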
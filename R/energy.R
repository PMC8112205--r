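#' Discretized Laplacian of the separation field
#'
#' Five-point stencil with periodic wrap:
#' \eqn{\Delta_d l_i = l_{north} + l_{south} + l_{east} + l_{west} - 4 l_i}.
#'
#' @param state A `lattice_state`.
#' @param site Optional 1-based site index; if `NULL`, all sites.
#' @return Laplacian value(s) in nm.
#' @export
discrete_laplacian <- function(state, site = NULL) {
  validate_state(state)
  lap <- laplacian_all_cpp(state$l, state$L)
  if (is.null(site)) return(lap)
  stopifnot(site >= 1, site <= state$L^2)
  lap[site]
}

#' Membrane bending energy
#'
#' Discretized Helfrich bending energy
#' \eqn{H_{me} = \kappa/(2a^2) \sum_i (\Delta_d l_i)^2}; always non-negative.
#'
#' @param state A `lattice_state`.
#' @param p A `model_params`.
#' @return Energy in kBT.
#' @export
bending_energy <- function(state, p) {
  total_energy(state, p)$e_bend
}

#' Receptor-ligand binding energy
#'
#' Square-well potential: a receptor and a ligand at the same lattice index
#' contribute \eqn{-u_b} iff the local separation satisfies
#' \eqn{l_c - l_b/2 < l_i < l_c + l_b/2} (strict inequalities).
#'
#' @inheritParams bending_energy
#' @return Energy in kBT (non-positive).
#' @export
binding_energy <- function(state, p) {
  total_energy(state, p)$e_bind
}

#' Raft-receptor coupling energy
#'
#' \eqn{-u_a \sum_i n_i^+ m_i^+}: each receptor residing on a raft patch
#' gains \eqn{u_a}.
#'
#' @inheritParams bending_energy
#' @return Energy in kBT (non-positive).
#' @export
raft_receptor_energy <- function(state, p) {
  total_energy(state, p)$e_raft_receptor
}

#' Raft-raft contact energy
#'
#' \eqn{-u \sum_{\langle i,j\rangle} n_i^+ n_j^+} over nearest-neighbour
#' pairs, each bond counted once, with periodic wrap. A fully covered
#' lattice has energy \eqn{-2uL^2} (two bonds per site).
#'
#' @inheritParams bending_energy
#' @return Energy in kBT (non-positive).
#' @export
raft_raft_energy <- function(state, p) {
  total_energy(state, p)$e_raft_raft
}

#' Total adhesion energy with component breakdown
#'
#' @inheritParams bending_energy
#' @return An `energy_breakdown` list with `e_bend`, `e_bind`,
#'   `e_raft_receptor`, `e_raft_raft`, `e_total` (kBT); `e_total` is the
#'   exact sum of the components.
#' @export
total_energy <- function(state, p) {
  validate_state(state)
  stopifnot(inherits(p, "model_params"))
  e <- energy_components_cpp(state$l, state$m_plus, state$m_minus,
                             state$n_plus, state$L, as_param_list(p))
  structure(as.list(e), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("energy (kBT): bend %.6g, bind %.6g, ",
                     "raft-receptor %.6g, raft-raft %.6g, total %.6g\n"),
              x$e_bend, x$e_bind, x$e_raft_receptor, x$e_raft_raft,
              x$e_total))
  invisible(x)
}

#' Move descriptors for incremental energy evaluation
#'
#' Constructors for the three trial-move types accepted by
#' [local_delta_energy()] and the single-move helpers. Sites are 1-based.
#'
#' @param site Source site.
#' @param dl Height displacement in nm (height move).
#' @param surface `"upper"` (receptor) or `"lower"` (ligand).
#' @param direction Hop direction, see [neighbor_site()].
#' @return A move descriptor list.
#' @name moves
NULL

#' @rdname moves
#' @export
height_move <- function(site, dl) {
  list(type = "height", site = site, dl = dl)
}

#' @rdname moves
#' @export
protein_hop <- function(surface, site, direction) {
  surface <- match.arg(surface, c("upper", "lower"))
  list(type = "protein", surface = surface, site = site,
       direction = direction)
}

#' @rdname moves
#' @export
raft_hop <- function(site, direction) {
  list(type = "raft", site = site, direction = direction)
}

#' Incremental (single-move) energy change
#'
#' Returns \eqn{\Delta H} for a proposed move, equal to
#' `total_energy(after) - total_energy(before)` but evaluated in O(1):
#' height moves touch the bending stencil of radius 2 plus the local
#' binding term; hops touch the binding/coupling/contact terms of the
#' source and destination neighbourhoods.
#'
#' @param state A `lattice_state`.
#' @param p A `model_params`.
#' @param move A descriptor from [height_move()], [protein_hop()] or
#'   [raft_hop()].
#' @return Energy change in kBT.
#' @export
local_delta_energy <- function(state, p, move) {
  validate_state(state)
  stopifnot(inherits(p, "model_params"))
  if (!is.list(move) || is.null(move$type))
    stop("invalid move descriptor")
  pl <- as_param_list(p)
  if (move$type == "height") {
    i <- move$site
    stopifnot(i >= 1, i <= state$L^2)
    lnew <- state$l[i] + move$dl
    if (lnew < 0) stop("height move would violate l >= 0")
    return(local_delta_cpp(state$l, state$m_plus, state$m_minus,
                           state$n_plus, state$L, pl, 1L,
                           i - 1L, 0L, lnew))
  }
  if (move$type == "protein") {
    from <- move$site
    to <- neighbor_site(state$L, from, move$direction)
    if (move$surface == "upper") {
      if (state$m_plus[from] != 1L) stop("no receptor at source site")
      if (state$m_plus[to] == 1L) stop("destination occupied by a receptor")
      return(local_delta_cpp(state$l, state$m_plus, state$m_minus,
                             state$n_plus, state$L, pl, 2L,
                             from - 1L, to - 1L, 0))
    }
    if (state$m_minus[from] != 1L) stop("no ligand at source site")
    if (state$m_minus[to] == 1L) stop("destination occupied by a ligand")
    return(local_delta_cpp(state$l, state$m_plus, state$m_minus,
                           state$n_plus, state$L, pl, 3L,
                           from - 1L, to - 1L, 0))
  }
  if (move$type == "raft") {
    from <- move$site
    to <- neighbor_site(state$L, from, move$direction)
    if (state$n_plus[from] != 1L) stop("no raft at source site")
    if (state$n_plus[to] == 1L) stop("destination occupied by a raft")
    return(local_delta_cpp(state$l, state$m_plus, state$m_minus,
                           state$n_plus, state$L, pl, 4L,
                           from - 1L, to - 1L, 0))
  }
  stop(sprintf("unknown move type '%s'", move$type))
}

#' Apply a move to a lattice state
#'
#' Pure helper used by the single-move samplers and tests: returns the
#' state after the (assumed valid) move.
#'
#' @inheritParams local_delta_energy
#' @return The updated `lattice_state`.
#' @export
apply_move <- function(state, move) {
  if (move$type == "height") {
    state$l[move$site] <- state$l[move$site] + move$dl
    return(state)
  }
  from <- move$site
  to <- neighbor_site(state$L, from, move$direction)
  if (move$type == "protein") {
    f <- if (move$surface == "upper") "m_plus" else "m_minus"
    state[[f]][from] <- 0L
    state[[f]][to] <- 1L
    return(state)
  }
  if (move$type == "raft") {
    state$n_plus[from] <- 0L
    state$n_plus[to] <- 1L
    return(state)
  }
  stop("unknown move type")
}
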
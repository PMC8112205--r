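#' Metropolis acceptance rule
#'
#' A move is always accepted if \eqn{\Delta H < 0}, otherwise with
#' probability \eqn{\exp(-\Delta H / k_B T)} (kT = 1 internally). Uses R's
#' RNG stream, so results are reproducible under [set.seed()].
#'
#' @param delta_h Energy change of the proposed move, kBT.
#' @return Logical: accept the move?
#' @seealso [metropolis_accept_prob()] for the analytic probability.
#' @export
metropolis_accept <- function(delta_h) {
  if (!is.finite(delta_h))
    stop("non-finite delta_h: energy bookkeeping bug upstream")
  delta_h <= 0 || stats::runif(1) < exp(-delta_h)
}

#' Analytic Metropolis acceptance probability
#'
#' `min(1, exp(-delta_h))`; exposed so detailed balance
#' \eqn{P(A \to B)/P(B \to A) = e^{-\Delta H}} can be checked exactly.
#'
#' @inheritParams metropolis_accept
#' @return Acceptance probability in `[0, 1]`.
#' @export
metropolis_accept_prob <- function(delta_h) {
  if (any(!is.finite(delta_h))) stop("non-finite delta_h")
  pmin(1, exp(-delta_h))
}

#' Single trial moves
#'
#' One Metropolis trial of each move type, operating on an R-level state
#' (used for unit tests and didactic runs; bulk sampling goes through
#' [run_simulation()]). Height proposals drawing `l < 0` are rejected
#' outright; hops into occupied destinations are rejected (single
#' occupancy per surface, one raft per membrane patch). In raft hops any
#' receptor on the source patch stays where it is.
#'
#' @param state A `lattice_state`.
#' @param p A `model_params`.
#' @param site Source site, 1-based.
#' @param step_height Maximum vertical displacement, nm.
#' @param dl Optional fixed displacement (overrides the uniform draw).
#' @param surface `"upper"` (receptor) or `"lower"` (ligand).
#' @param direction Hop direction, see [neighbor_site()].
#' @return A list with `state` (possibly updated), `accepted` (logical)
#'   and `delta` (the proposed \eqn{\Delta H}, `NA` for outright
#'   rejections).
#' @name trial_moves
NULL

#' @rdname trial_moves
#' @export
try_height_move <- function(state, p, site, step_height = 0.5, dl = NULL) {
  if (is.null(dl)) dl <- stats::runif(1, -step_height, step_height)
  if (state$l[site] + dl < 0)
    return(list(state = state, accepted = FALSE, delta = NA_real_))
  mv <- height_move(site, dl)
  delta <- local_delta_energy(state, p, mv)
  if (metropolis_accept(delta))
    return(list(state = apply_move(state, mv), accepted = TRUE,
                delta = delta))
  list(state = state, accepted = FALSE, delta = delta)
}

#' @rdname trial_moves
#' @export
try_protein_hop <- function(state, p, surface, site, direction) {
  surface <- match.arg(surface, c("upper", "lower"))
  f <- if (surface == "upper") "m_plus" else "m_minus"
  if (state[[f]][site] != 1L) stop("no protein at source site")
  if (surface == "lower" && !state$ligands_mobile)
    stop("ligand hops are not allowed in immobile-ligand scenarios")
  to <- neighbor_site(state$L, site, direction)
  if (state[[f]][to] == 1L)
    return(list(state = state, accepted = FALSE, delta = NA_real_))
  mv <- protein_hop(surface, site, direction)
  delta <- local_delta_energy(state, p, mv)
  if (metropolis_accept(delta))
    return(list(state = apply_move(state, mv), accepted = TRUE,
                delta = delta))
  list(state = state, accepted = FALSE, delta = delta)
}

#' @rdname trial_moves
#' @export
try_raft_hop <- function(state, p, site, direction) {
  if (state$n_plus[site] != 1L) stop("no raft at source site")
  to <- neighbor_site(state$L, site, direction)
  if (state$n_plus[to] == 1L)
    return(list(state = state, accepted = FALSE, delta = NA_real_))
  mv <- raft_hop(site, direction)
  delta <- local_delta_energy(state, p, mv)
  if (metropolis_accept(delta))
    return(list(state = apply_move(state, mv), accepted = TRUE,
                delta = delta))
  list(state = state, accepted = FALSE, delta = delta)
}
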
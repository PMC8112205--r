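#' Heat capacity per lattice site
#'
#' \eqn{C_V = (\langle H^2\rangle - \langle H\rangle^2)/(N k_B T^2)} with
#' kT = 1 internally; the peak of \eqn{C_V(u)} locates the homogeneous to
#' phase-separated transition. Plain (population) variance over the
#' samples, matching the replicate-SD error model.
#'
#' @param series A `sample_series`, or a numeric vector of total-energy
#'   samples (then `N` must be given).
#' @param N Number of lattice patches (only when `series` is numeric).
#' @return Heat capacity per site in kB units (non-negative).
#' @export
heat_capacity <- function(series, N = NULL) {
  if (inherits(series, "sample_series")) {
    e <- series$samples$e_total
    N <- series$N
  } else {
    e <- as.numeric(series)
    if (is.null(N)) stop("N must be supplied for raw energy samples")
  }
  if (length(e) < 2) stop("need at least 2 energy samples")
  v <- mean(e^2) - mean(e)^2
  max(v, 0) / N
}

#' Count receptor-ligand complexes in a state
#'
#' A complex exists at lattice index i iff a receptor and a ligand are
#' apposed there and the local separation lies strictly inside the
#' binding well, \eqn{l_c - l_b/2 < l_i < l_c + l_b/2}.
#'
#' @param state A `lattice_state`.
#' @param p A `model_params`.
#' @return Integer complex count.
#' @export
count_complexes <- function(state, p) {
  validate_state(state)
  inwell <- state$l > p$l_c - p$l_b / 2 & state$l < p$l_c + p$l_b / 2
  sum(state$m_plus == 1L & state$m_minus == 1L & inwell)
}

#' Two-dimensional binding constant K
#'
#' \eqn{K = \langle[RL]\rangle / (\langle[R]\rangle \langle[L]\rangle)}
#' in um^2, with area concentrations formed from time-averaged counts
#' over the sampling run divided by the membrane area (ratio of time
#' averages, not average of ratios). Zero complexes throughout give
#' K = 0; a saturated run (zero average unbound receptors or ligands) is
#' an error, not a silent drop.
#'
#' @param series A `sample_series`.
#' @return K in um^2.
#' @export
binding_constant <- function(series) {
  stopifnot(inherits(series, "sample_series"))
  s <- series$samples
  if (nrow(s) < 1) stop("empty sample series")
  rl <- mean(s$n_complexes)
  if (rl == 0) return(0)
  r_free <- series$n_receptors - rl
  l_free <- series$n_ligands - rl
  if (r_free <= 0 || l_free <= 0)
    stop("binding constant undefined: receptor or ligand pool saturated")
  A <- series$area_um2
  (rl / A) / ((r_free / A) * (l_free / A))
}

#' Receptor concentration inside raft domains
#'
#' Time-averaged count of receptors residing on raft patches divided by
#' the raft area (x times the membrane area), in um^-2.
#'
#' @param series A `sample_series`.
#' @return Concentration in um^-2.
#' @export
raft_receptor_concentration <- function(series) {
  stopifnot(inherits(series, "sample_series"))
  if (series$n_rafts == 0) stop("raft fraction x = 0: no raft area")
  raft_area <- series$n_rafts / series$N * series$area_um2
  mean(series$samples$n_receptors_on_rafts) / raft_area
}

#' Aggregate replicate measurements
#'
#' Mean and standard deviation over independent runs; the SD is the
#' population SD of the replicate set ("SD of the 10 measurements"),
#' i.e. denominator n.
#'
#' @param values Numeric vector of replicate values (n >= 1).
#' @return A list with `mean`, `sd`, `n_replicates`.
#' @export
aggregate_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("need at least one replicate value")
  n <- length(values)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  list(mean = m, sd = s, n_replicates = n)
}

#' Per-run observables table
#'
#' Convenience summary of one run: K, CV, complex counts, raft-receptor
#' concentration, conservation checks.
#'
#' @param series A `sample_series`.
#' @return A one-row data frame.
#' @export
observables_row <- function(series) {
  stopifnot(inherits(series, "sample_series"))
  K <- tryCatch(binding_constant(series), error = function(e) NA_real_)
  crr <- if (series$n_rafts > 0) raft_receptor_concentration(series)
         else NA_real_
  data.frame(
    L = series$L,
    x = series$raft_fraction,
    cR = series$n_receptors / series$area_um2,
    cL = series$n_ligands / series$area_um2,
    u = series$params$u,
    K = K,
    CV = heat_capacity(series),
    mean_complexes = mean(series$samples$n_complexes),
    raft_receptor_conc = crr,
    seed = series$engine_seed)
}
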
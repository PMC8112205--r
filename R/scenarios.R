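#' Scenario configuration: the synthetic systems under study
#'
#' Describes one adhesion system: lattice size, raft area fraction,
#' receptor/ligand area concentrations and the ligand placement mode.
#' The four modes are the studied systems: `"mobile"` ligands anchored to
#' a supported bilayer (ligand hops enabled) and immobile ligands placed
#' `"uniform"`ly, at `"random"`, or in `"clustered"` rasterized disks of
#' diameter `dc`.
#'
#' The studied parameter ranges are raft fraction x up to 0.3, receptor
#' concentration up to 2000 um^-2 and cL in {~580, 625, 1000} um^-2; the
#' constructor accepts any geometrically feasible values (the lattice-gas
#' reference point, for instance, needs x = 0.5).
#'
#' @param L Linear lattice size in patches (default 60: 600 x 600 nm^2 at
#'   a = 10 nm).
#' @param x Raft area fraction in `[0, 1]`.
#' @param cR Receptor concentration, um^-2.
#' @param cL Ligand concentration, um^-2.
#' @param ligand_mode One of `"mobile"`, `"uniform"`, `"random"`,
#'   `"clustered"`.
#' @param dc Cluster diameter, nm (clustered mode).
#' @param n_clusters Number of ligand clusters; default: as many whole
#'   disks as needed to best match `cL`.
#' @param seed Seed for the random placements.
#' @param a Lattice constant, nm (used for concentration conversions).
#' @return A `scenario_config`.
#' @export
scenario_config <- function(L = 60, x = 0.2, cR = 1000, cL = 1000,
                            ligand_mode = c("mobile", "uniform", "random",
                                            "clustered"),
                            dc = 50, n_clusters = NULL, seed = 1, a = 10) {
  ligand_mode <- match.arg(ligand_mode)
  stopifnot(L >= 2, x >= 0, x <= 1, cR >= 0, cL >= 0, a > 0)
  if (ligand_mode == "clustered" && dc < a)
    stop("cluster diameter dc must be at least one lattice constant")
  structure(list(L = as.integer(L), x = x, cR = cR, cL = cL,
                 ligand_mode = ligand_mode, dc = dc,
                 n_clusters = n_clusters, seed = as.integer(seed), a = a),
            class = "scenario_config")
}

#' Convert an area concentration to an entity count
#'
#' `round(c * (L a)^2 / 1e6)` entities for `c` in um^-2 and `a` in nm.
#'
#' @param c Concentration, um^-2.
#' @param L Lattice size, patches.
#' @param a Lattice constant, nm.
#' @return Integer count.
#' @seealso [count_to_concentration()] for the inverse (realized
#'   concentration logging).
#' @export
concentration_to_count <- function(c, L, a = 10) {
  stopifnot(c >= 0)
  n <- as.integer(round(c * (L * a)^2 / 1e6))
  if (n > L^2)
    stop(sprintf("count %d exceeds available patches %d", n, L^2))
  n
}

#' Realized concentration of a count of entities
#'
#' @param n Entity count.
#' @param L Lattice size, patches.
#' @param a Lattice constant, nm.
#' @return Concentration in um^-2.
#' @export
count_to_concentration <- function(n, L, a = 10) {
  n / (L * a)^2 * 1e6
}

#' Random raft placement
#'
#' Marks `round(x L^2)` distinct membrane patches as raft, uniformly at
#' random (uses R's RNG stream).
#'
#' @param state A `lattice_state`.
#' @param x Raft area fraction.
#' @return The updated state.
#' @export
place_rafts_random <- function(state, x) {
  n <- as.integer(round(x * state$L^2))
  state$n_plus <- integer(state$L^2)
  if (n > 0)
    state$n_plus[sample.int(state$L^2, n)] <- 1L
  state
}

#' Random receptor placement
#'
#' Receptors on distinct random membrane patches, independent of raft
#' placement: the raft affinity acts through the dynamics, not the
#' initialization.
#'
#' @param state A `lattice_state`.
#' @param cR Receptor concentration, um^-2.
#' @param a Lattice constant, nm.
#' @return The updated state.
#' @export
place_receptors_random <- function(state, cR, a = 10) {
  n <- concentration_to_count(cR, state$L, a)
  state$m_plus <- integer(state$L^2)
  if (n > 0)
    state$m_plus[sample.int(state$L^2, n)] <- 1L
  state
}

#' Lattice offsets of a rasterized circular cluster
#'
#' All offsets `(di, dj)` with `di^2 + dj^2 <= (dc / 2a)^2`, centred on a
#' patch: e.g. dc = 30 nm at a = 10 nm gives a 3 x 3 block of 9 sites,
#' dc = 50 nm gives 21 sites.
#'
#' @param dc Disk diameter, nm.
#' @param a Lattice constant, nm.
#' @return A two-column integer matrix of offsets.
#' @export
rasterize_disk <- function(dc, a = 10) {
  stopifnot(dc >= a)
  r <- dc / (2 * a)
  rng <- seq.int(-floor(r), floor(r))
  g <- expand.grid(di = rng, dj = rng)
  g <- g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
  as.matrix(g[order(g$di, g$dj), ])
}

#' Place ligands according to the scenario mode
#'
#' `"mobile"` and `"random"`: distinct random lower-surface patches (hops
#' enabled only for mobile). `"uniform"`: a maximally even square subgrid
#' (exact when the count is a perfect square whose root divides L, e.g.
#' 225 = 15^2 at spacing 4 on L = 60 for cL = 625 um^-2). `"clustered"`:
#' `n_clusters` rasterized disks of diameter `dc` at random centres with
#' pairwise (periodic) distance >= `dc`, rejection-sampled.
#'
#' @param state A `lattice_state`.
#' @param cfg A [scenario_config()].
#' @return The updated state, with attribute `"realized_cL"`.
#' @export
place_ligands <- function(state, cfg) {
  L <- state$L
  a <- cfg$a
  state$m_minus <- integer(L^2)
  state$ligands_mobile <- cfg$ligand_mode == "mobile"
  if (cfg$ligand_mode %in% c("mobile", "random")) {
    n <- concentration_to_count(cfg$cL, L, a)
    if (n > 0) state$m_minus[sample.int(L^2, n)] <- 1L
  } else if (cfg$ligand_mode == "uniform") {
    n <- concentration_to_count(cfg$cL, L, a)
    if (n > 0) {
      k <- round(sqrt(n))
      if (k^2 == n && L %% k == 0) {
        sp <- L %/% k
        pos <- seq.int(1L, L, by = sp)[seq_len(k)]
      } else {
        # maximally even: k^2 closest to n, ideal positions rounded
        k <- max(1L, k)
        pos <- unique(pmin(L, pmax(1L, round((seq_len(k) - 0.5) * L / k))))
      }
      idx <- as.vector(outer(pos, pos,
                             function(r, cc) (cc - 1L) * L + r))
      state$m_minus[idx[seq_len(min(n, length(idx)))]] <- 1L
    }
  } else {  # clustered
    offs <- rasterize_disk(cfg$dc, a)
    per <- nrow(offs)
    n_target <- concentration_to_count(cfg$cL, L, a)
    nc <- cfg$n_clusters
    if (is.null(nc)) nc <- max(1L, as.integer(round(n_target / per)))
    centers <- sample_cluster_centers(L, nc, cfg$dc / a)
    for (ci in seq_len(nrow(centers))) {
      r <- (centers[ci, 1] + offs[, 1]) %% L
      cc <- (centers[ci, 2] + offs[, 2]) %% L
      state$m_minus[cc * L + r + 1L] <- 1L
    }
    if (sum(state$m_minus) != nc * per)
      stop("cluster placement produced overlapping sites")
  }
  attr(state, "realized_cL") <-
    count_to_concentration(sum(state$m_minus), L, a)
  state
}

# Random cluster centres (0-based row/col) with pairwise periodic
# centre distance >= dmin_patches; rejection sampling capped at 1e5 tries.
sample_cluster_centers <- function(L, nc, dmin_patches) {
  centers <- matrix(NA_integer_, 0, 2)
  tries <- 0L
  while (nrow(centers) < nc) {
    tries <- tries + 1L
    if (tries > 1e5L)
      stop("could not place ligand clusters without overlap; ",
           "reduce n_clusters or dc")
    cand <- c(sample.int(L, 1) - 1L, sample.int(L, 1) - 1L)
    ok <- TRUE
    if (nrow(centers) > 0) {
      dr <- abs(centers[, 1] - cand[1]); dr <- pmin(dr, L - dr)
      dcc <- abs(centers[, 2] - cand[2]); dcc <- pmin(dcc, L - dcc)
      ok <- all(sqrt(dr^2 + dcc^2) >= dmin_patches)
    }
    if (ok) centers <- rbind(centers, cand)
  }
  centers
}

#' Build the initial lattice state for a scenario
#'
#' Seeds R's RNG with the scenario seed (restoring it afterwards), places
#' rafts, receptors and ligands, and initializes the separation field at
#' the binding-well centre `l_c` so binding is reachable without a
#' vertical drift phase. Identical seed and configuration give an
#' identical state.
#'
#' @param cfg A [scenario_config()].
#' @param p A `model_params`.
#' @return A `lattice_state` with attributes `realized_cR`, `realized_cL`,
#'   `realized_x`.
#' @export
build_initial_state <- function(cfg, p) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(p, "model_params"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  st <- lattice_state(cfg$L, l0 = p$l_c,
                      ligands_mobile = cfg$ligand_mode == "mobile")
  st <- place_rafts_random(st, cfg$x)
  st <- place_receptors_random(st, cfg$cR, cfg$a)
  st <- place_ligands(st, cfg)
  attr(st, "realized_cR") <-
    count_to_concentration(sum(st$m_plus), cfg$L, cfg$a)
  attr(st, "realized_x") <- sum(st$n_plus) / cfg$L^2
  validate_state(st)
  st
}

#' Describe the realized composition of a scenario
#'
#' @param cfg A [scenario_config()].
#' @param p A `model_params`.
#' @return A data frame of requested vs realized counts/concentrations.
#' @export
describe_scenario <- function(cfg, p = model_params()) {
  st <- build_initial_state(cfg, p)
  data.frame(
    quantity = c("receptors", "ligands", "rafts"),
    count = c(sum(st$m_plus), sum(st$m_minus), sum(st$n_plus)),
    requested = c(cfg$cR, cfg$cL, cfg$x),
    realized = c(attr(st, "realized_cR"), attr(st, "realized_cL"),
                 attr(st, "realized_x")),
    unit = c("um^-2", "um^-2", "fraction"))
}
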
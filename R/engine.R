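#' Trial-move mix per Monte Carlo cycle
#'
#' Numbers of attempted moves of each type in one MC cycle. The default
#' convention (used when `NULL` is passed to [run_simulation()]) gives each
#' membrane patch one height attempt, each mobile protein one hop attempt
#' and each raft patch one hop attempt per cycle; equilibrium observables
#' do not depend on these proportions, only the dynamics do.
#'
#' @param n_height,n_protein,n_raft Non-negative attempt counts; at least
#'   one must be positive.
#' @return A `move_mix` object.
#' @export
move_mix <- function(n_height, n_protein, n_raft) {
  stopifnot(n_height >= 0, n_protein >= 0, n_raft >= 0)
  if (n_height + n_protein + n_raft <= 0)
    stop("at least one move type must have a positive attempt count")
  structure(list(n_height = n_height, n_protein = n_protein,
                 n_raft = n_raft), class = "move_mix")
}

default_move_mix <- function(state, rigid = FALSE) {
  n_mob <- sum(state$m_plus) +
    if (state$ligands_mobile) sum(state$m_minus) else 0L
  move_mix(if (rigid) 0 else state$L^2, n_mob, sum(state$n_plus))
}

#' Monte Carlo run configuration
#'
#' Cycle counts and sampling cadence. One MC cycle maps to a physical time
#' of about 10 microseconds (protein diffusion over one 10 nm patch at
#' D = 1 um^2/s). The full-fidelity protocol is 5e7 relaxation plus 5e7
#' sampling cycles; [run_preset()] provides scaled-down configurations for
#' desk work and tests.
#'
#' @param n_relax_cycles Relaxation (discarded) cycles.
#' @param n_sample_cycles Sampling cycles.
#' @param sample_interval Cycles between recorded samples.
#' @param step_height Maximum vertical displacement per height move, nm.
#'   Default 0.5 nm, half the binding-well width, so the well is resolved
#'   while keeping acceptance moderate.
#' @param seed Integer RNG seed.
#' @param replicate_id Replicate index; the engine stream is seeded with
#'   `seed + replicate_id`.
#' @return A `run_config` object.
#' @export
run_config <- function(n_relax_cycles, n_sample_cycles,
                       sample_interval = 1000, step_height = 0.5,
                       seed = 1, replicate_id = 0) {
  stopifnot(n_relax_cycles >= 0, n_sample_cycles >= 0,
            sample_interval >= 1, step_height > 0)
  structure(list(n_relax_cycles = n_relax_cycles,
                 n_sample_cycles = n_sample_cycles,
                 sample_interval = sample_interval,
                 step_height = step_height,
                 seed = as.integer(seed),
                 replicate_id = as.integer(replicate_id)),
            class = "run_config")
}

#' Scale presets for run configurations
#'
#' `"full"` is the full-fidelity protocol (cluster scale); `"desk"` and
#' `"test"` are scaled-down versions for interactive work and unit tests.
#'
#' @param scale One of `"full"`, `"desk"`, `"test"`.
#' @param seed RNG seed.
#' @return A [run_config()].
#' @export
run_preset <- function(scale = c("desk", "test", "full"), seed = 1) {
  scale <- match.arg(scale)
  switch(scale,
         full = run_config(5e7, 5e7, sample_interval = 1000, seed = seed),
         desk  = run_config(1e5, 1e5, sample_interval = 50, seed = seed),
         test  = run_config(1e4, 1e4, sample_interval = 10, seed = seed))
}

#' Run one Monte Carlo cycle
#'
#' Performs the configured numbers of height, protein-hop and raft-hop
#' attempts in randomized interleaving. Thin wrapper around the compiled
#' engine, mainly useful for stepping small systems in tests.
#'
#' @param state A `lattice_state`.
#' @param p A `model_params`.
#' @param mix A [move_mix()]; `NULL` for the default convention.
#' @param seed Engine seed for this cycle; drawn from R's RNG when `NULL`.
#' @param step_height Maximum height displacement, nm.
#' @return The updated `lattice_state`.
#' @export
run_cycle <- function(state, p, mix = NULL, seed = NULL,
                      step_height = 0.5) {
  validate_state(state)
  if (is.null(mix)) mix <- default_move_mix(state)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  out <- run_engine_cpp(state$l, state$m_plus, state$m_minus,
                        state$n_plus, state$L, as_param_list(p),
                        state$ligands_mobile,
                        mix$n_height, mix$n_protein, mix$n_raft,
                        0, 1, 1, step_height, seed)
  state$l <- out$l
  state$m_plus <- out$m_plus
  state$m_minus <- out$m_minus
  state$n_plus <- out$n_plus
  state
}

#' Run a Monte Carlo simulation of an adhesion scenario
#'
#' Builds the initial lattice from the scenario configuration, relaxes it,
#' then samples total and component energies and composition observables
#' at the configured cadence. The returned series carries full provenance
#' (scenario, parameters, run configuration, seeds) plus the final state,
#' running-vs-recomputed energy check and per-move acceptance counts.
#'
#' @param scenario A [scenario_config()] (or a prebuilt `lattice_state`).
#' @param p A `model_params`.
#' @param run A [run_config()].
#' @param mix Optional [move_mix()]; default gives one attempt per entity
#'   per cycle (and one height attempt per patch unless `rigid`).
#' @param rigid If `TRUE`, membrane height moves are disabled (rigid
#'   planar membranes).
#' @return A `sample_series` object; see [heat_capacity()],
#'   [binding_constant()] and friends for downstream observables.
#' @export
run_simulation <- function(scenario, p, run, mix = NULL, rigid = FALSE) {
  stopifnot(inherits(p, "model_params"), inherits(run, "run_config"))
  if (inherits(scenario, "lattice_state")) {
    state <- scenario
    scen <- NULL
  } else {
    stopifnot(inherits(scenario, "scenario_config"))
    state <- build_initial_state(scenario, p)
    scen <- scenario
  }
  validate_state(state)
  if (is.null(mix)) mix <- default_move_mix(state, rigid = rigid)
  engine_seed <- run$seed + run$replicate_id
  out <- run_engine_cpp(state$l, state$m_plus, state$m_minus,
                        state$n_plus, state$L, as_param_list(p),
                        state$ligands_mobile,
                        mix$n_height, mix$n_protein, mix$n_raft,
                        run$n_relax_cycles, run$n_sample_cycles,
                        run$sample_interval, run$step_height, engine_seed)
  samples <- as.data.frame(out$samples)
  n_rec <- sum(state$m_plus)
  n_lig <- sum(state$m_minus)
  final <- state
  final$l <- out$l
  final$m_plus <- out$m_plus
  final$m_minus <- out$m_minus
  final$n_plus <- out$n_plus
  area_um2 <- state$L^2 * p$a^2 * 1e-6
  structure(list(samples = samples,
                 N = state$L^2,
                 L = state$L,
                 area_um2 = area_um2,
                 n_receptors = n_rec,
                 n_ligands = n_lig,
                 n_rafts = sum(state$n_plus),
                 raft_fraction = sum(state$n_plus) / state$L^2,
                 scenario = scen,
                 params = p,
                 run = run,
                 mix = mix,
                 engine_seed = engine_seed,
                 final_state = final,
                 running_energy = out$running,
                 recomputed_energy = out$recomputed,
                 attempted = out$attempted,
                 accepted = out$accepted),
            class = "sample_series")
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("sample_series: %d samples on %d x %d lattice (%.4g um^2)\n",
              nrow(x$samples), x$L, x$L, x$area_um2))
  cat(sprintf("  receptors %d, ligands %d, rafts %d (x = %.3f)\n",
              x$n_receptors, x$n_ligands, x$n_rafts, x$raft_fraction))
  if (nrow(x$samples) > 0)
    cat(sprintf("  <e_total> = %.4g kBT, <complexes> = %.4g\n",
                mean(x$samples$e_total), mean(x$samples$n_complexes)))
  invisible(x)
}

#' Write a sample series to CSV
#'
#' Columnar table (cycle, energy components, composition counts) preceded
#' by commented provenance header lines (config hash, seed, lattice).
#'
#' @param series A `sample_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "sample_series"))
  con <- file(path, "w")
  writeLines(c(
    "# raftadhesion sample_series",
    sprintf("# L %d area_um2 %.6g receptors %d ligands %d rafts %d",
            series$L, series$area_um2, series$n_receptors,
            series$n_ligands, series$n_rafts),
    sprintf("# engine_seed %d", series$engine_seed),
    sprintf("# config_hash %s", series_hash(series))), con)
  close(con)
  suppressWarnings(utils::write.table(series$samples, path, sep = ",",
                                      row.names = FALSE, append = TRUE,
                                      quote = FALSE))
  invisible(path)
}

series_hash <- function(series) {
  cfg <- list(scenario = series$scenario, params = unclass(series$params),
              run = unclass(series$run), mix = unclass(series$mix))
  config_hash(cfg)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}
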
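#' Read an experiment configuration
#'
#' Experiment configurations are JSON files with nested sections:
#' `scenario` (fields of [scenario_config()]), `params` (fields of
#' [model_params()]), `run` (either `preset` or fields of
#' [run_config()]), optional `sweep` (`u_grid` or `u_from`/`u_to`/`u_by`,
#' and `cR_grid`), `replicates`, and `outdir`. Missing sections use
#' defaults; every output is stamped with an MD5 hash of the parsed
#' configuration.
#'
#' @param path Path to a JSON config file, or a list already in config
#'   shape.
#' @return An `experiment_config` list.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (is.character(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else path
  if (!is.list(cfg)) stop("config must be a JSON object")
  scen <- do.call(scenario_config, as.list(cfg$scenario))
  params <- do.call(model_params, as.list(cfg$params))
  run <- if (!is.null(cfg$run$preset)) {
    rp <- run_preset(cfg$run$preset,
                     seed = if (is.null(cfg$run$seed)) 1 else cfg$run$seed)
    rp
  } else {
    do.call(run_config, as.list(cfg$run))
  }
  sweep <- cfg$sweep
  if (!is.null(sweep) && is.null(sweep$u_grid) &&
      !is.null(sweep$u_from))
    sweep$u_grid <- seq(sweep$u_from, sweep$u_to, by = sweep$u_by)
  out <- list(scenario = scen, params = params, run = run, sweep = sweep,
              replicates = if (is.null(cfg$replicates)) 3L
                           else as.integer(cfg$replicates),
              outdir = if (is.null(cfg$outdir)) "." else cfg$outdir,
              rigid = isTRUE(cfg$rigid))
  out$hash <- config_hash(out[c("scenario", "params", "run", "sweep",
                                "replicates", "rigid")])
  class(out) <- "experiment_config"
  out
}

require_fields <- function(cfg, fields, where) {
  miss <- fields[!fields %in% names(cfg) |
                   vapply(cfg[fields], is.null, TRUE)]
  if (length(miss) > 0)
    stop(sprintf("missing required config field(s) in %s: %s", where,
                 paste(miss, collapse = ", ")))
}

#' Run one simulation from a configuration
#'
#' Executes a single Monte Carlo run and persists the sample series
#' (CSV), the per-run observables row (CSV) and a final-state snapshot
#' into the configured output directory. Re-running the same
#' configuration reproduces the outputs identically.
#'
#' @param config Path to a JSON config or an `experiment_config`.
#' @return Invisibly, a list of output paths and the `sample_series`.
#' @export
cmd_simulate <- function(config) {
  cfg <- if (inherits(config, "experiment_config")) config
         else read_experiment_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  ser <- run_simulation(cfg$scenario, cfg$params, cfg$run,
                        rigid = cfg$rigid)
  tag <- substr(cfg$hash, 1, 8)
  p_series <- file.path(cfg$outdir, sprintf("series_%s.csv", tag))
  p_obs <- file.path(cfg$outdir, sprintf("observables_%s.csv", tag))
  p_state <- file.path(cfg$outdir, sprintf("state_%s.txt", tag))
  write_series_csv(ser, p_series)
  obs <- observables_row(ser)
  obs$config_hash <- cfg$hash
  utils::write.csv(obs, p_obs, row.names = FALSE)
  write_state(ser$final_state, p_state, params = cfg$params)
  invisible(list(series_csv = p_series, observables_csv = p_obs,
                 state = p_state, series = ser))
}

#' Run a phase-diagram experiment from a configuration
#'
#' Sweeps u for every receptor concentration in the sweep grid, locates
#' the CV-peak transitions and writes the phase diagram (raw and
#' normalized u*) as CSV plus a dots-with-error-bars figure.
#'
#' @param config Path to a JSON config or an `experiment_config`; its
#'   `sweep` section must provide `u_grid` and `cR_grid`.
#' @return Invisibly, the phase-diagram data frame and output paths.
#' @export
cmd_phase_diagram <- function(config) {
  cfg <- if (inherits(config, "experiment_config")) config
         else read_experiment_config(config)
  require_fields(cfg$sweep, c("u_grid", "cR_grid"), "sweep")
  if (length(cfg$sweep$cR_grid) == 0)
    stop("missing required config field(s) in sweep: cR_grid")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  pd <- build_phase_diagram(cfg$scenario, cfg$params, cfg$sweep$cR_grid,
                            cfg$sweep$u_grid, cfg$run,
                            n_replicates = cfg$replicates,
                            rigid = cfg$rigid)
  pd$config_hash <- cfg$hash
  tag <- substr(cfg$hash, 1, 8)
  p_csv <- file.path(cfg$outdir, sprintf("phase_diagram_%s.csv", tag))
  utils::write.csv(pd, p_csv, row.names = FALSE)
  p_fig <- file.path(cfg$outdir, sprintf("phase_diagram_%s.png", tag))
  grDevices::png(p_fig, width = 700, height = 500)
  plot_phase_diagram(pd)
  grDevices::dev.off()
  invisible(list(diagram = pd, csv = p_csv, figure = p_fig))
}

plot_phase_diagram <- function(pd, mf = NULL) {
  ylim <- range(c(pd$u_star_normalized - pd$u_star_sd / 1.763,
                  pd$u_star_normalized + pd$u_star_sd / 1.763, 1,
                  if (!is.null(mf)) mf$u_normalized), na.rm = TRUE)
  graphics::plot(pd$cR, pd$u_star_normalized, pch = 19, ylim = ylim,
                 xlab = expression(c[R] ~ (mu * m^-2)),
                 ylab = expression(u^"*" / u[0]^"*"),
                 main = sprintf("Phase diagram (%s ligands, x = %g)",
                                pd$scenario[1], pd$x[1]))
  sdn <- pd$u_star_sd / onsager_critical_coupling()
  graphics::arrows(pd$cR, pd$u_star_normalized - sdn,
                   pd$cR, pd$u_star_normalized + sdn,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 1, lty = 3)
  if (!is.null(mf))
    graphics::lines(mf$cR, mf$u_normalized, col = "red")
  invisible(NULL)
}

#' Mean-field phase line from a configuration
#'
#' Computes the mean-field transition line over the configured receptor
#' grid (mobile-ligand scenarios only) and writes CSV, optionally
#' overlaying an existing Monte Carlo phase diagram in the figure.
#'
#' @param config Path to a JSON config or an `experiment_config`.
#' @param mc_diagram Optional data frame from [cmd_phase_diagram()] to
#'   overlay.
#' @param Pb Contact probability; estimated at desk scale when `NULL`.
#' @return Invisibly, the mean-field line and output paths.
#' @export
cmd_mf <- function(config, mc_diagram = NULL, Pb = NULL) {
  cfg <- if (inherits(config, "experiment_config")) config
         else read_experiment_config(config)
  if (cfg$scenario$ligand_mode != "mobile")
    stop("mean-field theory is available for mobile-ligand scenarios ",
         "only; no mean-field treatment exists for immobile ligands")
  require_fields(cfg$sweep, "cR_grid", "sweep")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(Pb))
    Pb <- estimate_contact_probability(cfg$params, L = cfg$scenario$L,
                                       run = run_preset("test",
                                                        cfg$run$seed))
  mf <- mf_phase_line(cfg$scenario$x, cfg$sweep$cR_grid,
                      cL = cfg$scenario$cL, ua = cfg$params$u_a,
                      ub = cfg$params$u_b, Pb = Pb, a = cfg$params$a)
  mf$Pb <- Pb
  mf$config_hash <- cfg$hash
  tag <- substr(cfg$hash, 1, 8)
  p_csv <- file.path(cfg$outdir, sprintf("mf_phase_line_%s.csv", tag))
  utils::write.csv(mf, p_csv, row.names = FALSE)
  p_fig <- NULL
  if (!is.null(mc_diagram)) {
    p_fig <- file.path(cfg$outdir, sprintf("mf_overlay_%s.png", tag))
    grDevices::png(p_fig, width = 700, height = 500)
    plot_phase_diagram(mc_diagram, mf = mf)
    grDevices::dev.off()
  }
  invisible(list(mf_line = mf, csv = p_csv, figure = p_fig))
}

#' Fast validation suite
#'
#' Runs the quick correctness oracles: stencil arithmetic, detailed
#' balance of the acceptance rule, exact 4x4 lattice-gas enumeration vs
#' Monte Carlo, the dilute two-state raft-partition law, the mean-field
#' critical point and the analytic lattice-gas critical constant. Each
#' check reports measured vs expected and a pass flag.
#'
#' @param seed RNG seed for the stochastic checks.
#' @return A data frame (check, measured, expected, tol, pass).
#' @export
cmd_validate <- function(seed = 1) {
  checks <- list()
  add <- function(name, measured, expected, tol) {
    checks[[length(checks) + 1]] <<-
      data.frame(check = name, measured = measured, expected = expected,
                 tol = tol, pass = abs(measured - expected) <= tol,
                 seed = seed)
  }
  p <- model_params(u = 1.5)

  # single-bump bending energy: 20 h^2 stencil sum
  st <- lattice_state(8, l0 = 20)
  st$l[10] <- 21
  add("bending_single_bump", bending_energy(st, p),
      10 * p$kappa / p$a^2, 1e-12)

  # detailed balance of the analytic acceptance rule
  dh <- 1.37
  add("detailed_balance_ratio",
      metropolis_accept_prob(dh) / metropolis_accept_prob(-dh),
      exp(-dh), 1e-12)

  # 4x4 fixed-N lattice-gas: exact enumeration vs MC heat capacity
  ex <- lattice_gas_exact(4, 8, p$u)
  scen <- scenario_config(L = 4, x = 0.5, cR = 0, cL = 0,
                          ligand_mode = "random", seed = seed)
  ser <- run_simulation(scen, p, run_config(2e4, 2e5, sample_interval = 20,
                                            seed = seed),
                        mix = move_mix(0, 0, 8))
  add("lattice_gas_4x4_cv", heat_capacity(ser), ex$cv, 0.08 * ex$cv + 0.01)

  # dilute two-state raft partition: in/out concentration ratio -> e^ua
  p0 <- model_params(u = 0, u_a = 3)
  scen2 <- scenario_config(L = 32, x = 0.2, cR = 125, cL = 0,
                           ligand_mode = "random", seed = seed)
  st2 <- build_initial_state(scen2, p0)
  ser2 <- run_simulation(st2, p0, run_config(1e4, 4e4,
                                             sample_interval = 10,
                                             seed = seed),
                         mix = move_mix(0, sum(st2$m_plus),
                                        sum(st2$n_plus)))
  cin <- raft_receptor_concentration(ser2)
  nin <- mean(ser2$samples$n_receptors_on_rafts)
  nout <- ser2$n_receptors - nin
  cout <- nout / ((1 - ser2$raft_fraction) * ser2$area_um2)
  add("two_state_partition_ratio", cin / cout, exp(3), 0.15 * exp(3))

  # mean-field critical point at cR = 0, x = 1/2
  sol <- solve_self_consistent(mf_config(x = 0.5, cR = 0, u = 0.5))
  add("mf_critical_u", sol$u_transition, 1.0, 1e-6)

  # analytic lattice-gas critical coupling
  add("onsager_constant", onsager_critical_coupling(),
      2 * log(1 + sqrt(2)), 0)

  do.call(rbind, checks)
}

#' Command-line entry point
#'
#' Dispatches the pipeline commands for use with `Rscript`:
#' ```
#' Rscript -e 'raftadhesion::adhesion_cli()' simulate config.json
#' ```
#' Commands: `simulate`, `phase-diagram`, `mf`, `validate`,
#' `describe` (print realized scenario composition). All but
#' `validate` take a JSON config path.
#'
#' @param argv Command-line arguments; defaults to
#'   [commandArgs()]`(trailingOnly = TRUE)`.
#' @return The invoked command's value, invisibly.
#' @export
adhesion_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) < 1)
    stop("usage: adhesion_cli <simulate|phase-diagram|mf|validate|",
         "describe> [config.json]")
  cmd <- argv[1]
  if (cmd == "validate") {
    rep <- cmd_validate(seed = if (length(argv) > 1)
      as.integer(argv[2]) else 1L)
    print(rep)
    if (!all(rep$pass)) stop("validation checks failed")
    return(invisible(rep))
  }
  if (!cmd %in% c("simulate", "phase-diagram", "mf", "describe"))
    stop(sprintf("unknown command '%s'", cmd))
  if (length(argv) < 2) stop(sprintf("command '%s' needs a config", cmd))
  cfg <- read_experiment_config(argv[2])
  switch(cmd,
         "simulate" = invisible(cmd_simulate(cfg)),
         "phase-diagram" = invisible(cmd_phase_diagram(cfg)),
         "mf" = invisible(cmd_mf(cfg)),
         "describe" = {
           d <- describe_scenario(cfg$scenario, cfg$params)
           print(d)
           invisible(d)
         },
         stop(sprintf("unknown command '%s'", cmd)))
}

#' Exact fixed-composition lattice-gas reference
#'
#' Enumerates all `choose(L^2, n)` raft configurations of an L x L
#' periodic lattice at fixed raft count n (the ensemble sampled by the
#' conserved hopping dynamics), returning the exact Boltzmann averages
#' of the contact energy and the heat capacity per site, plus the energy
#' level probabilities. Feasible for L = 4.
#'
#' @param L Lattice size (use 4).
#' @param n Raft count.
#' @param u Contact energy, kBT.
#' @return List with `mean_e`, `cv`, `levels` (data frame of energy
#'   levels and probabilities).
#' @export
lattice_gas_exact <- function(L, n, u) {
  N <- L^2
  if (choose(N, n) > 2e6) stop("enumeration too large")
  combs <- utils::combn(N, n)
  p <- model_params(u = u)
  st <- lattice_state(L, l0 = p$l_c)
  right <- vapply(1:N, function(i) neighbor_site(L, i, 1L), 1L)
  down <- vapply(1:N, function(i) neighbor_site(L, i, 3L), 1L)
  e <- apply(combs, 2, function(occ) {
    v <- logical(N)
    v[occ] <- TRUE
    -u * (sum(v & v[right]) + sum(v & v[down]))
  })
  wt <- exp(-(e - min(e)))
  Z <- sum(wt)
  me <- sum(wt * e) / Z
  me2 <- sum(wt * e^2) / Z
  lev <- stats::aggregate(list(prob = wt / Z), by = list(energy = e), sum)
  list(mean_e = me, cv = (me2 - me^2) / N, levels = lev)
}
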
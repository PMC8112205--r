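test_that("heat capacity: hand cases, invariance to energy offset,
           error below 2 samples", {
  expect_equal(heat_capacity(rep(3.7, 10), N = 4), 0)
  expect_equal(heat_capacity(c(0, 2), N = 1), 1)  # variance 1
  expect_equal(heat_capacity(c(0, 2) + 123.4, N = 1), 1)
  expect_error(heat_capacity(1.0, N = 1), "at least 2")
})

test_that("count_complexes matches a brute-force per-site scan", {
  p <- model_params()
  st <- lattice_state(5, l0 = p$l_c)
  expect_equal(count_complexes(st, p), 0)
  st$m_plus[7] <- 1L; st$m_minus[7] <- 1L
  expect_equal(count_complexes(st, p), 1)
  st$l[7] <- 16.2  # outside the 1 nm well around 15
  expect_equal(count_complexes(st, p), 0)
  for (seed in 1:4) {
    str <- random_state(8, seed = seed, n_rec = 20, n_lig = 20,
                        rough = 0.8)
    brute <- sum(vapply(seq_len(64), function(i) {
      str$m_plus[i] == 1L && str$m_minus[i] == 1L &&
        str$l[i] > p$l_c - p$l_b / 2 && str$l[i] < p$l_c + p$l_b / 2
    }, TRUE))
    expect_equal(count_complexes(str, p), brute)
  }
})

test_that("binding constant: zero without complexes, saturation is an
           error, and the 2x2 exact enumeration value is recovered", {
  p <- model_params(u_b = 4, u = 0)
  # no complexes ever: K = 0 (membrane far from the well)
  st0 <- lattice_state(4, l0 = 40, ligands_mobile = TRUE)
  st0$m_plus[1] <- 1L; st0$m_minus[2] <- 1L
  ser0 <- run_simulation(st0, p, tiny_run(2), mix = move_mix(0, 2, 0))
  expect_equal(binding_constant(ser0), 0)
  # exact 2x2 enumeration: 1 receptor, 1 mobile ligand, rigid flat at lc,
  # 16 placements, bound iff same site with weight e^ub
  st <- lattice_state(2, l0 = p$l_c, ligands_mobile = TRUE)
  st$m_plus[1] <- 1L; st$m_minus[4] <- 1L
  ser <- run_simulation(st, p, run_config(1e4, 3e5, sample_interval = 2,
                                          seed = 3),
                        mix = move_mix(0, 2, 0))
  Pb <- exp(4) / (exp(4) + 3)
  A <- 4 * (10 * 10) * 1e-6  # um^2
  K_exact <- A * Pb / (1 - Pb)^2
  expect_equal(binding_constant(ser), K_exact, tolerance = 0.1)
  # conservation at every sample: complexes never exceed pools
  expect_true(all(ser$samples$n_complexes <= 1))
  # saturated pool -> informative error
  sat <- ser
  sat$samples$n_complexes <- rep(1, nrow(ser$samples))
  expect_error(binding_constant(sat), "saturated")
})

test_that("K is intensive: doubling the box at fixed concentrations
           leaves K unchanged within error", {
  p <- model_params(u_b = 6, u = 0)
  run <- run_config(5e3, 4e4, sample_interval = 10, seed = 11)
  ks <- vapply(c(8, 16), function(L) {
    scen <- scenario_config(L = L, x = 0, cR = 1500, cL = 1500,
                            ligand_mode = "mobile", seed = 7)
    ser <- run_simulation(scen, p, run)
    binding_constant(ser)
  }, 1.0)
  expect_equal(ks[1], ks[2], tolerance = 0.25)
})

test_that("conservation: [RL] + [R] = cR and [RL] + [L] = cL at every
           sample", {
  p <- model_params(u = 1.2)
  scen <- scenario_config(L = 12, x = 0.2, cR = 1500, cL = 1000,
                          ligand_mode = "mobile", seed = 3)
  st <- build_initial_state(scen, p)
  ser <- run_simulation(st, p, tiny_run(4))
  s <- ser$samples
  expect_true(all(s$n_complexes >= 0))
  expect_true(all(s$n_complexes <= min(ser$n_receptors, ser$n_ligands)))
  # counts are conserved identically: free = total - bound at all times
  expect_equal(ser$n_receptors - s$n_complexes + s$n_complexes,
               rep(ser$n_receptors, nrow(s)))
  expect_equal(ser$n_ligands - s$n_complexes + s$n_complexes,
               rep(ser$n_ligands, nrow(s)))
})

test_that("raft-receptor concentration: saturation bound, dilute
           two-state Boltzmann ratio, and ua = 0 neutrality", {
  # all receptors on rafts: cR / x
  p <- model_params(u = 0, u_a = 0)
  st <- lattice_state(10, l0 = 40)
  st$n_plus[1:20] <- 1L           # x = 0.2
  st$m_plus[1:10] <- 1L           # all 10 receptors on raft patches
  ser <- run_simulation(st, p, tiny_run(5, relax = 0, sample = 10,
                                        interval = 1),
                        mix = move_mix(64, 0, 0))
  area <- 100 * 100 * 1e-6
  expect_equal(raft_receptor_concentration(ser),
               mean(ser$samples$n_receptors_on_rafts) / (0.2 * area))
  expect_error(raft_receptor_concentration(
    run_simulation(lattice_state(4, l0 = 4), model_params(),
                   tiny_run(1, relax = 0, sample = 10, interval = 1),
                   mix = move_mix(16, 0, 0))), "x = 0")
  # ua = 0: in-raft concentration equals overall cR within error
  p0 <- model_params(u = 0, u_a = 0)
  scen <- scenario_config(L = 24, x = 0.25, cR = 1000, cL = 0,
                          ligand_mode = "random", seed = 5)
  st0 <- build_initial_state(scen, p0)
  ser0 <- run_simulation(st0, p0,
                         run_config(5e3, 3e4, sample_interval = 10,
                                    seed = 5),
                         mix = move_mix(0, sum(st0$m_plus),
                                        sum(st0$n_plus)))
  cr_overall <- ser0$n_receptors / ser0$area_um2
  expect_equal(raft_receptor_concentration(ser0), cr_overall,
               tolerance = 0.1)
  # dilute limit with ua = 3: in/out ratio -> e^3
  p3 <- model_params(u = 0, u_a = 3)
  scen3 <- scenario_config(L = 32, x = 0.2, cR = 125, cL = 0,
                           ligand_mode = "random", seed = 4)
  st3 <- build_initial_state(scen3, p3)
  ser3 <- run_simulation(st3, p3,
                         run_config(1e4, 5e4, sample_interval = 10,
                                    seed = 6),
                         mix = move_mix(0, sum(st3$m_plus),
                                        sum(st3$n_plus)))
  nin <- mean(ser3$samples$n_receptors_on_rafts)
  cin <- raft_receptor_concentration(ser3)
  cout <- (ser3$n_receptors - nin) /
    ((1 - ser3$raft_fraction) * ser3$area_um2)
  expect_equal(cin / cout, exp(3), tolerance = 0.12)
})

test_that("replicate aggregation uses the population SD", {
  expect_equal(aggregate_replicates(c(1, 1, 1)),
               list(mean = 1, sd = 0, n_replicates = 3))
  expect_equal(aggregate_replicates(c(0, 2)),
               list(mean = 1, sd = 1, n_replicates = 2))
  x <- c(2.3, -1.1, 0.4, 5.5, 3.2)
  agg <- aggregate_replicates(x)
  expect_equal(agg$mean, mean(x))
  expect_equal(agg$sd, stats::sd(x) * sqrt((length(x) - 1) / length(x)))
  expect_error(aggregate_replicates(numeric(0)), "at least one")
})
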
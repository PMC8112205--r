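test_that("Metropolis rule: downhill always accepted, uphill with
           probability exp(-dH), detailed balance exact", {
  set.seed(1)
  expect_true(all(replicate(50, metropolis_accept(-1))))
  expect_true(all(replicate(50, metropolis_accept(0))))  # exp(0) = 1
  expect_error(metropolis_accept(NaN), "non-finite")
  # analytic detailed balance for constructed state pairs
  for (dh in c(0.3, 1.7, 4)) {
    expect_identical(metropolis_accept_prob(-dh), 1)
    expect_equal(metropolis_accept_prob(dh) / metropolis_accept_prob(-dh),
                 exp(-dh), tolerance = 1e-15)
  }
  # empirical acceptance at dH = 2: e^-2 within 3 sigma binomial
  set.seed(7)
  n <- 1e5
  acc <- sum(replicate(n, metropolis_accept(2)))
  pexp <- exp(-2)
  expect_lt(abs(acc / n - pexp), 3 * sqrt(pexp * (1 - pexp) / n))
})

test_that("height moves respect the l >= 0 hard constraint and the
           rigid limit suppresses deformation", {
  p <- model_params()
  st <- lattice_state(8, l0 = 0.2)
  set.seed(3)
  out <- try_height_move(st, p, 5, dl = -0.3)  # would give l = -0.1
  expect_false(out$accepted)
  expect_identical(out$state$l, st$l)
  # engine-level: no site ever below 0 near the floor
  stf <- lattice_state(8, l0 = 0.3)
  ser <- run_simulation(stf, p, tiny_run(5), mix = move_mix(64, 0, 0))
  expect_true(all(ser$final_state$l >= 0))
  # flat free membrane: acceptance strictly between 0 and 1
  st15 <- lattice_state(8, l0 = 15)
  ser2 <- run_simulation(st15, p, tiny_run(6), mix = move_mix(64, 0, 0))
  rate <- ser2$accepted[["height"]] / ser2$attempted[["height"]]
  expect_gt(rate, 0); expect_lt(rate, 1)
  # very rigid membrane: non-flat proposals essentially never accepted
  pr <- model_params(kappa = 1e7)
  ser3 <- run_simulation(st15, pr, tiny_run(7), mix = move_mix(64, 0, 0))
  expect_lt(ser3$accepted[["height"]] / ser3$attempted[["height"]], 0.01)
  expect_lt(max(abs(ser3$final_state$l - 15)), 0.5)
})

test_that("protein hops: exclusion, raft-coupling cost, neutral hop;
           raft hops leave receptors behind", {
  p <- model_params()
  st <- lattice_state(6, l0 = 30)  # far from well: no binding terms
  st$m_plus[c(1, 2)] <- 1L         # sites 1,2 adjacent (same column)
  # destination occupied -> rejected outright
  out <- try_protein_hop(st, p, "upper", 1, "down")
  expect_false(out$accepted)
  expect_true(is.na(out$delta))
  expect_error(try_protein_hop(st, p, "upper", 9, 1), "no protein")
  # hop from raft to non-raft: dH = +ua
  st2 <- lattice_state(6, l0 = 30)
  st2$m_plus[8] <- 1L; st2$n_plus[8] <- 1L
  expect_equal(local_delta_energy(st2, p, protein_hop("upper", 8, 1)),
               p$u_a)
  # neutral hop between empty equivalent patches: dH = 0, accepted
  st3 <- lattice_state(6, l0 = 30)
  st3$m_plus[8] <- 1L
  out3 <- try_protein_hop(st3, p, "upper", 8, 1)
  expect_true(out3$accepted)
  expect_identical(out3$delta, 0)
  # raft hop away from a receptor-carrying patch costs +ua and the
  # receptor stays
  st4 <- lattice_state(6, l0 = 30)
  st4$n_plus[8] <- 1L; st4$m_plus[8] <- 1L
  mv <- raft_hop(8, 1)
  expect_equal(local_delta_energy(st4, p, mv), p$u_a)
  after <- apply_move(st4, mv)
  expect_identical(after$m_plus[8], 1L)
  expect_identical(after$n_plus[8], 0L)
  # raft detaching from a dimer: dH = +u
  pu <- model_params(u = 1.3)
  st5 <- lattice_state(6, l0 = 30)
  st5$n_plus[c(1, 2)] <- 1L
  expect_equal(local_delta_energy(st5, pu, raft_hop(2, 3)), 1.3)
  expect_error(try_raft_hop(st5, pu, 9, 1), "no raft")
})

test_that("immobile-ligand runs never move ligands; mobile runs do", {
  p <- model_params()
  scen <- scenario_config(L = 12, x = 0.2, cR = 1000, cL = 1000,
                          ligand_mode = "random", seed = 5)
  st <- build_initial_state(scen, p)
  ser <- run_simulation(st, p, tiny_run(8))
  expect_identical(ser$final_state$m_minus, st$m_minus)
  expect_error(try_protein_hop(st, p, "lower",
                               which(st$m_minus == 1L)[1], 1),
               "immobile")
  scen2 <- scenario_config(L = 12, x = 0.2, cR = 1000, cL = 1000,
                           ligand_mode = "mobile", seed = 5)
  st2 <- build_initial_state(scen2, p)
  ser2 <- run_simulation(st2, p, tiny_run(8))
  expect_false(identical(ser2$final_state$m_minus, st2$m_minus))
  expect_identical(sum(ser2$final_state$m_minus), sum(st2$m_minus))
})

test_that("hard constraints hold after long runs and counts are
           conserved", {
  p <- model_params(u = 1.5)
  scen <- scenario_config(L = 16, x = 0.25, cR = 1500, cL = 1000,
                          ligand_mode = "mobile", seed = 9)
  st <- build_initial_state(scen, p)
  ser <- run_simulation(st, p, tiny_run(10, relax = 2e3, sample = 2e3))
  fin <- ser$final_state
  expect_true(all(fin$l >= 0))
  expect_true(all(fin$m_plus %in% 0:1))
  expect_identical(sum(fin$m_plus), sum(st$m_plus))
  expect_identical(sum(fin$m_minus), sum(st$m_minus))
  expect_identical(sum(fin$n_plus), sum(st$n_plus))
})

test_that("same seed and config give bit-identical trajectories", {
  p <- model_params(u = 1.5)
  scen <- scenario_config(L = 12, x = 0.2, cR = 1000, cL = 1000,
                          ligand_mode = "mobile", seed = 2)
  a <- run_simulation(scen, p, tiny_run(42))
  b <- run_simulation(scen, p, tiny_run(42))
  expect_identical(a$samples, b$samples)
  expect_identical(a$final_state$l, b$final_state$l)
  c <- run_simulation(scen, p, tiny_run(43))
  expect_false(identical(a$samples$e_total, c$samples$e_total))
})

test_that("incremental energies drift less than 1e-6 kBT from full
           recomputation over >1e6 moves", {
  p <- model_params(u = 1.6)
  scen <- scenario_config(L = 16, x = 0.2, cR = 2000, cL = 1000,
                          ligand_mode = "mobile", seed = 12)
  st <- build_initial_state(scen, p)
  # ~1.3e6 attempted moves: 256 height + ~150 hops per cycle, 3200 cycles
  ser <- run_simulation(st, p, run_config(0, 3200, sample_interval = 3200,
                                          seed = 13))
  expect_gt(sum(ser$attempted), 1e6)
  expect_lt(max(abs(ser$running_energy - ser$recomputed_energy)), 1e-6)
})

test_that("run_cycle with an empty mix leaves the state unchanged and
           the rigid no-protein limit reduces to raft-only dynamics", {
  p <- model_params(u = 1)
  st <- random_state(8, seed = 21)
  expect_error(move_mix(0, 0, 0), "positive")
  ser <- run_simulation(st, p, tiny_run(3), mix = move_mix(0, 0, 12))
  expect_identical(ser$final_state$l, st$l)          # membrane frozen
  expect_identical(ser$final_state$m_plus, st$m_plus)  # proteins frozen
  expect_identical(sum(ser$final_state$n_plus), sum(st$n_plus))
})

test_that("free membrane satisfies equipartition of the discretized
           bending Hamiltonian", {
  p <- model_params()
  st <- lattice_state(16, l0 = 15)
  ser <- run_simulation(st, p, run_config(3e4, 6e4, sample_interval = 20,
                                          seed = 17),
                        mix = move_mix(256, 0, 0))
  # (N - 1)/2 kBT: one quadratic dof per non-zero mode
  expect_equal(mean(ser$samples$e_bend), (256 - 1) / 2, tolerance = 0.04)
  # measured contact probability matches the Gaussian roughness oracle
  pb <- mean(ser$samples$n_in_well) / 256
  expect_equal(pb, contact_probability_theory(p, 16), tolerance = 0.25)
})

test_that("rigid no-protein raft sector samples the exact fixed-N 4x4
           lattice gas", {
  u <- 1.5
  p <- model_params(u = u)
  ex <- lattice_gas_exact(4, 8, u)
  scen <- scenario_config(L = 4, x = 0.5, cR = 0, cL = 0,
                          ligand_mode = "random", seed = 1)
  ser <- run_simulation(scen, p, run_config(2e4, 2e5,
                                            sample_interval = 20,
                                            seed = 5),
                        mix = move_mix(0, 0, 8))
  expect_equal(mean(ser$samples$e_total), ex$mean_e, tolerance = 0.01)
  expect_equal(heat_capacity(ser), ex$cv, tolerance = 0.08)
  # energy-level histogram vs exact probabilities (goodness of fit on
  # thinned, fixed-seed samples)
  obs <- table(factor(ser$samples$e_total, levels = ex$levels$energy))
  pr <- ex$levels$prob
  keep <- pr > 1e-4
  chi2 <- sum((as.numeric(obs[keep]) - sum(obs) * pr[keep])^2 /
                (sum(obs) * pr[keep]))
  # correlated samples inflate chi2; generous fixed-seed bound
  expect_lt(chi2, 5 * sum(keep))
  expect_lt(sum(abs(as.numeric(obs) / sum(obs) - pr)) / 2, 0.05)  # TV
})
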
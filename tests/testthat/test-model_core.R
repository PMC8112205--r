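test_that("discrete Laplacian matches stencil arithmetic and the
           direct-summation oracle", {
  p <- model_params()
  # constant field -> 0 everywhere
  st <- lattice_state(6, l0 = 20)
  expect_equal(discrete_laplacian(st), rep(0, 36))
  # single bump of height h: -4h at the bump, +h at its 4 neighbours
  st$l[8] <- 20 + 2.5
  lap <- discrete_laplacian(st)
  expect_equal(lap[8], -10)
  nb <- vapply(1:4, function(d) neighbor_site(6, 8, d), 1L)
  expect_equal(lap[nb], rep(2.5, 4))
  expect_equal(sum(lap != 0), 5)
  # random field vs independent implementation, all sites
  st2 <- random_state(8, seed = 42)
  expect_equal(discrete_laplacian(st2), oracle_laplacian(st2$l, 8))
  expect_equal(discrete_laplacian(st2, site = 17),
               oracle_laplacian(st2$l, 8)[17])
})

test_that("energy terms reproduce hand-evaluated cases", {
  p <- model_params(kappa = 10, a = 10, u_b = 6, u_a = 3, u = 1.7)
  st <- lattice_state(8, l0 = 20)
  expect_equal(bending_energy(st, p), 0)
  # single bump h: stencil sum 20 h^2, energy 10 kappa h^2 / a^2
  st$l[10] <- 21
  expect_equal(bending_energy(st, p), 1.0)
  st$l[10] <- 20 + 3
  expect_equal(bending_energy(st, p), 10 * p$kappa * 9 / p$a^2)

  # square-well binding: apposed pair inside/outside the well
  st <- lattice_state(5, l0 = p$l_c)
  st$m_plus[7] <- 1L; st$m_minus[7] <- 1L
  expect_equal(binding_energy(st, p), -6)
  st$l[7] <- p$l_c + p$l_b          # outside
  expect_equal(binding_energy(st, p), 0)
  st$l[7] <- p$l_c + p$l_b / 2      # boundary: strict inequality
  expect_equal(binding_energy(st, p), 0)
  st$l[7] <- p$l_c
  st$m_minus[7] <- 0L               # receptor with no apposed ligand
  expect_equal(binding_energy(st, p), 0)

  # raft-receptor coupling: -ua per receptor on a raft patch
  st <- lattice_state(5, l0 = p$l_c)
  st$n_plus[3] <- 1L; st$m_plus[3] <- 1L
  expect_equal(raft_receptor_energy(st, p), -3)
  st$m_plus[4] <- 1L                # receptor off-raft adds nothing
  expect_equal(raft_receptor_energy(st, p), -3)
  st$n_plus[c(10, 11)] <- 1L; st$m_plus[c(10, 11)] <- 1L
  expect_equal(raft_receptor_energy(st, p), -3 * 3)

  # raft-raft contacts: single pair, isolated patch, full coverage
  st <- lattice_state(5, l0 = p$l_c)
  st$n_plus[c(7, 8)] <- 1L          # adjacent in a column
  expect_equal(raft_raft_energy(st, p), -p$u)
  st <- lattice_state(5, l0 = p$l_c)
  st$n_plus[13] <- 1L
  expect_equal(raft_raft_energy(st, p), 0)
  st$n_plus[] <- 1L                 # full coverage: 2 bonds per site
  expect_equal(raft_raft_energy(st, p), -2 * p$u * 25)
})

test_that("total energy is the exact component sum and matches the
           direct-summation oracle on random states", {
  for (seed in 1:5) {
    p <- model_params(u = 0.3 + 0.4 * seed)
    st <- random_state(8, seed = seed, p = p)
    e <- total_energy(st, p)
    expect_identical(e$e_total,
                     e$e_bend + e$e_bind + e$e_raft_receptor +
                       e$e_raft_raft)
    o <- oracle_energy(st, p)
    for (f in names(o)) expect_equal(e[[f]], o[[f]], tolerance = 1e-12)
    # sign structure: bending >= 0, all couplings <= 0
    expect_gte(e$e_bend, 0)
    expect_lte(e$e_bind, 0)
    expect_lte(e$e_raft_receptor, 0)
    expect_lte(e$e_raft_raft, 0)
  }
  # empty flat lattice: all zero
  e0 <- total_energy(lattice_state(6, l0 = 12), model_params())
  expect_equal(unlist(e0), c(e_bend = 0, e_bind = 0,
                             e_raft_receptor = 0, e_raft_raft = 0,
                             e_total = 0))
})

test_that("energies are invariant under lattice translation and under
           a uniform separation shift", {
  p <- model_params(u = 1.2)
  st <- random_state(8, seed = 7, p = p)
  e <- unlist(total_energy(st, p))
  for (shift in list(c(1L, 0L), c(0L, 1L), c(3L, 5L))) {
    e2 <- unlist(total_energy(translate_state(st, shift[1], shift[2]), p))
    expect_equal(e2, e, tolerance = 1e-12)
  }
  st2 <- st
  st2$l <- st2$l + 7.3
  expect_equal(bending_energy(st2, p), bending_energy(st, p),
               tolerance = 1e-9)
})

test_that("local_delta_energy equals brute-force total-energy difference
           for all move types", {
  p <- model_params(u = 0.9)
  st <- random_state(8, seed = 11, p = p)
  brute <- function(st, mv) {
    oracle_energy(apply_move(st, mv), p)$e_total -
      oracle_energy(st, p)$e_total
  }
  set.seed(99)
  for (k in 1:40) {
    i <- sample.int(64, 1)
    mv <- height_move(i, runif(1, -1, 1))
    if (st$l[i] + mv$dl >= 0)
      expect_equal(local_delta_energy(st, p, mv), brute(st, mv),
                   tolerance = 1e-9)
  }
  # protein and raft hops over every occupied site and direction
  for (i in which(st$m_plus == 1L)) for (d in 1:4) {
    to <- neighbor_site(8, i, d)
    if (st$m_plus[to] == 0L) {
      mv <- protein_hop("upper", i, d)
      expect_equal(local_delta_energy(st, p, mv), brute(st, mv),
                   tolerance = 1e-9)
    }
  }
  for (i in which(st$m_minus == 1L)) for (d in 1:4) {
    to <- neighbor_site(8, i, d)
    if (st$m_minus[to] == 0L) {
      mv <- protein_hop("lower", i, d)
      expect_equal(local_delta_energy(st, p, mv), brute(st, mv),
                   tolerance = 1e-9)
    }
  }
  for (i in which(st$n_plus == 1L)) for (d in 1:4) {
    to <- neighbor_site(8, i, d)
    if (st$n_plus[to] == 0L) {
      mv <- raft_hop(i, d)
      expect_equal(local_delta_energy(st, p, mv), brute(st, mv),
                   tolerance = 1e-9)
    }
  }
  # decoupled cases
  stf <- lattice_state(8, l0 = 20)
  expect_equal(local_delta_energy(stf, p, height_move(5, 1)),
               p$kappa / (2 * p$a^2) * 20)  # pure bending, h = 1
  str <- lattice_state(8, l0 = 20)
  str$n_plus[1] <- 1L
  expect_equal(local_delta_energy(str, p, raft_hop(1, 1)), 0)
})

test_that("local_delta_energy rejects contract violations", {
  p <- model_params()
  st <- random_state(8, seed = 3)
  expect_error(local_delta_energy(st, p, list(foo = 1)),
               "invalid move")
  empty <- which(st$m_plus == 0L)[1]
  expect_error(local_delta_energy(st, p, protein_hop("upper", empty, 1)),
               "no receptor")
  emptyr <- which(st$n_plus == 0L)[1]
  expect_error(local_delta_energy(st, p, raft_hop(emptyr, 1)),
               "no raft")
})

test_that("state snapshot serialization round-trips losslessly", {
  p <- model_params(u = 1.234567890123)
  st <- random_state(8, seed = 13, p = p)
  f <- tempfile(fileext = ".txt")
  write_state(st, f, params = p)
  back <- read_state(f)
  expect_identical(back$state$L, st$L)
  expect_identical(back$state$l, st$l)
  expect_identical(back$state$m_plus, st$m_plus)
  expect_identical(back$state$m_minus, st$m_minus)
  expect_identical(back$state$n_plus, st$n_plus)
  expect_identical(back$state$ligands_mobile, st$ligands_mobile)
  expect_equal(unclass(back$params)[1:7], unclass(p)[1:7])
  unlink(f)
})

test_that("model_params validates its invariants", {
  expect_error(model_params(kappa = -1), "kappa")
  expect_error(model_params(l_b = 20, l_c = 15), "l_b")
  expect_silent(model_params(u_b = 4))
})
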
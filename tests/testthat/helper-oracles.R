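# Independent oracles and small fixture builders.
# Everything here is deliberately written without reference to the
# package's compiled code paths: plain-R direct summation only.

# Direct-summation 5-point Laplacian (independent of the C++ stencil).
oracle_laplacian <- function(l, L) {
  m <- matrix(l, L, L)
  up <- rbind(m[L, , drop = FALSE], m[-L, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE])
  lf <- cbind(m[, L, drop = FALSE], m[, -L, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], m[, 1, drop = FALSE])
  as.vector(up + dn + lf + rt - 4 * m)
}

# Full-recompute energy oracle: direct sums over sites and bonds.
oracle_energy <- function(state, p) {
  L <- state$L
  lap <- oracle_laplacian(state$l, L)
  e_bend <- p$kappa / (2 * p$a^2) * sum(lap^2)
  inwell <- state$l > p$l_c - p$l_b / 2 & state$l < p$l_c + p$l_b / 2
  e_bind <- -p$u_b * sum(state$m_plus * state$m_minus * inwell)
  e_rp <- -p$u_a * sum(state$n_plus * state$m_plus)
  m <- matrix(state$n_plus, L, L)
  rt <- cbind(m[, -1, drop = FALSE], m[, 1, drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE])
  e_rr <- -p$u * (sum(m * rt) + sum(m * dn))
  list(e_bend = e_bend, e_bind = e_bind, e_raft_receptor = e_rp,
       e_raft_raft = e_rr,
       e_total = e_bend + e_bind + e_rp + e_rr)
}

# Random small state with all species present.
random_state <- function(L = 8, seed = 1, p = model_params(),
                         n_rec = 6, n_lig = 6, n_raft = 12,
                         mobile = TRUE, rough = 2) {
  set.seed(seed)
  st <- lattice_state(L, l0 = p$l_c, ligands_mobile = mobile)
  st$l <- pmax(0, p$l_c + stats::runif(L^2, -rough, rough))
  st$m_plus[sample.int(L^2, n_rec)] <- 1L
  st$m_minus[sample.int(L^2, n_lig)] <- 1L
  st$n_plus[sample.int(L^2, n_raft)] <- 1L
  st
}

# Translate the whole configuration by one lattice vector.
translate_state <- function(state, dr = 1L, dc = 0L) {
  L <- state$L
  perm <- function(v) {
    m <- matrix(v, L, L)
    m <- m[((seq_len(L) - 1L - dr) %% L) + 1L,
           ((seq_len(L) - 1L - dc) %% L) + 1L, drop = FALSE]
    as.vector(m)
  }
  state$l <- perm(state$l)
  state$m_plus <- as.integer(perm(state$m_plus))
  state$m_minus <- as.integer(perm(state$m_minus))
  state$n_plus <- as.integer(perm(state$n_plus))
  state
}

# Fast scaled-down run configs used across tests.
tiny_run <- function(seed, relax = 1e3, sample = 2e3, interval = 5)
  run_config(relax, sample, sample_interval = interval, seed = seed)
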
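# Fast positional-index evaluation of the reaction terms ----------------------
#
# Private hot-path variants of the reaction terms used by the steady-state
# solver, the LSA scans and the simulator. They operate on plain numeric
# vectors (m: 7 membrane, c: 3 cytosolic concentrations, k: 14 rates in
# canonical order) without validation or name lookups. The exported, validated
# functions in model_core.R remain the reference implementations; equality of
# the two layers is asserted in the test suite.
#
# Rate order (RATE_NAMES): 1 k_D, 2 k_tD, 3 k_bfD, 4 k_d, 5 k_fd, 6 k_bfd,
# 7 k_tg, 8 k_gt, 9 k_tB, 10 k_b, 11 k_bF, 12 k_bf, 13 k_F, 14 k_f
# Membrane order: 1 m_d, 2 m_t, 3 m_tg, 4 m_g, 5 m_b, 6 m_bf, 7 m_f
# Cytosol order: 1 c_D, 2 c_B, 3 c_F

g_fast <- function(m, c, k) {
  act <- k[5] * m[7] + k[6] * m[6]
  gtg <- k[7] * m[2] * m[4] - k[8] * m[3]
  c((k[1] + k[2] * m[2]) * c[1] + k[8] * m[3] - act * m[1] - k[4] * m[1],
    act * m[1] + k[3] * m[6] * c[1] - k[7] * m[2] * m[4],
    gtg,
    -gtg,
    k[9] * m[2] * c[2] - k[10] * m[5] + k[12] * m[6] - k[11] * m[5] * c[3],
    k[11] * m[5] * c[3] - k[12] * m[6],
    k[13] * c[3] - k[14] * m[7])
}

f_fast <- function(m, c, k) {
  c(k[4] * m[1] - (k[1] + k[2] * m[2] + k[3] * m[6]) * c[1],
    k[10] * m[5] - k[9] * m[2] * c[2],
    k[14] * m[7] + k[12] * m[6] - (k[13] + k[11] * m[5]) * c[3])
}

# Jacobian blocks as plain matrices (same layout as reaction_jacobians)
jac_fast <- function(m, c, k) {
  G_m <- matrix(0, 7, 7); G_c <- matrix(0, 7, 3)
  F_m <- matrix(0, 3, 7); F_c <- matrix(0, 3, 3)
  act <- k[5] * m[7] + k[6] * m[6]
  F_c[1, 1] <- -(k[1] + k[2] * m[2] + k[3] * m[6])
  F_m[1, 1] <- k[4]; F_m[1, 2] <- -k[2] * c[1]; F_m[1, 6] <- -k[3] * c[1]
  F_c[2, 2] <- -k[9] * m[2]
  F_m[2, 2] <- -k[9] * c[2]; F_m[2, 5] <- k[10]
  F_c[3, 3] <- -(k[13] + k[11] * m[5])
  F_m[3, 7] <- k[14]; F_m[3, 6] <- k[12]; F_m[3, 5] <- -k[11] * c[3]

  G_m[1, 1] <- -act - k[4]; G_m[1, 2] <- k[2] * c[1]; G_m[1, 3] <- k[8]
  G_m[1, 6] <- -k[6] * m[1]; G_m[1, 7] <- -k[5] * m[1]
  G_c[1, 1] <- k[1] + k[2] * m[2]
  G_m[2, 1] <- act; G_m[2, 2] <- -k[7] * m[4]; G_m[2, 4] <- -k[7] * m[2]
  G_m[2, 6] <- k[6] * m[1] + k[3] * c[1]; G_m[2, 7] <- k[5] * m[1]
  G_c[2, 1] <- k[3] * m[6]
  G_m[3, 2] <- k[7] * m[4]; G_m[3, 4] <- k[7] * m[2]; G_m[3, 3] <- -k[8]
  G_m[4, ] <- -G_m[3, ]
  G_m[5, 2] <- k[9] * c[2]; G_m[5, 5] <- -k[10] - k[11] * c[3]
  G_m[5, 6] <- k[12]
  G_c[5, 2] <- k[9] * m[2]; G_c[5, 3] <- -k[11] * m[5]
  G_m[6, 5] <- k[11] * c[3]; G_m[6, 6] <- -k[12]
  G_c[6, 3] <- k[11] * m[5]
  G_m[7, 7] <- -k[14]; G_c[7, 3] <- k[13]
  list(G_m = G_m, G_c = G_c, F_m = F_m, F_c = F_c)
}

# largest |individual mass-action term|, positional variant
term_scale_fast <- function(m, c, k) {
  max(abs(c(k[1] * c[1], k[2] * m[2] * c[1], k[3] * m[6] * c[1], k[4] * m[1],
            k[5] * m[7] * m[1], k[6] * m[6] * m[1], k[7] * m[2] * m[4],
            k[8] * m[3], k[9] * m[2] * c[2], k[10] * m[5],
            k[11] * m[5] * c[3], k[12] * m[6], k[13] * c[3],
            k[14] * m[7])))
}

# small linear-congruential generator (Numerical-Recipes constants) for
# deterministic solver-internal jitter that leaves .Random.seed untouched
lcg_unif <- function(n, seed) {
  x <- (as.numeric(seed) + 12345) %% 2^32
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (1664525 * x + 1013904223) %% 2^32
    out[i] <- x / 2^32
  }
  out
}

# expand active-state vector into full (m, c)
split_state <- function(x, sys) {
  if (!sys$reduced && length(sys$c_active) == 3L)
    return(list(m = x[1:7], c = x[8:10]))
  nm <- length(sys$m_active)
  m <- numeric(7); c <- numeric(3)
  m[sys$m_active] <- x[seq_len(nm)]
  c[sys$c_active] <- x[nm + seq_along(sys$c_active)]
  list(m = m, c = c)
}
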
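# Independent oracles and generators used across the test suite.

# Stoichiometry-matrix oracle for the reaction terms: the 13 elementary
# reactions coded as stoichiometric columns over the species
# (c_D, c_B, c_F | m_d, m_t, m_tg, m_g, m_b, m_bf, m_f), with mass-action
# propensities. f is the bulk-species change (per membrane area), g the
# membrane-species change. Written independently of the closed-form
# implementation in the package.
stoich_oracle <- function(point, params) {
  k <- params$rates
  cc <- point$c; m <- point$m
  species <- c("c_D", "c_B", "c_F",
               "m_d", "m_t", "m_tg", "m_g", "m_b", "m_bf", "m_f")
  Smat <- matrix(0, 10, 13, dimnames = list(species, paste0("R", 1:13)))
  w <- numeric(13)
  put <- function(r, minus, plus) {
    for (s in minus) Smat[s, r] <<- Smat[s, r] - 1
    for (s in plus) Smat[s, r] <<- Smat[s, r] + 1
  }
  put(1, "c_D", "m_d");  w[1] <- k[["k_D"]] * cc[["c_D"]]
  put(2, "c_D", "m_d");  w[2] <- k[["k_tD"]] * m[["m_t"]] * cc[["c_D"]]
  put(3, "c_D", "m_t");  w[3] <- k[["k_bfD"]] * m[["m_bf"]] * cc[["c_D"]]
  put(4, "m_d", "c_D");  w[4] <- k[["k_d"]] * m[["m_d"]]
  put(5, "m_d", "m_t")
  w[5] <- (k[["k_fd"]] * m[["m_f"]] + k[["k_bfd"]] * m[["m_bf"]]) * m[["m_d"]]
  put(6, c("m_t", "m_g"), "m_tg"); w[6] <- k[["k_tg"]] * m[["m_t"]] * m[["m_g"]]
  put(7, "m_tg", c("m_d", "m_g")); w[7] <- k[["k_gt"]] * m[["m_tg"]]
  put(8, "c_B", "m_b");  w[8] <- k[["k_tB"]] * m[["m_t"]] * cc[["c_B"]]
  put(9, "m_b", "c_B");  w[9] <- k[["k_b"]] * m[["m_b"]]
  put(10, c("m_b", "c_F"), "m_bf"); w[10] <- k[["k_bF"]] * m[["m_b"]] * cc[["c_F"]]
  put(11, "m_bf", c("m_b", "c_F")); w[11] <- k[["k_bf"]] * m[["m_bf"]]
  put(12, "c_F", "m_f"); w[12] <- k[["k_F"]] * cc[["c_F"]]
  put(13, "m_f", "c_F"); w[13] <- k[["k_f"]] * m[["m_f"]]
  change <- as.numeric(Smat %*% w)
  names(change) <- species
  list(f = change[1:3], g = change[4:10])
}

# central finite differences of f and g with respect to all concentrations
fd_jacobians <- function(point, params, eps = 1e-6) {
  n_m <- 7L; n_c <- 3L
  G_m <- matrix(0, n_m, n_m); G_c <- matrix(0, n_m, n_c)
  F_m <- matrix(0, n_c, n_m); F_c <- matrix(0, n_c, n_c)
  for (j in seq_len(n_m)) {
    h <- eps * max(1, abs(point$m[j]))
    mp <- point$m; mm <- point$m
    mp[j] <- mp[j] + h; mm[j] <- max(mm[j] - h, 0)
    dh <- mp[j] - mm[j]
    pp <- concentration_point(point$c, mp)
    pm <- concentration_point(point$c, mm)
    G_m[, j] <- (reaction_rate_g(pp, params) - reaction_rate_g(pm, params)) / dh
    F_m[, j] <- (reaction_flux_f(pp, params) - reaction_flux_f(pm, params)) / dh
  }
  for (j in seq_len(n_c)) {
    h <- eps * max(1, abs(point$c[j]))
    cp <- point$c; cm <- point$c
    cp[j] <- cp[j] + h; cm[j] <- max(cm[j] - h, 0)
    dh <- cp[j] - cm[j]
    pp <- concentration_point(cp, point$m)
    pm <- concentration_point(cm, point$m)
    G_c[, j] <- (reaction_rate_g(pp, params) - reaction_rate_g(pm, params)) / dh
    F_c[, j] <- (reaction_flux_f(pp, params) - reaction_flux_f(pm, params)) / dh
  }
  list(G_m = G_m, G_c = G_c, F_m = F_m, F_c = F_c)
}

random_params <- function(D_c = 10, D_m = 0.01) {
  rates <- stats::setNames(10^stats::runif(14, -2, 1.5), cdc42rd:::RATE_NAMES)
  do.call(parameter_set, c(as.list(rates), list(D_c = D_c, D_m = D_m)))
}

random_point <- function(scale = 10) {
  concentration_point(stats::runif(3, 0, scale), stats::runif(7, 0, scale))
}

# a fixed, hand-picked parameter set with appreciable activity on every
# pathway; used where tests need a deterministic non-degenerate configuration
fixture_params <- function() {
  parameter_set(k_D = 0.05, k_tD = 0.05, k_bfD = 0.5, k_d = 1, k_fd = 0.05,
                k_bfd = 0.5, k_tg = 0.1, k_gt = 0.5, k_tB = 0.2, k_b = 1,
                k_bF = 0.3, k_bf = 0.5, k_F = 0.05, k_f = 1,
                D_c = 10, D_m = 0.01)
}

fixture_anchors <- function() {
  copy_numbers(N_Cdc42 = 5000, N_GAPs = 2000, N_Bem1 = 2000, N_GEF = 1000)
}
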
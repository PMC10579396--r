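# Axisymmetric nonlinear simulator --------------------------------------------
#
# Discretizes the bulk-surface reaction-diffusion system on an axisymmetric
# (r, theta) finite-volume grid: cytosolic species diffuse in the ball,
# membrane species diffuse on the bounding sphere, and the two are coupled in
# flux form through the attachment-detachment fluxes f, so every exchange
# event moves mass exactly between a boundary bulk cell and its membrane cell.

#' Conservative finite-volume grid for the axisymmetric ball
#'
#' Radial edges are uniform in r over (0, R], polar edges uniform in theta
#' over [0, pi]. Cell volumes and face areas use the exact spherical metric
#' (r^2 sin(theta) weights via cos(theta) differences), so the cells tile the
#' ball exactly and the membrane cells tile the sphere exactly. Zero-flux
#' regularity holds at r = 0 and on the symmetry axis by construction (no
#' faces there).
#'
#' @param geom A [geometry()].
#' @param n_r,n_theta Number of radial and polar cells (each >= 4).
#' @return An object of class `"cdc42_grid"` with cell centres, volumes,
#'   areas, and sparse Laplacian operators `L_bulk` (unit-diffusivity bulk
#'   operator, cells indexed radially fastest) and `L_mem` (unit-diffusivity
#'   membrane operator over theta).
#' @export
build_grid <- function(geom, n_r = 32L, n_theta = 64L) {
  stopifnot(inherits(geom, "cdc42_geometry"), n_r >= 4L, n_theta >= 4L)
  R <- geom$R
  r_e <- R * seq(0, 1, length.out = n_r + 1L)
  th_e <- pi * seq(0, 1, length.out = n_theta + 1L)
  mu_e <- cos(th_e)                    # decreasing from 1 to -1
  d_mu <- mu_e[-length(mu_e)] - mu_e[-1L]        # > 0, sums to 2
  r_c <- (r_e[-1L] + r_e[-(n_r + 1L)]) / 2
  th_c <- (th_e[-1L] + th_e[-(n_theta + 1L)]) / 2
  dr <- R / n_r
  dth <- pi / n_theta

  vol_r <- 2 * pi * diff(r_e^3) / 3              # per radial shell, unit d_mu
  V_cells <- outer(vol_r, d_mu)                  # n_r x n_theta
  A_mem <- 2 * pi * R^2 * d_mu                   # n_theta, sums to S

  idx <- function(i, j) (j - 1L) * n_r + i
  n_cells <- n_r * n_theta
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v)
  }
  # radial faces between (i, j) and (i+1, j)
  for (j in seq_len(n_theta)) {
    for (i in seq_len(n_r - 1L)) {
      Af <- 2 * pi * r_e[i + 1L]^2 * d_mu[j]     # face area
      w <- Af / dr                               # flux = w * (c2 - c1)
      a <- idx(i, j); b <- idx(i + 1L, j)
      add(a, b, w / V_cells[i, j]); add(a, a, -w / V_cells[i, j])
      add(b, a, w / V_cells[i + 1L, j]); add(b, b, -w / V_cells[i + 1L, j])
    }
  }
  # angular faces between (i, j) and (i, j+1); arc length r_c * dth
  for (j in seq_len(n_theta - 1L)) {
    sf <- sin(th_e[j + 1L])
    for (i in seq_len(n_r)) {
      Af <- pi * (r_e[i + 1L]^2 - r_e[i]^2) * sf
      w <- Af / (r_c[i] * dth)
      a <- idx(i, j); b <- idx(i, j + 1L)
      add(a, b, w / V_cells[i, j]); add(a, a, -w / V_cells[i, j])
      add(b, a, w / V_cells[i, j + 1L]); add(b, b, -w / V_cells[i, j + 1L])
    }
  }
  L_bulk <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(n_cells, n_cells))

  # membrane operator over theta
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n_theta - 1L)) {
    Lf <- 2 * pi * R * sin(th_e[j + 1L])         # face length
    w <- Lf / (R * dth)
    add(j, j + 1L, w / A_mem[j]); add(j, j, -w / A_mem[j])
    add(j + 1L, j, w / A_mem[j + 1L]); add(j + 1L, j + 1L, -w / A_mem[j + 1L])
  }
  L_mem <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(n_theta, n_theta))

  structure(list(n_r = n_r, n_theta = n_theta, r_edges = r_e,
                 theta_edges = th_e, r_centers = r_c, theta_centers = th_c,
                 mu_edges = mu_e, d_mu = d_mu, V_cells = V_cells,
                 A_mem = A_mem, L_bulk = L_bulk, L_mem = L_mem,
                 boundary_idx = idx(n_r, seq_len(n_theta)),
                 V_boundary = V_cells[n_r, ], geom = geom),
            class = "cdc42_grid")
}

# cell averages of the Legendre polynomial P_l over the mu extent of each
# theta cell: integral P_l dmu = (P_{l+1} - P_{l-1}) / (2l+1), so cell sums
# telescope exactly (a mode perturbation changes no copy number)
legendre_cell_average <- function(grid, l) {
  if (l == 0L) return(rep(1, grid$n_theta))
  mu <- grid$mu_edges
  Pm <- legendre_eval(mu, l - 1L)
  Pp <- legendre_eval(mu, l + 1L)
  anti <- (Pp - Pm) / (2 * l + 1)
  (anti[-length(anti)] - anti[-1L]) / grid$d_mu
}

legendre_eval <- function(x, l) {
  if (l == 0L) return(rep(1, length(x)))
  if (l == 1L) return(x)
  Pkm1 <- rep(1, length(x)); Pk <- x
  for (k in seq_len(l - 1L)) {
    Pkp1 <- ((2 * k + 1) * x * Pk - k * Pkm1) / (k + 1)
    Pkm1 <- Pk; Pk <- Pkp1
  }
  Pk
}

#' Initial condition for a simulation
#'
#' Builds a [build_grid()]-discretized state from a homogeneous base state,
#' optionally perturbed:
#' \describe{
#'   \item{`"none"`}{the exact (discretized) homogeneous state.}
#'   \item{`"mode_perturbation"`}{adds `amplitude * P_l(cos theta)` (cell
#'     averages of the Legendre polynomial, so copy numbers are exactly
#'     unchanged) to the chosen membrane species; default species `m_t`,
#'     default amplitude 1% of the base `m_t`.}
#'   \item{`"local_stimulus"`}{adds a Gaussian bump in theta (centre `theta0`,
#'     s.d. `width`, height `amplitude`) to the chosen membrane species
#'     (default `m_f`), then rescales that protein's fields so its copy
#'     number is exactly unchanged.}
#' }
#'
#' @param base A converged [solve_homogeneous()] state.
#' @param grid A [build_grid()].
#' @param kind One of `"none"`, `"mode_perturbation"`, `"local_stimulus"`.
#' @param l,amplitude Mode index and absolute amplitude (um^-2) for
#'   `mode_perturbation`; `amplitude = NULL` uses 1% of the base value.
#' @param species Membrane species name perturbed.
#' @param theta0,width Centre and width (radians) of the local stimulus.
#' @return An object of class `"cdc42_sim_state"`: membrane fields `M`
#'   (n_theta x 7), bulk fields `C` (n_cells x 3), time `t`, and the
#'   conserved-total audit of the initial state.
#' @export
initial_condition <- function(base, grid, kind = c("none", "mode_perturbation",
                                                   "local_stimulus"),
                              l = 1L, amplitude = NULL, species = NULL,
                              theta0 = 0, width = 0.3) {
  kind <- match.arg(kind)
  stopifnot(inherits(base, "cdc42_steady"), inherits(grid, "cdc42_grid"))
  if (!base$converged)
    stop("initial_condition: base state did not converge", call. = FALSE)
  n_th <- grid$n_theta
  M <- matrix(rep(unname(base$point$m), each = n_th), n_th, 7)
  C <- matrix(rep(unname(base$point$c), each = nrow(grid$L_bulk)),
              nrow(grid$L_bulk), 3)
  colnames(M) <- MEM_SPECIES; colnames(C) <- CYT_SPECIES

  if (kind == "mode_perturbation") {
    if (is.null(species)) species <- "m_t"
    s <- match(species, MEM_SPECIES)
    if (is.null(amplitude)) amplitude <- 0.01 * base$point$m[[species]]
    M[, s] <- M[, s] + amplitude * legendre_cell_average(grid, l)
    if (any(M[, s] < 0))
      stop("initial_condition: perturbation drives ", species, " negative",
           call. = FALSE)
  } else if (kind == "local_stimulus") {
    if (is.null(species)) species <- "m_f"
    s <- match(species, MEM_SPECIES)
    if (is.null(amplitude))
      stop("initial_condition: local_stimulus needs an amplitude",
           call. = FALSE)
    bump <- amplitude * exp(-(grid$theta_centers - theta0)^2 / (2 * width^2))
    M[, s] <- M[, s] + bump
    # rescale the perturbed protein's fields to restore its copy number
    pool <- names(Filter(function(p) species %in% p$m, PROTEIN_POOLS))[1]
    target <- copy_numbers_fast(unname(base$point$m), unname(base$point$c),
                                grid$geom)[[pool]]
    ach <- sim_audit_protein(M, C, grid, pool)
    if (ach > 0) {
      fac <- target / ach
      mcols <- match(PROTEIN_POOLS[[pool]]$m, MEM_SPECIES)
      ccols <- match(PROTEIN_POOLS[[pool]]$c, CYT_SPECIES)
      M[, mcols] <- M[, mcols] * fac
      if (length(ccols)) C[, ccols] <- C[, ccols] * fac
    }
  }
  state <- structure(list(grid = grid, system = base$system, M = M, C = C,
                          t = 0, base = base),
                     class = "cdc42_sim_state")
  state$audit <- sim_audit(state)
  state
}

sim_audit_protein <- function(M, C, grid, pool) {
  p <- PROTEIN_POOLS[[pool]]
  mcols <- match(p$m, MEM_SPECIES)
  ccols <- match(p$c, CYT_SPECIES)
  tot <- sum(grid$A_mem * rowSums(M[, mcols, drop = FALSE]))
  if (length(ccols))
    tot <- tot + sum(as.numeric(grid$V_cells) *
                       rowSums(C[, ccols, drop = FALSE]))
  tot
}

#' Conserved-total audit of a simulation state
#'
#' @param state A `"cdc42_sim_state"`.
#' @return Named vector of the four protein totals (molecule counts).
#' @export
sim_audit <- function(state) {
  vapply(names(PROTEIN_POOLS), function(p)
    sim_audit_protein(state$M, state$C, state$grid, p), numeric(1))
}

# vectorized reaction terms over theta: M is n_theta x 7, Cb n_theta x 3
g_vec <- function(M, Cb, k) {
  act <- k[5] * M[, 7] + k[6] * M[, 6]
  gtg <- k[7] * M[, 2] * M[, 4] - k[8] * M[, 3]
  cbind((k[1] + k[2] * M[, 2]) * Cb[, 1] + k[8] * M[, 3] -
          act * M[, 1] - k[4] * M[, 1],
        act * M[, 1] + k[3] * M[, 6] * Cb[, 1] - k[7] * M[, 2] * M[, 4],
        gtg,
        -gtg,
        k[9] * M[, 2] * Cb[, 2] - k[10] * M[, 5] + k[12] * M[, 6] -
          k[11] * M[, 5] * Cb[, 3],
        k[11] * M[, 5] * Cb[, 3] - k[12] * M[, 6],
        k[13] * Cb[, 3] - k[14] * M[, 7])
}

f_vec <- function(M, Cb, k) {
  cbind(k[4] * M[, 1] - (k[1] + k[2] * M[, 2] + k[3] * M[, 6]) * Cb[, 1],
        k[10] * M[, 5] - k[9] * M[, 2] * Cb[, 2],
        k[14] * M[, 7] + k[12] * M[, 6] - (k[13] + k[11] * M[, 5]) * Cb[, 3])
}

#' Advance the bulk-surface dynamics
#'
#' Integrates the discretized system by the method of lines with the stiff
#' sparse-Jacobian solver `lsodes` (implicit BDF): bulk diffusion, membrane
#' diffusion, membrane reactions, and flux-form boundary exchange. Error is
#' controlled by relative tolerance `rtol`; nonnegativity is monitored and
#' integration aborts with a diagnostic dump if fields turn significantly
#' negative.
#'
#' @param state A [initial_condition()] state.
#' @param t_end End time in seconds.
#' @param n_save Number of saved snapshots (evenly spaced, including t_end).
#' @param rtol,atol Integration tolerances.
#' @return An object of class `"cdc42_trajectory"`: `times`, list of
#'   `states`, a data frame `metrics` ([polarity_metrics()] per snapshot),
#'   and `audit` (matrix of conserved totals per snapshot).
#' @export
run_simulation <- function(state, t_end, n_save = 25L, rtol = 1e-8,
                           atol = 1e-10) {
  stopifnot(inherits(state, "cdc42_sim_state"), t_end > 0)
  grid <- state$grid
  sys <- state$system
  k <- unname(sys$params$rates)
  D_c <- sys$params$D_c
  D_m <- unname(sys$params$D_m)
  n_th <- grid$n_theta
  n_cells <- nrow(grid$L_bulk)
  bidx <- grid$boundary_idx
  Vb <- grid$V_boundary
  scale0 <- max(abs(c(state$M, state$C)), 1)

  pack <- function(M, C) c(as.numeric(C), as.numeric(M))
  unpack <- function(y) {
    C <- matrix(y[seq_len(3 * n_cells)], n_cells, 3)
    M <- matrix(y[3 * n_cells + seq_len(7 * n_th)], n_th, 7)
    list(M = M, C = C)
  }

  rhs <- function(t, y, p) {
    s <- unpack(y)
    Cb <- s$C[bidx, , drop = FALSE]
    f <- f_vec(s$M, Cb, k)
    g <- g_vec(s$M, Cb, k)
    dC <- D_c * as.matrix(grid$L_bulk %*% s$C)
    # flux-form exchange: boundary bulk cells gain f * A / V
    dC[bidx, ] <- dC[bidx, ] + f * (grid$A_mem / Vb)
    dM <- as.matrix(grid$L_mem %*% s$M) %*% diag(D_m) + g
    list(pack(dM, dC))
  }

  times <- seq(0, t_end, length.out = n_save + 1L)
  y0 <- pack(state$M, state$C)
  sol <- deSolve::lsodes(y = y0, times = times, func = rhs, parms = NULL,
                         rtol = rtol, atol = atol * scale0,
                         maxsteps = 100000)
  if (nrow(sol) < length(times))
    warning("run_simulation: integrator stopped early at t = ",
            max(sol[, 1]))
  states <- vector("list", nrow(sol))
  audits <- matrix(NA_real_, nrow(sol), 4,
                   dimnames = list(NULL, names(PROTEIN_POOLS)))
  metrics <- vector("list", nrow(sol))
  for (i in seq_len(nrow(sol))) {
    s <- unpack(as.numeric(sol[i, -1]))
    neg <- min(s$M, s$C)
    if (neg < -1e-6 * scale0)
      stop(sprintf("run_simulation: significant negativity (%.3g) at t = %.3g",
                   neg, sol[i, 1]), call. = FALSE)
    st <- structure(list(grid = grid, system = sys, M = s$M, C = s$C,
                         t = sol[i, 1], base = state$base),
                    class = "cdc42_sim_state")
    states[[i]] <- st
    audits[i, ] <- sim_audit(st)
    metrics[[i]] <- as.data.frame(polarity_metrics(st))
  }
  metrics <- cbind(t = sol[, 1], do.call(rbind, metrics))
  structure(list(times = sol[, 1], states = states, metrics = metrics,
                 audit = audits),
            class = "cdc42_trajectory")
}

#' Polarity metrics of a simulation state
#'
#' Characterizes the membrane Cdc42-GTP pattern: Legendre mode amplitudes of
#' `m_t` (area-weighted projections, `a_l = (2l+1)/2 integral m_t P_l dmu`),
#' the polarity ratio `max(m_t)/min(m_t)`, the fraction of total membrane
#' Cdc42 within 60 degrees of the `m_t` maximum (polar-cap fraction), and the
#' uniformity index of the total Cdc42 membrane density
#' (area-weighted coefficient of variation of `m_d + m_t + m_tg`; zero for a
#' perfectly uniform total density).
#'
#' @param state A `"cdc42_sim_state"`.
#' @param l_max Number of Legendre amplitudes computed.
#' @return List with `a1`, `a2` (Legendre amplitudes of `m_t`), `ratio`,
#'   `cap_fraction`, `uniformity`.
#' @export
polarity_metrics <- function(state, l_max = 4L) {
  grid <- state$grid
  mt <- state$M[, 2]
  w <- grid$d_mu / 2                      # integration weights over mu
  amps <- vapply(seq_len(l_max), function(l) {
    (2 * l + 1) * sum(mt * legendre_cell_average(grid, l) * w)
  }, numeric(1))
  total <- state$M[, 1] + state$M[, 2] + state$M[, 3]
  mean_tot <- sum(total * w)
  uniformity <- if (mean_tot > 0)
    sqrt(sum((total - mean_tot)^2 * w)) / mean_tot else 0
  j_peak <- which.max(mt)
  cap <- abs(grid$theta_centers - grid$theta_centers[j_peak]) <= pi / 3
  cap_fraction <- if (sum(total * grid$A_mem) > 0)
    sum(total[cap] * grid$A_mem[cap]) / sum(total * grid$A_mem) else 0
  ratio <- if (min(mt) > 0) max(mt) / min(mt) else Inf
  list(a1 = amps[1], a2 = if (l_max >= 2) amps[2] else NA_real_,
       ratio = ratio, cap_fraction = cap_fraction, uniformity = uniformity)
}

#' Early-time mode growth rate from a trajectory
#'
#' Fits `log |a_l(t)|` linearly over the window where the amplitude has grown
#' by less than `window_factor` relative to its initial value (and is above
#' the numerical floor), returning the slope as the measured growth rate.
#'
#' @param traj A [run_simulation()] trajectory started from a
#'   `mode_perturbation` initial condition.
#' @param l Mode index (1 or 2).
#' @param window_factor Amplitude growth factor delimiting the linear window.
#' @return List with `sigma` (fitted rate, 1/s), `n_points`, and the fit
#'   window.
#' @export
measure_growth_rate <- function(traj, l = 1L, window_factor = 10) {
  a <- vapply(traj$states, function(s) {
    grid <- s$grid
    w <- grid$d_mu / 2
    (2 * l + 1) * sum(s$M[, 2] * legendre_cell_average(grid, l) * w)
  }, numeric(1))
  a0 <- abs(a[1])
  if (a0 == 0) stop("measure_growth_rate: zero initial amplitude")
  ok <- abs(a) > 1e-12 & abs(a) <= window_factor * a0
  # use the largest contiguous window from t = 0
  stop_at <- which(!ok)[1]
  if (!is.na(stop_at)) ok[stop_at:length(ok)] <- FALSE
  if (sum(ok) < 3) stop("measure_growth_rate: window too short; lower t_end")
  fit <- stats::lm(log(abs(a[ok])) ~ traj$times[ok])
  list(sigma = unname(stats::coef(fit)[2]), n_points = sum(ok),
       t_window = range(traj$times[ok]))
}
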
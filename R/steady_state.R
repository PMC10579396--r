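# Homogeneous steady states ----------------------------------------------------

# Largest magnitude among the individual mass-action terms at a point; used to
# nondimensionalize residual tolerances.
reaction_term_scale <- function(point, params) {
  term_scale_fast(unname(point$m), unname(point$c), unname(params$rates))
}

#' Jacobian of the well-mixed compartment reduction
#'
#' The laterally uniform dynamics reduce to a compartment ODE coupling the
#' membrane concentrations to the bulk concentrations through the surface-to-
#' volume ratio: `dm/dt = g(m, c)`, `dc/dt = (S/V) f(m, c)` (f > 0 is net
#' membrane-to-bulk flux, so the bulk gains mass at rate `(S/V) f`). The
#' Jacobian of this reduction governs the stability of the homogeneous steady
#' state against spatially uniform (l = 0) perturbations; protein-number
#' conservation contributes one exactly neutral direction per conserved pool.
#'
#' @param point A [concentration_point()].
#' @param sys A [apply_scenario()] system.
#' @param geom A [geometry()].
#' @return Square matrix over the active species (membrane block first).
#' @export
wellmixed_jacobian <- function(point, sys, geom) {
  J <- jac_fast(unname(point$m), unname(point$c), unname(sys$params$rates))
  ma <- sys$m_active; ca <- sys$c_active
  rbind(cbind(J$G_m[ma, ma, drop = FALSE], J$G_c[ma, ca, drop = FALSE]),
        cbind((geom$S / geom$V) * J$F_m[ca, ma, drop = FALSE],
              (geom$S / geom$V) * J$F_c[ca, ca, drop = FALSE]))
}

wellmixed_rhs_raw <- function(x, sys, geom, k = unname(sys$params$rates)) {
  st <- split_state(x, sys)
  g <- g_fast(st$m, st$c, k)
  f <- f_fast(st$m, st$c, k)
  c(g[sys$m_active], (geom$S / geom$V) * f[sys$c_active])
}

# Mass-consistent initial guess: each protein split between its basal membrane
# species and (if present) its cytosolic pool.
initial_guess <- function(sys, geom, bulk_fraction = 0.5) {
  tg <- unclass(sys$targets)
  m <- numeric(7); cc <- numeric(3)
  bf_cdc42 <- if (sys$cdc42_on_membrane) 0 else bulk_fraction
  # Cdc42: bulk share in c_D, membrane share in the basal species m_d (the
  # relaxation populates m_t; seeding inert species would freeze mass there
  # in degenerate rate configurations)
  cc[1] <- bf_cdc42 * tg[["N_Cdc42"]] / geom$V
  m[1] <- (1 - bf_cdc42) * tg[["N_Cdc42"]] / geom$S
  # GAPs: all free on the membrane
  m[4] <- tg[["N_GAPs"]] / geom$S
  # Bem1
  if (2 %in% sys$c_active) {
    cc[2] <- bulk_fraction * tg[["N_Bem1"]] / geom$V
    m[5] <- (1 - bulk_fraction) * tg[["N_Bem1"]] / geom$S
  }
  # GEF
  cc[3] <- bulk_fraction * tg[["N_GEF"]] / geom$V
  m[7] <- (1 - bulk_fraction) * tg[["N_GEF"]] / geom$S
  c(m[sys$m_active], cc[sys$c_active])
}

# Copy numbers from plain (m, c) vectors
copy_numbers_fast <- function(m, c, geom) {
  c(N_Cdc42 = geom$V * c[1] + geom$S * (m[1] + m[2] + m[3]),
    N_GAPs = geom$S * (m[4] + m[3]),
    N_Bem1 = geom$V * c[2] + geom$S * (m[5] + m[6]),
    N_GEF = geom$V * c[3] + geom$S * (m[7] + m[6]))
}

# The reaction equations are exactly rank-deficient along the conservation
# directions; for each conserved pool one redundant equation row is replaced
# by the copy-number constraint (divided by S so all rows carry comparable
# units). The replaced rows:
#   N_Cdc42 -> f_D row (or g_d if the cytosolic pool is structurally removed)
#   N_GAPs  -> g_g row
#   N_Bem1  -> f_B row
#   N_GEF   -> f_F row
conservation_row <- function(pool, sys) {
  nm <- length(sys$m_active)
  switch(pool,
    N_Cdc42 = if (1L %in% sys$c_active) nm + match(1L, sys$c_active)
              else match(1L, sys$m_active),
    N_GAPs = match(4L, sys$m_active),
    N_Bem1 = nm + match(2L, sys$c_active),
    N_GEF = nm + match(3L, sys$c_active))
}

newton_residual <- function(x, sys, geom, k, tg, pools) {
  st <- split_state(x, sys)
  g <- g_fast(st$m, st$c, k)
  f <- f_fast(st$m, st$c, k)
  res <- c(g[sys$m_active], f[sys$c_active])
  ach <- copy_numbers_fast(st$m, st$c, geom)
  for (pool in pools)
    res[conservation_row(pool, sys)] <- (ach[[pool]] - tg[[pool]]) / geom$S
  res
}

newton_jacobian <- function(x, sys, geom, k, pools) {
  st <- split_state(x, sys)
  J <- jac_fast(st$m, st$c, k)
  ma <- sys$m_active; ca <- sys$c_active
  A <- rbind(cbind(J$G_m[ma, ma, drop = FALSE], J$G_c[ma, ca, drop = FALSE]),
             cbind(J$F_m[ca, ma, drop = FALSE], J$F_c[ca, ca, drop = FALSE]))
  nm <- length(ma)
  pool_members_m <- list(N_Cdc42 = c(1L, 2L, 3L), N_GAPs = c(3L, 4L),
                         N_Bem1 = c(5L, 6L), N_GEF = c(6L, 7L))
  pool_members_c <- list(N_Cdc42 = 1L, N_GAPs = integer(0), N_Bem1 = 2L,
                         N_GEF = 3L)
  for (pool in pools) {
    row <- numeric(ncol(A))
    pm <- match(pool_members_m[[pool]], ma); pm <- pm[!is.na(pm)]
    row[pm] <- 1
    pc <- match(pool_members_c[[pool]], ca); pc <- pc[!is.na(pc)]
    if (length(pc)) row[nm + pc] <- geom$V / geom$S
    A[conservation_row(pool, sys), ] <- row
  }
  A
}

newton_solve <- function(x0, sys, geom, max_iter = 40L) {
  k <- unname(sys$params$rates)
  tg <- unclass(sys$targets)
  pools <- active_pools(sys)
  x <- x0
  res <- newton_residual(x, sys, geom, k, tg, pools)
  nrm <- max(abs(res))
  st0 <- split_state(x, sys)
  tol_stop <- 1e-15 * max(1, term_scale_fast(st0$m, st0$c, k))
  negative_projections <- 0L
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (nrm < tol_stop) break
    A <- newton_jacobian(x, sys, geom, k, pools)
    step <- tryCatch(solve(A, -res), error = function(e) NULL)
    if (is.null(step)) {
      # degenerate configurations (inert species under zero rates) leave the
      # replaced system rank-deficient; take the minimum-norm step, which
      # does not move the inert directions
      sv <- svd(A)
      keep <- sv$d > max(sv$d) * 1e-12
      if (!any(keep)) return(list(x = x, norm = nrm, ok = FALSE,
                                  iter = iter, neg = negative_projections))
      step <- as.numeric(sv$v[, keep, drop = FALSE] %*%
        ((t(sv$u[, keep, drop = FALSE]) %*% -res) / sv$d[keep]))
    }
    lambda <- 1
    improved <- FALSE
    for (ls in 1:25) {
      x_new <- x + lambda * step
      if (any(x_new < 0)) {
        bad <- x_new < 0
        if (all(x_new[bad] > -1e-10 * max(1, max(abs(x_new))))) {
          x_new[bad] <- 0
          negative_projections <- negative_projections + sum(bad)
        } else {
          lambda <- lambda / 2
          next
        }
      }
      res_new <- newton_residual(x_new, sys, geom, k, tg, pools)
      nrm_new <- max(abs(res_new))
      if (is.finite(nrm_new) && (nrm_new < nrm || nrm_new < tol_stop)) {
        x <- x_new; res <- res_new; nrm <- nrm_new; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(x = x, norm = nrm, ok = TRUE, iter = iter, neg = negative_projections)
}

# Pseudo-transient continuation: damped implicit-Euler steps of the well-mixed
# relaxation ODE with adaptive pseudo-time step. Unconditionally stable for
# the stiff kinetics and cheap near the fixed point; accuracy along the path
# is irrelevant because the Newton polish runs interleaved.
ptc_relax <- function(x0, sys, geom, try_newton = NULL, max_steps = 400L) {
  k <- unname(sys$params$rates)
  x <- pmax(x0, 0)
  scale0 <- max(abs(x), 1)
  r <- wellmixed_rhs_raw(x, sys, geom, k)
  dt <- 0.1 * scale0 / max(max(abs(r)), 1e-12)
  n <- length(x)
  accepted <- 0L
  for (step in seq_len(max_steps)) {
    if (max(abs(r)) < 1e-9 * scale0) break
    st <- split_state(x, sys)
    J <- wellmixed_jacobian(list(m = st$m, c = st$c), sys, geom)
    A <- diag(1 / dt, n) - J
    dx <- tryCatch(solve(A, r), error = function(e) NULL)
    if (is.null(dx)) { dt <- dt / 4; next }
    x_new <- x + dx
    if (any(x_new < -1e-8 * scale0)) { dt <- dt / 4; next }
    x_new <- pmax(x_new, 0)
    r_new <- wellmixed_rhs_raw(x_new, sys, geom, k)
    if (!all(is.finite(r_new)) || max(abs(r_new)) > 2 * max(abs(r)) + 1e-12) {
      dt <- dt / 4
      next
    }
    x <- x_new; r <- r_new
    dt <- dt * 2
    accepted <- accepted + 1L
    if (!is.null(try_newton) && accepted %% 8L == 0L) {
      hit <- try_newton(x)
      if (!is.null(hit)) return(list(x = hit, t_end = NA_real_, polished = TRUE))
    }
  }
  list(x = x, t_end = NA_real_, polished = FALSE)
}

relax_ode <- function(x0, sys, geom, t_max = 1e5, rtol = 1e-7, atol = 1e-10,
                      try_newton = NULL) {
  k <- unname(sys$params$rates)
  rhs <- function(t, y, p) list(wellmixed_rhs_raw(y, sys, geom, k))
  jac <- function(t, y, p) {
    st <- split_state(y, sys)
    wellmixed_jacobian(list(m = st$m, c = st$c), sys, geom)
  }
  x <- pmax(x0, 0)
  t_end <- 0
  horizon <- 10
  scale0 <- max(abs(x), 1)
  while (t_end < t_max) {
    sol <- tryCatch(
      suppressWarnings(
        deSolve::lsoda(y = x, times = c(0, horizon), func = rhs, parms = NULL,
                       jacfunc = jac, jactype = "fullusr",
                       rtol = rtol, atol = atol * scale0, maxsteps = 20000)),
      error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < 2 || any(!is.finite(sol[2, -1]))) break
    x_new <- pmax(as.numeric(sol[2, -1]), 0)
    rhs_norm <- max(abs(wellmixed_rhs_raw(x_new, sys, geom, k)))
    moved <- max(abs(x_new - x)) / scale0
    x <- x_new
    t_end <- t_end + horizon
    # polishing along the way: accept as soon as Newton lands on a
    # copy-number-consistent root of the relaxation basin
    if (!is.null(try_newton)) {
      hit <- try_newton(x)
      if (!is.null(hit)) return(list(x = hit, t_end = t_end, polished = TRUE))
    }
    if (rhs_norm < 1e-8 * scale0 || moved < 1e-10) break
    horizon <- horizon * 10
  }
  list(x = x, t_end = t_end, polished = FALSE)
}

#' Solve for the laterally homogeneous steady state
#'
#' Finds concentrations at which all membrane reactions and all bulk-membrane
#' fluxes vanish (`g = 0`, `f = 0` componentwise) while realizing the requested
#' protein copy numbers. At such a state the bulk is exactly uniform, since the
#' boundary flux is the only source term of the bulk diffusion problem.
#'
#' The solver relaxes the well-mixed compartment ODE (`dm/dt = g`,
#' `dc/dt = (S/V) f`) from a mass-consistent initial guess until it is nearly
#' stationary, then applies a damped Newton iteration in which, for every
#' conserved protein, one redundant reaction equation is replaced by the
#' copy-number constraint (the reaction system is exactly rank-deficient along
#' those directions). If multiple steady-state branches exist the branch
#' continued from the relaxation endpoint is reported.
#'
#' @param params A [parameter_set()] or a [apply_scenario()] system (in which
#'   case `targets` must be `NULL`).
#' @param targets A [copy_numbers()] object (ignored when `params` is a
#'   system).
#' @param geom A [geometry()].
#' @param tol Absolute residual tolerance after nondimensionalizing by the
#'   largest individual reaction term (default 1e-12).
#' @param seed Integer seed controlling the jittered restarts used if the
#'   deterministic path fails; the default path is fully deterministic.
#' @param x0 Optional warm-start active-state vector (overrides the built-in
#'   initial guess; used for continuation along parameter scans).
#' @param relax_first If `TRUE` (default) run the ODE relaxation before the
#'   Newton polish; `FALSE` attempts Newton directly from the guess.
#' @param strict If `TRUE`, relax to stationarity with the conservative stiff
#'   integrator before polishing, without interleaved Newton attempts. Slower
#'   but guaranteed to report the attractor of the well-mixed relaxation
#'   dynamics rather than a nearby root; used as a fallback when a fast
#'   solve lands on a uniformly unstable root.
#' @return An object of class `"cdc42_steady"` with fields `point` (full
#'   10-species [concentration_point()]), `system`, `copy_numbers` (achieved),
#'   `residual_f`, `residual_g` (max-norms), `converged`, and `diagnostics`.
#' @export
solve_homogeneous <- function(params, targets = NULL, geom, tol = 1e-12,
                              seed = 1L, x0 = NULL, relax_first = TRUE,
                              strict = FALSE) {
  if (inherits(params, "cdc42_system")) {
    sys <- params
    if (!is.null(targets))
      stop("solve_homogeneous: give 'targets' either in the system or directly",
           call. = FALSE)
  } else {
    sys <- apply_scenario(params, targets, "WT")
  }
  stopifnot(inherits(geom, "cdc42_geometry"))
  tg <- unclass(sys$targets)
  k <- unname(sys$params$rates)

  if (all(tg == 0)) {
    point <- concentration_point()
    return(new_steady(point, sys, geom, converged = TRUE,
                      diagnostics = list(path = "trivial")))
  }

  guesses <- list()
  # a warm start (continuation) is polished directly; relaxing it would drag
  # the iterate to the warm start's conserved totals, not the requested ones
  if (!is.null(x0) && !strict)
    guesses <- c(guesses, list(list(x = unname(pmax(x0, 0)),
                                    method = "newton")))
  if (!relax_first && !strict)
    guesses <- c(guesses, list(list(x = initial_guess(sys, geom, 0.5),
                                    method = "newton")))
  for (bf in c(0.5, 0.9, 0.1))
    guesses <- c(guesses, list(list(x = initial_guess(sys, geom, bf),
                                    method = if (strict) "lsoda" else "ptc")))
  # jittered restarts with a conservative stiff integrator, used only if the
  # deterministic guesses fail; the jitter comes from a seed-derived LCG so
  # the solver never touches the caller's RNG stream
  n_state <- length(sys$m_active) + length(sys$c_active)
  jitter <- matrix(0.25 + 1.5 * lcg_unif(3 * n_state, seed), nrow = 3)
  for (j in 1:3)
    guesses <- c(guesses,
                 list(list(x = initial_guess(sys, geom, 0.5) * jitter[j, ],
                           method = "lsoda")))

  best <- NULL
  pools <- active_pools(sys)
  evaluate_root <- function(ns, gi, relax_time) {
    st <- split_state(pmax(ns$x, 0), sys)
    scale <- max(1, term_scale_fast(st$m, st$c, k))
    g <- g_fast(st$m, st$c, k)
    f <- f_fast(st$m, st$c, k)
    res_g <- max(abs(g[sys$m_active]))
    res_f <- if (length(sys$c_active)) max(abs(f[sys$c_active])) else 0
    ach <- copy_numbers_fast(st$m, st$c, geom)
    cn_ok <- all(abs(ach - tg)[pools] <= 1e-8 * pmax(1, tg[pools]))
    converged <- ns$ok && max(res_g, res_f) <= tol * scale && cn_ok
    list(m = st$m, c = st$c, res_g = res_g, res_f = res_f,
         converged = converged,
         diagnostics = list(guess = gi, newton_iter = ns$iter,
                            negative_projections = ns$neg,
                            relax_time = relax_time,
                            residual_norm = ns$norm))
  }
  for (gi in seq_along(guesses)) {
    x <- guesses[[gi]]$x
    relax_time <- NA_real_
    cand <- NULL
    method <- guesses[[gi]]$method
    if (method != "newton") {
      try_newton <- function(xr) {
        ns <- newton_solve(xr, sys, geom)
        cc <- evaluate_root(ns, gi, relax_time)
        if (cc$converged) {
          cand <<- cc
          pmax(ns$x, 0)
        } else NULL
      }
      if (strict) try_newton <- NULL
      relaxed <- if (method == "ptc")
        ptc_relax(x, sys, geom, try_newton = try_newton)
      else relax_ode(x, sys, geom, try_newton = try_newton,
                     t_max = if (strict) 1e6 else 1e5,
                     rtol = if (strict) 1e-10 else 1e-7)
      relax_time <- relaxed$t_end
      if (!is.null(cand)) cand$diagnostics$relax_time <- relax_time
      x <- relaxed$x
    }
    if (is.null(cand))
      cand <- evaluate_root(newton_solve(x, sys, geom), gi, relax_time)
    if (is.null(best) || (cand$converged && !best$converged) ||
        (cand$converged == best$converged &&
         max(cand$res_g, cand$res_f) < max(best$res_g, best$res_f)))
      best <- cand
    if (best$converged) break
  }

  point <- concentration_point(best$c, best$m)
  new_steady(point, sys, geom, converged = best$converged,
             residual_f = best$res_f, residual_g = best$res_g,
             diagnostics = best$diagnostics)
}

new_steady <- function(point, sys, geom, converged, residual_f = 0,
                       residual_g = 0, diagnostics = list()) {
  structure(list(point = point, system = sys, geom = geom,
                 copy_numbers = copy_numbers_fast(unname(point$m),
                                                  unname(point$c), geom),
                 residual_f = residual_f, residual_g = residual_g,
                 converged = converged, diagnostics = diagnostics),
            class = "cdc42_steady")
}

#' @export
print.cdc42_steady <- function(x, ...) {
  cat("Homogeneous steady state (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("  cytosol  [um^-3]:", paste(sprintf("%s=%.4g", CYT_SPECIES, x$point$c),
                                   collapse = ", "), "\n")
  cat("  membrane [um^-2]:", paste(sprintf("%s=%.4g", MEM_SPECIES, x$point$m),
                                   collapse = ", "), "\n")
  cat(sprintf("  residuals: |f| <= %.3g, |g| <= %.3g\n", x$residual_f,
              x$residual_g))
  invisible(x)
}
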
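# Linear stability analysis on the sphere -------------------------------------

#' Bulk response function h_l
#'
#' Logarithmic radial derivative, at the membrane, of the bulk eigenfunction of
#' the diffusion operator that is regular at the origin and grows at rate
#' `sigma`: for `sigma > 0` the radial profile is the modified spherical Bessel
#' function `i_l(kappa r)` with `kappa = sqrt(sigma/D_c)`, giving
#' `h_l(sigma) = kappa i_l'(kappa R) / i_l(kappa R)`. For `sigma < 0` the
#' analytic continuation through the ordinary spherical Bessel function `j_l`
#' is used; `h_l(0) = l/R` is the removable limit. `h_l` relates the
#' perturbation amplitude of a cytosolic concentration at the membrane to its
#' radial gradient there, and thereby closes the membrane eigenvalue problem.
#'
#' @param sigma Real growth rate, 1/s.
#' @param l Spherical-harmonic mode index (integer >= 0).
#' @param D_c Cytosolic diffusion constant, um^2/s.
#' @param R Sphere radius, um.
#' @return `h_l` in 1/um. For `sigma < 0`, evaluation at a pole of the
#'   continuation (a zero of `j_l(kR)`) returns `NA` with a warning.
#' @export
bulk_response <- function(sigma, l, D_c, R) {
  stopifnot(length(sigma) == 1L, l >= 0, D_c > 0, R > 0)
  l <- as.integer(l)
  if (sigma == 0) return(l / R)
  if (sigma > 0) {
    x <- sqrt(sigma / D_c) * R
    # h = (l + x * i_{l+1}(x)/i_l(x)) / R, via i_l'(x) = i_{l+1}(x) + (l/x) i_l(x)
    (l + x * msbessel_ratio(x, l)) / R
  } else {
    k <- sqrt(-sigma / D_c)
    x <- k * R
    jl <- sphbessel_j(x, l)
    jl1 <- sphbessel_j(x, l + 1L)
    if (!is.finite(jl) || abs(jl) < 1e-280 ||
        abs(jl) < 1e-13 * max(abs(jl1), 1e-280)) {
      warning(sprintf("bulk_response: sigma = %g is at a pole of the continuation (zero of j_%d)",
                      sigma, l))
      return(NA_real_)
    }
    # j_l'(x) = (l/x) j_l(x) - j_{l+1}(x)
    l / R - k * jl1 / jl
  }
}

# ratio i_{l+1}(x)/i_l(x) of modified spherical Bessel functions, first kind
msbessel_ratio <- function(x, l) {
  if (x < 1e-4) return(x / (2 * l + 3))  # small-argument series limit
  num <- besselI(x, l + 1.5, expon.scaled = TRUE)
  den <- besselI(x, l + 0.5, expon.scaled = TRUE)
  if (is.finite(num) && is.finite(den) && den > 0) return(num / den)
  # fall back to the continued fraction from the three-term recurrence
  L <- l + 30L + as.integer(x)
  r <- x / (2 * L + 3)
  for (j in seq(L - 1L, l, by = -1L)) r <- 1 / ((2 * j + 3) / x + r)
  r
}

sphbessel_j <- function(x, l) {
  if (x < 1e-8) return(if (l == 0L) 1 - x^2 / 6 else x^l / prod(seq(1, 2 * l + 1, by = 2)))
  sqrt(pi / (2 * x)) * besselJ(x, l + 0.5)
}

# Pre-assembled linearization context at a homogeneous base state
lsa_context <- function(base) {
  sys <- base$system
  J <- reaction_jacobians(base$point, sys$params)
  ma <- sys$m_active; ca <- sys$c_active
  list(G_m = J$G_m[ma, ma, drop = FALSE],
       G_c = J$G_c[ma, ca, drop = FALSE],
       F_m = J$F_m[ca, ma, drop = FALSE],
       F_c = J$F_c[ca, ca, drop = FALSE],
       D_m = base$system$params$D_m[ma],
       D_c = sys$params$D_c,
       R = base$geom$R,
       n_m = length(ma))
}

#' Membrane mode matrix J_l(sigma)
#'
#' Linearizing the bulk-surface dynamics around a homogeneous steady state and
#' expanding in spherical harmonics decouples the modes. For mode `l`, the
#' bulk amplitude is slaved to the membrane amplitudes through the boundary
#' flux condition, and eliminating it yields an effective membrane eigenvalue
#' problem with matrix
#' `J_l(sigma) = G_m - q_l^2 diag(D_m) + G_c (D_c h_l(sigma) I - F_c)^{-1} F_m`
#' where `q_l^2 = l(l+1)/R^2` and `h_l` is [bulk_response()].
#'
#' @param sigma Real growth rate at which the bulk response is evaluated.
#' @param l Mode index.
#' @param base A converged [solve_homogeneous()] state.
#' @return Square matrix over the active membrane species.
#' @export
mode_matrix <- function(sigma, l, base) {
  stopifnot(inherits(base, "cdc42_steady"))
  if (!base$converged)
    stop("mode_matrix: base state did not converge", call. = FALSE)
  mode_matrix_ctx(sigma, l, lsa_context(base))
}

mode_matrix_ctx <- function(sigma, l, ctx) {
  h <- bulk_response(sigma, l, ctx$D_c, ctx$R)
  if (!is.finite(h))
    stop(sprintf("mode_matrix: bulk response undefined at sigma = %g", sigma),
         call. = FALSE)
  q2 <- l * (l + 1) / ctx$R^2
  A <- ctx$D_c * h * diag(nrow(ctx$F_c)) - ctx$F_c
  Ainv_Fm <- tryCatch(solve(A, ctx$F_m), error = function(e)
    stop(sprintf("mode_matrix: singular bulk coupling at sigma = %g", sigma),
         call. = FALSE))
  ctx$G_m - q2 * diag(ctx$D_m, nrow = ctx$n_m) + ctx$G_c %*% Ainv_Fm
}

# leading eigenvalue: largest real part (ties by magnitude); returns the
# real part and whether the leading eigenvalue is complex
leading_eigenvalue <- function(M) {
  ev <- eigen(M, only.values = TRUE)$values
  re <- Re(ev)
  i <- order(re, abs(ev), decreasing = TRUE)[1]
  list(re = re[i], complex = abs(Im(ev[i])) > 1e-10 * max(1, abs(ev[i])))
}

#' Growth rate of spherical-harmonic mode l
#'
#' Instability at mode `l` is declared iff the leading eigenvalue of
#' `J_l(0)` is positive (the stationary-pattern zero-crossing criterion). When
#' unstable, the self-consistent growth rate solves
#' `lambda_max(J_l(sigma)) = sigma`; it is located by bracketed scalar root
#' finding on `psi(sigma) = lambda_max(J_l(sigma)) - sigma` over
#' `(0, sigma_hi]`, doubling `sigma_hi` until `psi < 0`.
#'
#' @param l Mode index (>= 1 for lateral modes).
#' @param base A converged [solve_homogeneous()] state.
#' @return List with `l`, `unstable`, `sigma` (growth rate, `NA` when stable
#'   or not converged), `lambda0` (leading eigenvalue of `J_l(0)`),
#'   `oscillatory` flag, and `converged` (root-finder status).
#' @export
growth_rate <- function(l, base) {
  stopifnot(inherits(base, "cdc42_steady"))
  if (!base$converged)
    stop("growth_rate: base state did not converge", call. = FALSE)
  growth_rate_ctx(l, lsa_context(base))
}

growth_rate_ctx <- function(l, ctx) {
  le <- leading_eigenvalue(mode_matrix_ctx(0, l, ctx))
  out <- list(l = l, unstable = le$re > 0, sigma = NA_real_, lambda0 = le$re,
              oscillatory = le$complex && le$re > 0, converged = TRUE)
  if (!out$unstable) return(out)
  psi <- function(sigma) leading_eigenvalue(mode_matrix_ctx(sigma, l, ctx))$re - sigma
  hi <- max(le$re, 1e-8)
  psi_hi <- psi(hi)
  it <- 0
  while (psi_hi > 0 && it < 60) {
    hi <- hi * 2
    psi_hi <- psi(hi)
    it <- it + 1
  }
  if (psi_hi > 0) {
    out$converged <- FALSE
    return(out)
  }
  root <- tryCatch(
    stats::uniroot(psi, lower = 0, upper = hi, f.lower = le$re,
                   f.upper = psi_hi, tol = 1e-12),
    error = function(e) NULL)
  if (is.null(root)) {
    out$converged <- FALSE
    return(out)
  }
  sigma <- root$root
  # polish to |psi| < 1e-10 * max(1, sigma)
  if (abs(psi(sigma)) > 1e-10 * max(1, sigma)) {
    root <- stats::uniroot(psi, lower = max(0, sigma - 1e-6 * max(1, sigma)),
                           upper = min(hi, sigma + 1e-6 * max(1, sigma)),
                           extendInt = "downX", tol = .Machine$double.eps^0.9)
    sigma <- root$root
  }
  out$sigma <- sigma
  out$converged <- abs(psi(sigma)) <= 1e-10 * max(1, sigma)
  out
}

# l = 0 audit: eigenvalues of the well-mixed Jacobian on the conservation
# complement. Conservation contributes one exactly neutral eigenvalue per
# conserved pool; they are identified by |lambda| below a round-off threshold
# and excluded.
l0_audit <- function(base, null_tol = 1e-9) {
  J <- wellmixed_jacobian(base$point, base$system, base$geom)
  ev <- eigen(J, only.values = TRUE)$values
  thr <- null_tol * max(1, max(abs(J)))
  null_modes <- abs(ev) < thr
  n_pools <- length(active_pools(base$system))
  list(eigenvalues = ev, null_count = sum(null_modes),
       expected_null = n_pools,
       stable = all(Re(ev[!null_modes]) < 0),
       max_re = if (any(!null_modes)) max(Re(ev[!null_modes])) else -Inf)
}

#' Classify a (parameters, copy numbers, scenario) point
#'
#' Solves the homogeneous base state under the scenario, audits its stability
#' against uniform (l = 0) perturbations on the conservation-complement
#' subspace, then scans the lateral modes `l = 1..l_max` for instability.
#'
#' @param params A [parameter_set()].
#' @param targets A [copy_numbers()] object.
#' @param geom A [geometry()].
#' @param scenario Scenario name(s), see [apply_scenario()].
#' @param knobs Scenario knobs, see [apply_scenario()].
#' @param l_max Largest lateral mode scanned (default 20). A warning is issued
#'   if the fastest mode comes within 2 of `l_max`.
#' @param x0 Optional warm start for the base-state solver.
#' @param compute_sigma If `TRUE` (default) locate the self-consistent growth
#'   rate for every unstable mode; `FALSE` records only the instability
#'   criterion `lambda_max(J_l(0)) > 0` (faster; `l_fastest` is then `NA`).
#' @param early_exit If `TRUE`, stop scanning modes at the first unstable one
#'   (used by screening pipelines that only need the classification).
#' @return An object of class `"cdc42_dispersion"`: `classification` (one of
#'   `"stable"`, `"laterally_unstable"`, `"no_valid_base_state"`), a `modes`
#'   data frame (columns `l`, `lambda0`, `sigma`, `unstable`, `oscillatory`,
#'   `converged`), `l_fastest`, the `base` state and the l = 0 `audit`.
#' @export
classify <- function(params, targets, geom, scenario = "WT", knobs = list(),
                     l_max = 20L, x0 = NULL, compute_sigma = TRUE,
                     early_exit = FALSE, relax_first = TRUE) {
  sys <- if (inherits(params, "cdc42_system")) params
         else apply_scenario(params, targets, scenario, knobs)
  base <- solve_homogeneous(sys, NULL, geom, x0 = x0,
                            relax_first = relax_first)
  out <- classify_base(base, l_max = l_max, compute_sigma = compute_sigma,
                       early_exit = early_exit)
  if (out$classification == "no_valid_base_state") {
    # the fast solve (warm start or interleaved Newton polish) may have
    # landed on a root that is not the attractor of the well-mixed
    # relaxation; re-solve strictly along the relaxation branch before
    # concluding that no valid base state exists
    base <- solve_homogeneous(sys, NULL, geom, strict = TRUE)
    out <- classify_base(base, l_max = l_max, compute_sigma = compute_sigma,
                         early_exit = early_exit)
  }
  out
}

classify_base <- function(base, l_max = 20L, compute_sigma = TRUE,
                          early_exit = FALSE) {
  out <- list(classification = "no_valid_base_state",
              modes = NULL, l_fastest = NA_integer_, base = base, audit = NULL,
              reason = NULL)
  class(out) <- "cdc42_dispersion"
  if (!base$converged) {
    out$reason <- "base state solver did not converge"
    return(out)
  }
  audit <- l0_audit(base)
  out$audit <- audit
  if (!audit$stable) {
    out$reason <- "base state unstable to uniform (l = 0) perturbations"
    return(out)
  }
  ctx <- lsa_context(base)
  rows <- vector("list", l_max)
  for (l in seq_len(l_max)) {
    if (compute_sigma) {
      gr <- growth_rate_ctx(l, ctx)
    } else {
      le <- leading_eigenvalue(mode_matrix_ctx(0, l, ctx))
      gr <- list(lambda0 = le$re, sigma = NA_real_, unstable = le$re > 0,
                 oscillatory = le$complex && le$re > 0, converged = TRUE)
    }
    rows[[l]] <- data.frame(l = l, lambda0 = gr$lambda0, sigma = gr$sigma,
                            unstable = gr$unstable,
                            oscillatory = gr$oscillatory,
                            converged = gr$converged)
    if (early_exit && gr$unstable) break
  }
  modes <- do.call(rbind, rows)
  out$modes <- modes
  if (any(modes$unstable)) {
    out$classification <- "laterally_unstable"
    ok <- modes$unstable & is.finite(modes$sigma)
    if (any(ok)) {
      out$l_fastest <- modes$l[ok][which.max(modes$sigma[ok])]
      if (out$l_fastest >= l_max - 2L)
        warning(sprintf("classify: fastest mode l = %d is within 2 of l_max = %d; increase l_max",
                        out$l_fastest, l_max))
    }
  } else {
    out$classification <- "stable"
  }
  out
}

#' @export
print.cdc42_dispersion <- function(x, ...) {
  cat("Linear stability classification:", x$classification, "\n")
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  if (!is.na(x$l_fastest))
    cat(sprintf("  fastest mode l* = %d, sigma = %.4g 1/s\n", x$l_fastest,
                x$modes$sigma[x$modes$l == x$l_fastest]))
  invisible(x)
}

#' Stability diagram over copy-number space
#'
#' Classifies every cell of a grid in the (N_Cdc42, N_GAPs) plane under a
#' scenario, holding the Bem1 and GEF copy numbers fixed. Shaded (unstable)
#' cells are the regimes where spontaneous polarization is possible.
#'
#' @param params A [parameter_set()].
#' @param N_Cdc42,N_GAPs Strictly increasing numeric vectors spanning the grid
#'   axes (molecule counts).
#' @param targets A [copy_numbers()] giving the fixed `N_Bem1` and `N_GEF`.
#' @param geom A [geometry()].
#' @param scenario,knobs Passed to [apply_scenario()].
#' @param l_max Largest mode scanned per cell.
#' @return An object of class `"cdc42_diagram"`: long-format data frame
#'   `cells` with columns `N_Cdc42`, `N_GAPs`, `class`, `l_fastest`,
#'   `sigma_max`, plus the axes and scenario label. Per-cell solver failures
#'   are recorded as `"no_valid_base_state"` and the scan continues.
#' @export
stability_diagram <- function(params, N_Cdc42, N_GAPs, targets, geom,
                              scenario = "WT", knobs = list(), l_max = 20L) {
  stopifnot(length(N_Cdc42) >= 1, length(N_GAPs) >= 1,
            !is.unsorted(N_Cdc42, strictly = TRUE),
            !is.unsorted(N_GAPs, strictly = TRUE))
  tg <- unclass(targets)
  rows <- vector("list", length(N_Cdc42) * length(N_GAPs))
  idx <- 0L
  for (i in seq_along(N_Cdc42)) {
    x0 <- NULL  # warm start up each GAP column
    for (j in seq_along(N_GAPs)) {
      cell_targets <- copy_numbers(N_Cdc42 = N_Cdc42[i], N_GAPs = N_GAPs[j],
                                   N_Bem1 = tg[["N_Bem1"]],
                                   N_GEF = tg[["N_GEF"]])
      res <- tryCatch(
        suppressWarnings(classify(params, cell_targets, geom, scenario, knobs,
                                  l_max = l_max, x0 = x0)),
        error = function(e) NULL)
      idx <- idx + 1L
      if (is.null(res)) {
        rows[[idx]] <- data.frame(N_Cdc42 = N_Cdc42[i], N_GAPs = N_GAPs[j],
                                  class = "no_valid_base_state",
                                  l_fastest = NA_integer_,
                                  sigma_max = NA_real_)
        x0 <- NULL
        next
      }
      sigma_max <- if (!is.null(res$modes) && any(res$modes$unstable))
        suppressWarnings(max(res$modes$sigma, na.rm = TRUE)) else NA_real_
      rows[[idx]] <- data.frame(N_Cdc42 = N_Cdc42[i], N_GAPs = N_GAPs[j],
                                class = res$classification,
                                l_fastest = res$l_fastest,
                                sigma_max = sigma_max)
      x0 <- if (res$base$converged)
        with(res$base, c(point$m[res$base$system$m_active],
                         point$c[res$base$system$c_active])) else NULL
    }
  }
  structure(list(cells = do.call(rbind, rows), N_Cdc42 = N_Cdc42,
                 N_GAPs = N_GAPs, scenario = scenario,
                 targets = targets),
            class = "cdc42_diagram")
}

#' Logarithmically spaced copy-number grid axis
#'
#' @param from,to Endpoints (counts).
#' @param n Number of grid points.
#' @return Strictly increasing numeric vector.
#' @export
log_axis <- function(from, to, n = 40L) exp(seq(log(from), log(to), length.out = n))

#' Critical GAP copy number for lateral instability
#'
#' For a fixed Cdc42 copy number, bisects in `N_GAPs` for the boundary between
#' the laterally unstable (low-GAP) and stable (high-GAP) regimes. In the
#' Bem1-deletion scenario this boundary is the critical GAP/Cdc42 ratio that
#' delimits the latent polarization mechanism.
#'
#' @param params A [parameter_set()].
#' @param N_Cdc42 Cdc42 copy number of the column scanned.
#' @param targets A [copy_numbers()] giving the fixed `N_Bem1`, `N_GEF`.
#' @param geom A [geometry()].
#' @param scenario,knobs Passed to [apply_scenario()].
#' @param bracket Length-2 vector `c(lo, hi)` of GAP copy numbers with the
#'   point unstable at `lo` and stable at `hi`.
#' @param rel_tol Relative bracket width at which bisection stops
#'   (default 1e-3).
#' @param l_max Largest mode scanned.
#' @param unstable_fn Optional predicate `function(N_GAPs) -> logical`
#'   replacing the built-in classifier (used for testing the bisection).
#' @return List with `N_GAPs_crit`, the final `bracket`, and `iterations`.
#' @export
critical_gap_threshold <- function(params, N_Cdc42, targets, geom,
                                   scenario = "bem1_delta", knobs = list(),
                                   bracket, rel_tol = 1e-3, l_max = 20L,
                                   unstable_fn = NULL) {
  stopifnot(length(bracket) == 2L, bracket[1] > 0, bracket[2] > bracket[1])
  if (is.null(unstable_fn)) {
    tg <- unclass(targets)
    unstable_fn <- function(N_gaps) {
      cl <- suppressWarnings(classify(
        params, copy_numbers(N_Cdc42 = N_Cdc42, N_GAPs = N_gaps,
                             N_Bem1 = tg[["N_Bem1"]], N_GEF = tg[["N_GEF"]]),
        geom, scenario, knobs, l_max = l_max))
      cl$classification == "laterally_unstable"
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (!unstable_fn(lo))
    stop("critical_gap_threshold: point not unstable at lower bracket",
         call. = FALSE)
  if (unstable_fn(hi))
    stop("critical_gap_threshold: point not stable at upper bracket",
         call. = FALSE)
  iterations <- 0L
  while ((hi - lo) > rel_tol * hi) {
    mid <- sqrt(lo * hi)
    if (unstable_fn(mid)) lo <- mid else hi <- mid
    iterations <- iterations + 1L
    if (iterations > 200L) break
  }
  list(N_GAPs_crit = sqrt(lo * hi), bracket = c(lo, hi),
       iterations = iterations)
}
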
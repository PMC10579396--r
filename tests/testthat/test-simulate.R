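test_that("the finite-volume grid tiles the ball and the sphere exactly", {
  geom <- geometry(2.5)
  grid <- build_grid(geom, 12, 24)
  expect_equal(sum(grid$V_cells), geom$V, tolerance = 1e-13)
  expect_equal(sum(grid$A_mem), geom$S, tolerance = 1e-13)
  # conservative operators: volume-weighted column sums vanish
  expect_lt(max(abs(Matrix::colSums(as.numeric(grid$V_cells) * grid$L_bulk))),
            1e-10)
  expect_lt(max(abs(Matrix::colSums(grid$A_mem * grid$L_mem))), 1e-10)
  expect_error(build_grid(geom, 2, 24), ">= 4")
})

test_that("bulk diffusion reproduces the analytic eigenmode decay at second order", {
  # no-flux eigenmode of the ball: j_1(k r) P_1(cos theta) with j_1'(kR) = 0,
  # decaying at rate D k^2
  geom <- geometry(2.5)
  x1 <- 2.081575978
  kk <- x1 / geom$R
  j1 <- function(x) ifelse(x < 1e-6, x / 3, sin(x) / x^2 - cos(x) / x)
  p0 <- parameter_set(D_c = 10, D_m = 0.01)
  base <- solve_homogeneous(p0, copy_numbers(), geom)
  errs <- vapply(c(8L, 16L), function(n) {
    grid <- build_grid(geom, n, 2L * n)
    st <- initial_condition(base, grid, "none")
    prof <- outer(j1(kk * grid$r_centers), cos(grid$theta_centers))
    st$C[, 1] <- 10 + as.numeric(prof)
    tr <- run_simulation(st, t_end = 0.05, n_save = 5)
    amp <- vapply(tr$states, function(s) {
      w <- as.numeric(grid$V_cells); ph <- as.numeric(prof)
      sum(w * ph * s$C[, 1]) / sum(w * ph * ph)
    }, numeric(1))
    rate <- -unname(stats::coef(stats::lm(log(amp) ~ tr$times))[2])
    abs(rate / (10 * kk^2) - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.02)          # < 2% at modest resolution
  expect_lt(errs[2], errs[1] / 3)   # roughly quartered when h is halved
})

test_that("initial conditions hit exact Legendre content and conserve copy numbers", {
  geom <- geometry(2.5)
  grid <- build_grid(geom, 8, 32)
  p <- fixture_params()
  base <- solve_homogeneous(p, fixture_anchors(), geom)
  expect_true(base$converged)

  # zero amplitude reproduces the homogeneous state exactly
  st0 <- initial_condition(base, grid, "mode_perturbation", l = 1,
                           amplitude = 0)
  expect_equal(max(abs(sweep(st0$M, 2, unname(base$point$m)))), 0)

  # requested l = 1 amplitude is recovered exactly by the quadrature
  st1 <- initial_condition(base, grid, "mode_perturbation", l = 1,
                           amplitude = 0.037)
  pm <- polarity_metrics(st1)
  expect_equal(pm$a1, 0.037, tolerance = 5e-3)  # within quadrature error
  # and the perturbation moves no mass
  expect_equal(unname(sim_audit(st1)), unname(sim_audit(st0)),
               tolerance = 1e-12)

  # local stimulus restores the perturbed protein's copy number exactly
  st2 <- initial_condition(base, grid, "local_stimulus", species = "m_f",
                           amplitude = 5, width = 0.3)
  target <- cdc42rd:::copy_numbers_fast(unname(base$point$m),
                                        unname(base$point$c), geom)
  expect_equal(sim_audit(st2)[["N_GEF"]], target[["N_GEF"]],
               tolerance = 1e-12)

  # perturbations that drive fields negative are rejected
  expect_error(initial_condition(base, grid, "mode_perturbation", l = 1,
                                 amplitude = -10 * base$point$m[["m_t"]]),
               "negative")
})

test_that("polarity metrics have the closed-form values on analytic profiles", {
  geom <- geometry(2.5)
  grid <- build_grid(geom, 4, 64)
  p0 <- parameter_set()
  sys <- apply_scenario(p0, copy_numbers(), "WT")
  mu_avg <- cdc42rd:::legendre_cell_average(grid, 1)
  st <- structure(list(grid = grid, system = sys,
                       M = cbind(0, 1 + 0.5 * mu_avg, 0, 0, 0, 0, 0),
                       C = matrix(0, nrow(grid$L_bulk), 3), t = 0),
                  class = "cdc42_sim_state")
  pm <- polarity_metrics(st)
  expect_equal(pm$a1, 0.5, tolerance = 1e-3)  # midpoint-quadrature error
  expect_equal(pm$ratio, 3, tolerance = 1e-3)  # (1+0.5)/(1-0.5) on cell averages
  # uniform profile: ratio 1, no mode content, zero uniformity index
  st$M[, 2] <- 2
  st$M[, 1] <- 1
  pm2 <- polarity_metrics(st)
  expect_equal(pm2$a1, 0, tolerance = 1e-12)
  expect_equal(pm2$ratio, 1)
  expect_equal(pm2$uniformity, 0, tolerance = 1e-12)
})

test_that("the exact homogeneous steady state stays constant under integration", {
  geom <- geometry(2.5)
  grid <- build_grid(geom, 8, 16)
  p <- fixture_params()
  base <- solve_homogeneous(p, fixture_anchors(), geom)
  st <- initial_condition(base, grid, "none")
  tr <- run_simulation(st, t_end = 100, n_save = 4)
  final <- tr$states[[length(tr$states)]]
  scale <- max(abs(st$M))
  expect_lt(max(abs(final$M - st$M)) / scale, 1e-6)
  expect_lt(max(abs(final$C - st$C)) / max(abs(st$C)), 1e-6)
  # conserved totals drift far below 1e-6 relative over the run
  drift <- max(abs(sweep(tr$audit, 2, tr$audit[1, ], "/") - 1), na.rm = TRUE)
  expect_lt(drift, 1e-8)
})
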
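test_that("bulk response function has the analytic limits and closed forms", {
  R <- 2.5; D_c <- 10
  # removable limit h_l(0) = l/R, checked against sigma -> 0+
  for (l in 0:10) {
    expect_equal(bulk_response(0, l, D_c, R), l / R)
    expect_equal(bulk_response(1e-10, l, D_c, R), l / R, tolerance = 1e-8)
    # large-sigma asymptote sqrt(sigma / D_c)
    sig <- 1e8
    expect_equal(bulk_response(sig, l, D_c, R), sqrt(sig / D_c),
                 tolerance = 1e-3)
  }
  # l = 2, R = 4 at sigma = 0 is exactly 0.5
  expect_equal(bulk_response(0, 2, 10, 4), 0.5)
  # closed form through i_0(x) = sinh(x)/x at kappa R = 1:
  # h_0 = (coth(1) - 1)/R
  sigma <- D_c * (1 / R)^2
  expect_equal(bulk_response(sigma, 0, D_c, R), (1 / tanh(1) - 1) / R,
               tolerance = 1e-12)
  # negative-sigma continuation via j_l: at a pole the value is NA + warning
  # j_0(x) = sin(x)/x has zeros at x = n*pi
  sigma_pole <- -D_c * (pi / R)^2
  expect_warning(h <- bulk_response(sigma_pole, 0, D_c, R), "pole")
  expect_true(is.na(h))
  # away from poles the continuation is finite and real
  expect_true(is.finite(bulk_response(-0.5, 2, D_c, R)))
})

test_that("mode matrix reduces to pure membrane diffusion when reactions are off", {
  geom <- geometry(2.5)
  p <- parameter_set(D_c = 10, D_m = 0.03)
  st <- solve_homogeneous(p, copy_numbers(), geom)
  for (l in c(1, 3, 7)) {
    J <- mode_matrix(0, l, st)
    q2 <- l * (l + 1) / geom$R^2
    expect_equal(J, diag(-0.03 * q2, 7), ignore_attr = TRUE)
  }
})

test_that("block elimination in the mode matrix satisfies the boundary flux condition", {
  # independent check of the bulk-amplitude elimination: for any membrane
  # perturbation dm, the slaved bulk amplitude dc must satisfy
  # D_c h_l dc = F_m dm + F_c dc
  geom <- geometry(2.5)
  set.seed(31)
  p <- fixture_params()
  st <- solve_homogeneous(p, fixture_anchors(), geom)
  expect_true(st$converged)
  ctx <- cdc42rd:::lsa_context(st)
  for (l in c(1, 2, 5)) {
    for (sigma in c(0, 0.05, 1)) {
      h <- bulk_response(sigma, l, ctx$D_c, ctx$R)
      J <- mode_matrix(sigma, l, st)
      dm <- stats::rnorm(7)
      dc <- solve(ctx$D_c * h * diag(3) - ctx$F_c, ctx$F_m %*% dm)
      expect_equal(as.numeric(ctx$D_c * h * dc),
                   as.numeric(ctx$F_m %*% dm + ctx$F_c %*% dc),
                   tolerance = 1e-10)
      # and J dm equals the membrane linearization with that slaved bulk
      q2 <- l * (l + 1) / geom$R^2
      expect_equal(as.numeric(J %*% dm),
                   as.numeric(ctx$G_m %*% dm - q2 * ctx$D_m * dm +
                                ctx$G_c %*% dc),
                   tolerance = 1e-10)
    }
  }
})

test_that("decoupled membrane species give the pure-diffusion dispersion relation", {
  # sigma_l = -D_m l(l+1)/R^2, stable for every l >= 1
  geom <- geometry(2.5)
  p <- parameter_set(D_c = 10, D_m = 0.02)
  st <- solve_homogeneous(p, copy_numbers(), geom)
  ctx <- cdc42rd:::lsa_context(st)
  for (l in 1:6) {
    gr <- cdc42rd:::growth_rate_ctx(l, ctx)
    expect_false(gr$unstable)
    expect_equal(gr$lambda0, -0.02 * l * (l + 1) / geom$R^2, tolerance = 1e-12)
  }
})

test_that("growth rate is the exact fixed point when J_l does not depend on sigma", {
  # no bulk coupling: a single membrane species with linear gain +k and
  # diffusion; sigma_l = k - D_m q_l^2 exactly
  ctx <- list(G_m = matrix(0.4, 1, 1), G_c = matrix(0, 1, 1),
              F_m = matrix(0, 1, 1), F_c = matrix(-1, 1, 1),
              D_m = 0.01, D_c = 10, R = 2.5, n_m = 1L)
  for (l in 1:3) {
    gr <- cdc42rd:::growth_rate_ctx(l, ctx)
    q2 <- l * (l + 1) / 2.5^2
    lam <- 0.4 - 0.01 * q2
    expect_true(gr$unstable)
    expect_equal(gr$sigma, lam, tolerance = 1e-9)
  }
})

test_that("classification is deterministic and trivial cases are stable", {
  geom <- geometry(2.5)
  cl0 <- classify(fixture_params(), copy_numbers(), geom, "WT")
  expect_equal(cl0$classification, "stable")
  cl1 <- classify(fixture_params(), fixture_anchors(), geom, "WT")
  cl2 <- classify(fixture_params(), fixture_anchors(), geom, "WT")
  expect_identical(cl1$classification, cl2$classification)
  expect_identical(cl1$modes, cl2$modes)
})

test_that("a 1x1 stability diagram equals classify and rescans reproduce exactly", {
  geom <- geometry(2.5)
  p <- fixture_params()
  tg <- fixture_anchors()
  d1 <- stability_diagram(p, 5000, 2000, tg, geom, "WT")
  cl <- classify(p, tg, geom, "WT")
  expect_equal(nrow(d1$cells), 1L)
  expect_equal(d1$cells$class, cl$classification)

  ax_c <- log_axis(1000, 10000, 3)
  ax_g <- log_axis(300, 6000, 3)
  d2 <- stability_diagram(p, ax_c, ax_g, tg, geom, "bem1_delta")
  d3 <- stability_diagram(p, ax_c, ax_g, tg, geom, "bem1_delta")
  expect_identical(d2$cells$class, d3$cells$class)
  expect_equal(nrow(d2$cells), 9L)
  expect_true(all(d2$cells$class %in%
                    c("stable", "laterally_unstable", "no_valid_base_state")))
})

test_that("threshold bisection brackets a synthetic monotone classifier", {
  stub <- function(N_gaps) N_gaps < 100
  out <- critical_gap_threshold(fixture_params(), 5000, fixture_anchors(),
                                geometry(2.5), bracket = c(10, 1000),
                                unstable_fn = stub)
  expect_equal(out$N_GAPs_crit, 100, tolerance = 1e-3)
  expect_error(
    critical_gap_threshold(fixture_params(), 5000, fixture_anchors(),
                           geometry(2.5), bracket = c(200, 1000),
                           unstable_fn = stub),
    "not unstable at lower bracket")
})
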
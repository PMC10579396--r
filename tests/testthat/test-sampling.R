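test_that("degenerate ranges give the single deterministic parameter set", {
  rg <- lapply(default_rate_ranges(), function(r) c(r[1], r[1]))
  spec <- sampling_spec(n = 1, seed = 7, ranges = rg)
  smp <- sample_parameter_sets(spec)
  expect_equal(unname(smp$draws[1, ]),
               unname(vapply(default_rate_ranges(), `[`, numeric(1), 1L)))
})

test_that("the draw stream is seed-reproducible and stable in order", {
  s1 <- sample_parameter_sets(sampling_spec(n = 50, seed = 3))
  s2 <- sample_parameter_sets(sampling_spec(n = 50, seed = 3))
  expect_identical(s1$draws, s2$draws)
  # draw i is independent of the total number of draws requested
  s3 <- sample_parameter_sets(sampling_spec(n = 10, seed = 3))
  expect_identical(s3$draws, s1$draws[1:10, ])
  s4 <- sample_parameter_sets(sampling_spec(n = 50, seed = 4))
  expect_false(identical(s4$draws, s1$draws))
})

test_that("log-rate marginals are uniform by the Kolmogorov-Smirnov test", {
  spec <- sampling_spec(n = 5000, seed = 11)
  smp <- sample_parameter_sets(spec)
  for (kname in c("k_D", "k_tg", "k_f")) {
    rg <- log(spec$ranges[[kname]])
    u <- (log(smp$draws[, kname]) - rg[1]) / (rg[2] - rg[1])
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    expect_gt(ks$p.value, 1e-4)
  }
})

test_that("viability predicates fail gracefully for degenerate kinetics", {
  # all attachment rates zero: no protein reaches the membrane, so the
  # wild type cannot polarize (P1 fails)
  p <- parameter_set(k_d = 1, k_b = 1, k_f = 1)
  vf <- viability_filter(p, fixture_anchors(), geometry(2.5))
  expect_false(vf$P1)
  expect_false(vf$pass)
  expect_match(vf$reason, "P1")
})

test_that("reference selection minimizes log-distance to the log-mean", {
  mk <- function(v) do.call(parameter_set,
                            c(as.list(stats::setNames(v, cdc42rd:::RATE_NAMES)),
                              list(D_c = 10, D_m = 0.01)))
  # single member
  p1 <- mk(rep(1, 14))
  expect_identical(reference_set(list(p1))$rates, p1$rates)
  # three collinear log-points: the middle one wins
  ps <- list(mk(rep(0.1, 14)), mk(rep(1, 14)), mk(rep(10, 14)))
  expect_equal(attr(reference_set(ps), "index"), 2L)
  # random ensembles: agree with an exhaustive distance scan
  set.seed(21)
  for (rep in 1:5) {
    ps <- lapply(1:12, function(i) mk(10^stats::runif(14, -2, 2)))
    L <- t(vapply(ps, function(p) log(p$rates), numeric(14)))
    d2 <- rowSums(sweep(L, 2, colMeans(L))^2)
    expect_equal(attr(reference_set(ps), "index"), which.min(d2))
  }
  expect_error(reference_set(list()), "empty")
})

test_that("the screening pipeline is deterministic end to end", {
  spec <- sampling_spec(n = 40, seed = 9)
  scr1 <- run_screen(spec)
  scr2 <- run_screen(spec)
  expect_identical(scr1$table, scr2$table)
  expect_identical(scr1$viable_index, scr2$viable_index)
})
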
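test_that("WT scenario is the identity and all scenarios are deterministic", {
  p <- fixture_params()
  tg <- fixture_anchors()
  s1 <- apply_scenario(p, tg, "WT")
  expect_identical(s1$params$rates, p$rates)
  expect_identical(unclass(s1$targets), unclass(tg))
  expect_false(s1$reduced)
  s2 <- apply_scenario(p, tg, "WT")
  expect_identical(s1, s2)
  expect_error(apply_scenario(p, tg, "bem2_delta"), "unknown scenario")
})

test_that("Bem1 deletion removes the Bem1-containing species structurally", {
  s <- apply_scenario(fixture_params(), fixture_anchors(), "bem1_delta")
  expect_true(s$reduced)
  expect_equal(unclass(s$targets)[["N_Bem1"]], 0)
  expect_false(any(c("m_b", "m_bf") %in% cdc42rd:::MEM_SPECIES[s$m_active]))
  expect_false("c_B" %in% cdc42rd:::CYT_SPECIES[s$c_active])
  expect_setequal(cdc42rd:::active_pools(s), c("N_Cdc42", "N_GAPs", "N_GEF"))
})

test_that("Bem3 loss reduces the GAP pool by 25% by default", {
  tg <- fixture_anchors()
  s <- apply_scenario(fixture_params(), tg, "bem1_bem3_delta")
  expect_equal(unclass(s$targets)[["N_GAPs"]], 0.75 * unclass(tg)[["N_GAPs"]])
  s2 <- apply_scenario(fixture_params(), tg, "bem1_bem3_delta",
                       knobs = list(bem3_fraction = 0.4))
  expect_equal(unclass(s2$targets)[["N_GAPs"]], 0.6 * unclass(tg)[["N_GAPs"]])
  expect_error(apply_scenario(fixture_params(), tg, "bem1_bem3_delta",
                              knobs = list(bem3_fraction = 1.5)), "\\[0, 1\\]")
})

test_that("immobile Cdc42 zeroes the exchange rates and moves Cdc42 to the membrane", {
  s <- apply_scenario(fixture_params(), fixture_anchors(), "cdc42_immobile")
  expect_equal(unname(s$params$rates[c("k_D", "k_tD", "k_bfD", "k_d")]),
               rep(0, 4))
  expect_equal(unname(s$params$D_m[c("m_d", "m_t", "m_tg")]), rep(1e-4, 3))
  expect_true(s$cdc42_on_membrane)
  expect_false("c_D" %in% cdc42rd:::CYT_SPECIES[s$c_active])
  # the steady state then carries the full Cdc42 pool on the membrane
  geom <- geometry(2.5)
  st <- solve_homogeneous(s, NULL, geom)
  expect_true(st$converged)
  expect_equal(st$copy_numbers[["N_Cdc42"]], 5000, tolerance = 1e-8)
  expect_equal(st$point$c[["c_D"]], 0)
})

test_that("fast GAP turnover eliminates complex sequestration", {
  geom <- geometry(2.5)
  p <- fixture_params()
  tg <- fixture_anchors()
  st0 <- solve_homogeneous(apply_scenario(p, tg, "WT"), NULL, geom)
  sf <- apply_scenario(p, tg, "gap_fast")
  expect_equal(sf$params$rates[["k_gt"]], 1e3 * p$rates[["k_gt"]])
  st1 <- solve_homogeneous(sf, NULL, geom)
  expect_true(st0$converged && st1$converged)
  frac0 <- st0$point$m[["m_tg"]] /
    (st0$point$m[["m_tg"]] + st0$point$m[["m_g"]])
  frac1 <- st1$point$m[["m_tg"]] /
    (st1$point$m[["m_tg"]] + st1$point$m[["m_g"]])
  expect_gt(frac0 / frac1, 10)
  # preserve-ratio variant scales complex formation too
  sfr <- apply_scenario(p, tg, "gap_fast",
                        knobs = list(gap_fast_preserve_ratio = TRUE))
  expect_equal(sfr$params$rates[["k_tg"]], 1e3 * p$rates[["k_tg"]])
})

test_that("GEF boost scales both catalytic activities and scenarios compose", {
  p <- fixture_params()
  s <- apply_scenario(p, fixture_anchors(), "gef_boost",
                      knobs = list(gef_boost_factor = 5))
  expect_equal(s$params$rates[["k_fd"]], 5 * p$rates[["k_fd"]])
  expect_equal(s$params$rates[["k_bfd"]], 5 * p$rates[["k_bfd"]])

  s2 <- apply_scenario(p, fixture_anchors(), c("bem1_delta", "gap_fast"))
  expect_true(s2$reduced)
  expect_equal(s2$params$rates[["k_gt"]], 1e3 * p$rates[["k_gt"]])
})
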
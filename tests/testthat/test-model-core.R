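test_that("geometry derives volume and surface from the radius", {
  g <- geometry(2.5)
  expect_equal(g$V, 4 / 3 * pi * 2.5^3)
  expect_equal(g$S, 4 * pi * 2.5^2)
  expect_error(geometry(-1), "positive")
  expect_error(geometry(c(1, 2)), "positive")
})

test_that("parameter and point constructors validate their inputs", {
  expect_error(parameter_set(k_D = -1), ">= 0")
  expect_error(parameter_set(k_zz = 1), "unknown rate")
  expect_error(parameter_set(k_D = 1, D_c = 0), "positive")
  expect_error(concentration_point(c(-1, 0, 0), numeric(7)), "finite and >= 0")
  expect_error(copy_numbers(N_Cdc42 = -5), ">= 0")
  p <- parameter_set(D_m = c(m_d = 0, m_t = 1e-3, m_tg = 0, m_g = 1, m_b = 0,
                             m_bf = 0, m_f = 0.1))
  expect_equal(unname(p$D_m[["m_g"]]), 1)
  expect_error(parameter_set(D_m = c(m_d = 1)), "cover every membrane species")
})

test_that("reaction terms vanish at the zero point and reproduce single-term examples", {
  p0 <- parameter_set()
  z <- concentration_point()
  expect_equal(unname(reaction_flux_f(z, p0)), c(0, 0, 0))
  expect_equal(unname(reaction_rate_g(z, p0)), rep(0, 7))

  # lone detachment: m_d = 1, k_d = 2 gives f_D = 2
  p <- parameter_set(k_d = 2)
  pt <- concentration_point(m = c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(reaction_flux_f(pt, p)), c(2, 0, 0))

  # lone complex formation: m_t = 2, m_g = 3, k_tg = 0.5
  p <- parameter_set(k_tg = 0.5)
  pt <- concentration_point(m = c(0, 2, 0, 3, 0, 0, 0))
  g <- reaction_rate_g(pt, p)
  expect_equal(unname(g[c("g_tg", "g_t", "g_g")]), c(3, -3, -3))
  expect_equal(unname(g[c("g_d", "g_b", "g_bf", "g_f")]), rep(0, 4))

  expect_error(reaction_flux_f(list(c = c(-1, 0, 0), m = numeric(7)), p),
               "finite and >= 0")
})

test_that("f and g match the independent stoichiometry-matrix oracle", {
  set.seed(101)
  for (i in 1:50) {
    p <- random_params()
    pt <- random_point()
    or <- stoich_oracle(pt, p)
    expect_equal(unname(reaction_flux_f(pt, p)), unname(or$f),
                 tolerance = 1e-10)
    expect_equal(unname(reaction_rate_g(pt, p)), unname(or$g),
                 tolerance = 1e-10)
  }
})

test_that("conservation identities hold to near machine precision on 1000 random states", {
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    p <- random_params()
    pt <- random_point(scale = stats::runif(1, 0.1, 50))
    f <- reaction_flux_f(pt, p)
    g <- reaction_rate_g(pt, p)
    scale <- max(abs(c(f, g)), 1e-300)
    viol <- max(abs(c(g[["g_d"]] + g[["g_t"]] + g[["g_tg"]] + f[["f_D"]],
                      g[["g_b"]] + g[["g_bf"]] + f[["f_B"]],
                      g[["g_bf"]] + g[["g_f"]] + f[["f_F"]],
                      g[["g_g"]] + g[["g_tg"]]))) / scale
    worst <- max(worst, viol)
  }
  expect_lt(worst, 1e-12)
})

test_that("analytic Jacobians agree with central finite differences", {
  set.seed(303)
  for (i in 1:100) {
    p <- random_params()
    pt <- random_point()
    J <- reaction_jacobians(pt, p)
    Jfd <- fd_jacobians(pt, p)
    for (blk in c("G_m", "G_c", "F_m", "F_c")) {
      scale <- max(abs(J[[blk]]), 1)
      expect_lt(max(abs(unname(J[[blk]]) - Jfd[[blk]])) / scale, 1e-6)
    }
  }
  # bilinear entry has the closed form k_tg * m_g
  p <- fixture_params()
  pt <- random_point()
  J <- reaction_jacobians(pt, p)
  expect_equal(J[["G_m"]]["m_tg", "m_t"],
               p$rates[["k_tg"]] * pt$m[["m_g"]], ignore_attr = TRUE)
  # zero rates give four zero matrices
  J0 <- reaction_jacobians(pt, parameter_set())
  expect_true(all(vapply(J0, function(M) all(M == 0), logical(1))))
})

test_that("the fast positional evaluation layer equals the reference implementation", {
  set.seed(404)
  for (i in 1:25) {
    p <- random_params()
    pt <- random_point()
    m <- unname(pt$m); cc <- unname(pt$c); k <- unname(p$rates)
    expect_equal(cdc42rd:::f_fast(m, cc, k), unname(reaction_flux_f(pt, p)))
    expect_equal(cdc42rd:::g_fast(m, cc, k), unname(reaction_rate_g(pt, p)))
    Jf <- cdc42rd:::jac_fast(m, cc, k)
    Jr <- reaction_jacobians(pt, p)
    for (blk in c("G_m", "G_c", "F_m", "F_c"))
      expect_equal(Jf[[blk]], unname(Jr[[blk]]))
  }
})

test_that("copy numbers integrate uniform states and are invariant to within-pool redistribution", {
  geom <- geometry(1)
  z <- concentration_point()
  expect_equal(unname(unclass(copy_numbers_of(z, geom))), rep(0, 4))

  pt <- concentration_point(c(1, 0, 0), c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(copy_numbers_of(pt, geom)[["N_Cdc42"]], 4 * pi / 3 + 4 * pi)

  set.seed(505)
  for (i in 1:20) {
    pt <- random_point()
    cn <- copy_numbers_of(pt, geom)
    # shuffle Cdc42 mass between m_d, m_t, m_tg keeping the sum fixed
    m2 <- pt$m
    tot <- sum(m2[c("m_d", "m_t", "m_tg")])
    sh <- stats::runif(3); sh <- sh / sum(sh) * tot
    m2[c("m_d", "m_t", "m_tg")] <- sh
    cn2 <- copy_numbers_of(concentration_point(pt$c, m2), geom)
    expect_equal(cn2[["N_Cdc42"]], cn[["N_Cdc42"]])
    expect_equal(cn2[["N_GAPs"]], copy_numbers_of(pt, geom)[["N_GAPs"]] +
                   geom$S * (m2[["m_tg"]] - pt$m[["m_tg"]]))
  }
})
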
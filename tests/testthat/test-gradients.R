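# FD oracles run on a common integration window (the base history's
# truncation age): the closed forms and the finite differences then probe
# the same integral, with the truncation device held fixed.

fd_on_window <- function(lh, fitness, h = 1e-6) {
  xt <- certain_mortality_age(lh$params)
  R <- lh$params$R
  (fitness(lh_with(lh, R = R + h), xt) -
     fitness(lh_with(lh, R = R - h), xt)) / (2 * h)
}

test_that("Hamilton's gradient matches a perturbation oracle", {
  human <- species_history("human")
  p <- human$params
  xt <- certain_mortality_age(p)
  # r of a history with mortality raised additively by eps from age a
  r_eps <- function(a, eps) {
    f <- function(r)
      stats::integrate(function(x)
        exp(-r * x - eps * pmax(0, x - a)) * gm_survival(p, x) *
          reproduction_rate(human, x), 13, xt, rel.tol = 1e-12)$value - 1
    stats::uniroot(f, c(-1, 1), tol = 1e-12)$root
  }
  for (a in c(20, 40)) {
    eps <- 1e-6
    oracle <- (r_eps(a, eps) - r_eps(a, -eps)) / (2 * eps)
    expect_equal(hamilton_gradient(human, a), oracle, tolerance = 1e-4)
  }
})

test_that("Hamilton's gradient is non-positive and fades with onset age", {
  human <- species_history("human")
  a_grid <- c(13, 20, 40, 60, 80)
  vals <- vapply(a_grid, function(a) hamilton_gradient(human, a), numeric(1))
  expect_true(all(vals < 0))
  expect_true(all(diff(abs(vals)) < 0))
  # beyond the truncation age nothing is selected
  expect_equal(hamilton_gradient(human, 150), 0)
  # a permanent increment from birth is a change of M: gradient -1 exactly
  expect_equal(hamilton_gradient(human, 0), -1, tolerance = 1e-8)
})

test_that("closed-form senescence-rate gradients match finite differences", {
  for (lh in fixture_species()) {
    xt <- certain_mortality_age(lh$params)
    fd_l <- fd_on_window(lh, function(l, xt) lrs(l, truncation_age = xt)$value)
    expect_equal(dlrs_dR(lh, truncation_age = xt)$value, fd_l,
                 tolerance = 1e-4)
    fd_r <- fd_on_window(lh, function(l, xt)
      euler_lotka_r(l, truncation_age = xt)$value)
    expect_equal(dr_dR(lh, truncation_age = xt)$value, fd_r,
                 tolerance = 1e-4)
  }
})

test_that("gradient closed forms hold on randomized parameter sets", {
  for (lh in random_life_histories(10, seed = 31)) {
    xt <- certain_mortality_age(lh$params)
    fd_l <- fd_on_window(lh, function(l, xt) lrs(l, truncation_age = xt)$value)
    expect_equal(dlrs_dR(lh, truncation_age = xt)$value, fd_l,
                 tolerance = 1e-4)
  }
})

test_that("gradients vanish with the internal-damage coefficient", {
  lh <- life_history(gm_params(0, 0.1, 0.01), xs = 5, zeta = 0.1)
  expect_equal(dlrs_dR(lh)$value, 0)
  expect_equal(dr_dR(lh)$value, 0)
})

test_that("R = 0 redirects to the negligible-senescence limit", {
  lh0 <- life_history(gm_params(0.001, 0, 0.0025), 10, zeta = 0.1)
  expect_error(dlrs_dR(lh0), "gradient_r0_limit")
  expect_error(dr_dR(lh0), "gradient_r0_limit")
  expect_error(gradient_r0_limit(species_history("human")), "R = 0")
})

test_that("the negligible-senescence limit matches its closed form", {
  G <- 0.001; M <- 0.0025; xs <- 10; zeta <- 0.1; c0 <- G + M
  lh0 <- life_history(gm_params(G, 0, M), xs, zeta = zeta)
  closed <- -(G * zeta / 2) * exp(-c0 * xs) *
    (xs^2 / c0 + 2 * xs / c0^2 + 2 / c0^3)
  # the quadrature stops at the truncation age; the x^2-weighted tail beyond
  # it carries ~0.5% of the closed form's (improper-integral) mass
  expect_equal(gradient_r0_limit(lh0, "lrs")$value, closed, tolerance = 1e-2)
  # continuity: Eq-form gradient at R = 1e-6 is within 1e-3 of the limit
  lh6 <- life_history(gm_params(G, 1e-6, M), xs, zeta = zeta)
  expect_equal(dlrs_dR(lh6)$value, gradient_r0_limit(lh0, "lrs")$value,
               tolerance = 1e-3)
  # zero internal risk -> zero limit
  lhG0 <- life_history(gm_params(0, 0, M), xs, zeta = zeta)
  expect_equal(gradient_r0_limit(lhG0, "lrs")$value, 0)
  expect_equal(gradient_r0_limit(lhG0, "euler_lotka_r")$value, 0)
})

test_that("selection for negligible senescence strengthens with start-age", {
  # on the stationary-population (reproduction-regulated) scale, later
  # maturity strengthens selection against senescence at R = 0
  G <- 0.001; M <- 0.0025; zeta <- 0.1
  dd <- demographic_scenario("dd_reproduction")
  vals <- vapply(c(5, 10, 20, 40), function(xs) {
    lh <- life_history(gm_params(G, 0, M), xs, zeta = zeta)
    gradient_r0_limit(apply_density_dependence(lh, dd), "lrs")$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))  # more negative = stronger selection
})

test_that("finite-difference gradients have the predicted signs", {
  for (nm in c("human", "yellow_baboon")) {
    lh <- species_history(nm)
    for (est in c("lrs", "euler_lotka_r")) {
      expect_lt(generic_gradient(lh, "G", est)$value, 0)
      expect_lt(generic_gradient(lh, "M", est)$value, 0)
      expect_lt(generic_gradient(lh, "xs", est)$value, 0)
      expect_gt(generic_gradient(lh, "zeta", est)$value, 0)
    }
  }
})

test_that("LRS is linear in the reproduction rate", {
  human <- species_history("human")
  g <- generic_gradient(human, "zeta", "lrs")$value
  expect_equal(g, lrs(human)$value / human$zeta, tolerance = 1e-6)
})

test_that("regulation through external mortality leaves selection unchanged", {
  for (nm in c("human", "lion")) {
    lh <- species_history(nm)
    xt <- certain_mortality_age(lh$params)
    adj <- apply_density_dependence(lh, demographic_scenario("dd_external"))
    # senescence-rate gradient: identical on a common integration window
    expect_equal(dr_dR(adj, truncation_age = xt)$value,
                 dr_dR(lh, truncation_age = xt)$value, tolerance = 1e-6)
    # external-mortality gradient of r is -1 under either regime; the two
    # finite differences run on their own truncation windows, so they agree
    # only up to the truncation device's footprint (~1e-5)
    expect_equal(generic_gradient(adj, "M", "euler_lotka_r")$value,
                 generic_gradient(lh, "M", "euler_lotka_r")$value,
                 tolerance = 1e-4)
  }
})

test_that("selection on senescence strengthens as maturity nears certain death", {
  # along the stationary-population gradient curve (reproduction-regulated),
  # raising xs towards the certain-mortality age makes the gradient more
  # negative
  dd <- demographic_scenario("dd_reproduction")
  vals <- vapply(c(13, 40, 70, 95), function(xs) {
    lh <- lh_with(species_history("human"), xs = xs)
    dlrs_dR(apply_density_dependence(lh, dd))$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("declining populations select against senescence more strongly", {
  for (lh in fixture_species()) {
    g_grow <- dr_dR(apply_density_dependence(
      lh, demographic_scenario("growing")))$value
    g_decl <- dr_dR(apply_density_dependence(
      lh, demographic_scenario("declining")))$value
    expect_lt(g_decl, 0)
    expect_gt(abs(g_decl), abs(g_grow))
  }
})
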
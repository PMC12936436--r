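test_that("log-modulus is odd, sign-preserving and exact on decades", {
  expect_equal(log_modulus(0), 0)
  expect_equal(log_modulus(9), 1)
  expect_equal(log_modulus(-99), -2)
  v <- c(-1e4, -2.5, 0, 0.1, 37)
  expect_equal(log_modulus(-v), -log_modulus(v))
  expect_equal(sign(log_modulus(v)), sign(v))
})

test_that("second derivative agrees with a direct second difference", {
  # without regulation the derivative of the closed-form gradient must match
  # the second central difference of LRS itself
  human <- species_history("human")
  none <- demographic_scenario("none")
  d2 <- second_derivative_R(human, "lrs", none)
  h <- 1e-4
  L <- function(R) lrs(lh_with(human, R = R))$value
  direct <- (L(0.071 + h) - 2 * L(0.071) + L(0.071 - h)) / h^2
  expect_equal(d2, direct, tolerance = 1e-2)
})

test_that("feedback near negligible senescence splits the species", {
  # reproduction-regulated stationary populations: positive feedback at low
  # senescence rates for the long-maturity, low-external-risk species only
  for (nm in c("human", "killer_whale")) {
    lh <- lh_with(species_history(nm), R = 0.01)
    expect_gt(second_derivative_R(lh), 0)
  }
  for (nm in c("yellow_baboon", "lion")) {
    lh <- lh_with(species_history(nm), R = 0.01)
    expect_lte(second_derivative_R(lh), 0)
  }
})

test_that("feedback turns negative when maturity nears certain death", {
  for (lh in fixture_species()) {
    f <- function(R)
      certain_mortality_age(gm_params(lh$params$G, R, lh$params$M)) -
        1.3 * lh$xs
    R_hi <- stats::uniroot(f, c(0.01, 50))$root
    expect_lt(second_derivative_R(lh_with(lh, R = R_hi)), 0)
  }
})

test_that("mixed derivatives are symmetric and match a 4-point stencil", {
  human <- species_history("human")
  none <- demographic_scenario("none")
  m_RG <- mixed_derivative(human, "G", scenario = none)
  # reverse order: differentiate the G-gradient in R
  hr <- 1e-4 * 0.071
  dG <- function(R) generic_gradient(lh_with(human, R = R), "G", "lrs")$value
  m_GR <- (dG(0.071 + hr) - dG(0.071 - hr)) / (2 * hr)
  expect_equal(m_RG, m_GR, tolerance = 1e-3)
  # bivariate stencil of LRS itself
  hg <- 1e-4 * human$params$G
  L <- function(R, G) lrs(lh_with(human, R = R, G = G))$value
  stencil <- (L(0.071 + hr, 0.00041 + hg) - L(0.071 + hr, 0.00041 - hg) -
                L(0.071 - hr, 0.00041 + hg) + L(0.071 - hr, 0.00041 - hg)) /
    (4 * hr * hg)
  expect_equal(m_RG, stencil, tolerance = 1e-2)
})

test_that("co-evolutionary feedback with internal risk follows the G-M balance", {
  # G > M and early maturity relative to certain death: positive feedback
  # (low senescence and low internal risk select for each other)
  for (nm in c("human", "killer_whale")) {
    lh <- lh_with(species_history(nm), R = 0.02)
    expect_gt(mixed_derivative(lh, "G"), 0)
  }
  # external risk dominates (M > G): negative feedback, the regime of a
  # Strehler-Mildvan-like negative G-R association
  for (nm in c("yellow_baboon", "lion")) {
    lh <- species_history(nm)
    expect_gt(lh$params$M, lh$params$G)
    expect_lt(mixed_derivative(lh, "G"), 0)
  }
})

test_that("feedback maps evaluate the grid and mask non-viable cells", {
  human <- species_history("human")
  Rs <- c(0.02, 0.2, 0.45, 0.6, 0.9)
  Gs <- c(2e-4, 4.1e-4)
  fm <- feedback_map(human, x_spec = list(param = "G", values = Gs),
                     y_spec = list(param = "R", values = Rs),
                     derivative = "second_R")
  expect_equal(dim(fm$values), c(2L, 5L))
  # the mask is exactly the survival rule
  for (i in seq_along(Gs)) for (j in seq_along(Rs)) {
    expect_identical(fm$mask[i, j],
                     gm_survival(gm_params(Gs[i], Rs[j], 1e-5), 13) <= 1e-4)
    expect_identical(is.na(fm$values[i, j]), fm$mask[i, j])
  }
  expect_true(any(fm$mask))      # the high-R corner is non-viable
  expect_false(all(fm$mask))
  # single-cell oracle: the species dot reproduces the pointwise value
  cell <- feedback_map(human, list(param = "G", values = 4.1e-4),
                       list(param = "R", values = 0.071), "second_R")
  expect_equal(cell$values[1, 1], second_derivative_R(human),
               tolerance = 1e-10)
  # values are pointwise: unchanged at shared points of a finer grid
  fm2 <- feedback_map(human, x_spec = list(param = "G", values = Gs),
                      y_spec = list(param = "R", values = c(0.02, 0.1, 0.2)),
                      derivative = "second_R")
  expect_equal(fm2$values[, c(1, 3)], fm$values[, 1:2])
  # grid validation
  expect_error(feedback_map(human, list(param = "G", values = c(2, 1)),
                            list(param = "R", values = 1), "second_R"),
               "strictly increasing")
  expect_error(feedback_map(human, list(param = "G", values = -1),
                            list(param = "R", values = 1), "second_R"),
               "outside the parameter domain")
  df <- as.data.frame(fm)
  expect_equal(nrow(df), 10L)
  expect_named(df, c("G", "R", "value", "mask"))
})

test_that("the approximate near-zero condition tracks the computed sign", {
  # fixtures
  expect_true(approx_positive_feedback_condition(
    species_history("killer_whale"))$near_zero_R)
  expect_false(approx_positive_feedback_condition(
    species_history("lion"))$near_zero_R)
  # zero external risk: any G > 0 qualifies
  lh <- life_history(gm_params(1e-5, 0.1, 0), xs = 5, zeta = 0.1)
  expect_true(approx_positive_feedback_condition(lh)$near_zero_R)
  # agreement with the sign of the computed second derivative at R = 0.001
  # over a log-uniform sample of (G, M, xs)
  set.seed(41)
  agree <- 0L; used <- 0L
  while (used < 120L) {
    G <- 10^runif(1, -4, -2); M <- 10^runif(1, -5, -1)
    xs <- 10^runif(1, log10(2), log10(13))
    lh <- life_history(gm_params(G, 0.001, M), xs, zeta = 0.1)
    if (gm_survival(lh$params, xs) <= 1e-4) next
    used <- used + 1L
    pred <- approx_positive_feedback_condition(lh)$near_zero_R
    agree <- agree + (pred == (second_derivative_R(lh) > 0))
  }
  expect_gte(agree / used, 0.9)
})

test_that("the away-from-zero flag reflects distance to certain death", {
  human <- species_history("human")      # xd ~ 104 >> 2 * 13
  expect_true(approx_positive_feedback_condition(human)$away_from_zero_R)
  squeezed <- lh_with(human, R = 0.6)    # xd shrinks towards xs
  expect_false(approx_positive_feedback_condition(squeezed)$away_from_zero_R)
  # the alternative (squared) reading of the threshold stays available
  both <- approx_positive_feedback_condition(human, reading = "squared")
  expect_type(both$near_zero_R, "logical")
})
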
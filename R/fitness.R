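# Fitness estimators (Euler-Lotka r and lifetime reproductive success)
# and the density-dependence regimes.

#' Demographic scenario (density-dependence regime)
#'
#' Describes how population growth is regulated:
#' * `none` — no density dependence; populations grow or decline
#'   exponentially and fitness is the Euler-Lotka growth rate.
#' * `dd_reproduction` — density dependence acts on reproduction equally at
#'   all ages; the reproduction rate is divided by the lifetime reproductive
#'   success so the regulated population is stationary (LRS = 1) and LRS is
#'   the fitness estimator.
#' * `dd_external` — density dependence acts through external mortality;
#'   `M` absorbs the unregulated growth rate (`M + r`) so the regulated
#'   growth rate is zero. Requires `r > 0`.
#' * `growing` / `declining` — the reproduction rate of the
#'   `dd_reproduction`-normalised history is multiplied by `theta`
#'   (`theta > 1` growing, `0 < theta < 1` declining).
#'
#' @param regime One of `"none"`, `"dd_reproduction"`, `"dd_external"`,
#'   `"growing"`, `"declining"`.
#' @param theta Reproduction multiplier used by the growing/declining
#'   regimes; defaults to 10 (growing) and 0.1 (declining).
#' @return An object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(regime = c("none", "dd_reproduction",
                                            "dd_external", "growing",
                                            "declining"),
                                 theta = NULL) {
  regime <- match.arg(regime)
  if (regime == "growing") {
    theta <- theta %||% 10
    if (theta <= 1) stop("growing regime requires theta > 1", call. = FALSE)
  } else if (regime == "declining") {
    theta <- theta %||% 0.1
    if (theta <= 0 || theta >= 1)
      stop("declining regime requires 0 < theta < 1", call. = FALSE)
  }
  structure(list(regime = regime, theta = theta),
            class = "demographic_scenario")
}

.fitness_result <- function(estimator, value, truncation_age, residual) {
  structure(list(estimator = estimator, value = value,
                 truncation_age = truncation_age, residual = residual),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  lab <- switch(x$estimator,
                lrs = "lifetime reproductive success (LRS)",
                euler_lotka_r = "Euler-Lotka growth rate r")
  cat(sprintf("%s = %.8g  (truncation age %.4g, residual %.3g)\n",
              lab, x$value, x$truncation_age, x$residual))
  invisible(x)
}

#' Lifetime reproductive success
#'
#' Expected lifetime offspring number
#' \eqn{LRS = \int_{x_s}^{\infty} l(x)\, m(x)\, dx}, evaluated by adaptive
#' quadrature on `[xs, truncation age]`.
#'
#' @param lh A [life_history()] object.
#' @param truncation_age Upper limit of the age integral; defaults to
#'   [certain_mortality_age()] of `lh` (survival `1e-4`).
#' @return A `fitness_result` with `estimator = "lrs"`.
#' @examples
#' human <- life_history(gm_params(0.00041, 0.071, 0.00001), 13, zeta = 0.036)
#' lrs(human)
#' @export
lrs <- function(lh, truncation_age = NULL) {
  stopifnot(inherits(lh, "life_history"))
  p <- lh$params
  xt <- truncation_age %||% certain_mortality_age(p)
  m <- .repro_fun(lh)
  q <- .quad(function(x) exp(.gm_log_survival(p$G, p$R, p$M, x)) * m(x),
             lh$xs, xt)
  .fitness_result("lrs", q$value, xt, q$abs.error)
}

#' Euler-Lotka intrinsic growth rate
#'
#' Solves the Euler-Lotka equation
#' \eqn{1 = \int_{x_s}^{\infty} e^{-rx} l(x) m(x)\, dx} for the intrinsic
#' growth rate `r` by bracketed root search (initial bracket
#' `[-1, 1]` per year, geometric expansion, then Brent refinement).
#' The root satisfies the sign trichotomy `r > 0` iff `LRS > 1`,
#' `r = 0` iff `LRS = 1`, `r < 0` iff `LRS < 1`.
#'
#' @inheritParams lrs
#' @return A `fitness_result` with `estimator = "euler_lotka_r"`.
#' @export
euler_lotka_r <- function(lh, truncation_age = NULL) {
  stopifnot(inherits(lh, "life_history"))
  p <- lh$params
  xt <- truncation_age %||% certain_mortality_age(p)
  m <- .repro_fun(lh)
  # exponent cap: during bracket expansion strongly negative trial rates
  # would overflow e^{-rx}; capping keeps f finite without moving the root
  # (near the root the exponent is far below the cap)
  f <- function(r)
    .quad(function(x)
      exp(pmin(-r * x + .gm_log_survival(p$G, p$R, p$M, x), 200)) * m(x),
      lh$xs, xt)$value - 1
  if (f(0) == -1)
    stop("LRS is zero: the Euler-Lotka equation has no root", call. = FALSE)
  lo <- -1; hi <- 1
  n <- 0L
  while (f(lo) * f(hi) > 0) {
    lo <- lo * 2; hi <- hi * 2
    n <- n + 1L
    if (n > 60L)
      stop(sprintf("no sign change of the Euler-Lotka equation in [%g, %g]",
                   lo, hi), call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  .fitness_result("euler_lotka_r", root, xt, abs(f(root)))
}

#' Apply a density-dependence regime to a life history
#'
#' Returns the life history whose vital rates include the population
#' regulation of `scenario`:
#' * `dd_reproduction` divides the reproduction rate by the unregulated
#'   LRS, so the adjusted LRS is exactly 1;
#' * `dd_external` adds the unregulated growth rate `r` to the external
#'   mortality `M`, so the adjusted growth rate is exactly 0 (requires
#'   `r > 0`);
#' * `growing`/`declining` multiply the `dd_reproduction`-normalised
#'   reproduction rate by `theta`;
#' * `none` is the identity.
#'
#' @param lh A [life_history()] object.
#' @param scenario A [demographic_scenario()].
#' @return The adjusted `life_history`.
#' @export
apply_density_dependence <- function(lh, scenario) {
  stopifnot(inherits(lh, "life_history"),
            inherits(scenario, "demographic_scenario"))
  switch(scenario$regime,
    none = lh,
    dd_reproduction = .dd_repro(lh),
    dd_external = {
      r <- euler_lotka_r(lh)$value
      if (r <= 0)
        stop("dd_external is defined only for r > 0 (got r = ",
             signif(r, 6), ")", call. = FALSE)
      # M absorbs the growth rate. Because the truncation age shifts with M,
      # the increment is refined by fixed-point iteration (dr/dM = -1, so
      # one correction per step) until the regulated growth rate is zero
      # under the adjusted history's own truncation age.
      delta <- r
      for (i in 1:6) {
        resid <- euler_lotka_r(.lh_modify(lh, M = lh$params$M + delta))$value
        if (abs(resid) < 1e-12) break
        delta <- delta + resid
      }
      .lh_modify(lh, M = lh$params$M + delta)
    },
    growing = .scale_repro(.dd_repro(lh), scenario$theta),
    declining = .scale_repro(.dd_repro(lh), scenario$theta)
  )
}

.dd_repro <- function(lh) {
  R0 <- lrs(lh)$value
  if (R0 <= 0)
    stop("cannot normalise reproduction: LRS is zero", call. = FALSE)
  .scale_repro(lh, 1 / R0)
}

.scale_repro <- function(lh, fac) {
  if (!is.null(lh$zeta)) {
    .lh_modify(lh, zeta = lh$zeta * fac)
  } else {
    f <- lh$mx
    life_history(lh$params, lh$xs, mx = function(x) fac * f(x))
  }
}
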
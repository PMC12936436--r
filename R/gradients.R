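# Selection gradients: Hamilton's classic gradient, the closed-form
# senescence-rate gradients under both fitness estimators, their
# negligible-senescence (R -> 0) limits, and finite-difference gradients
# for the remaining life-history parameters.

.selection_gradient <- function(parameter, estimator, value, method) {
  structure(list(parameter = parameter, estimator = estimator,
                 value = value, method = method),
            class = "selection_gradient")
}

#' @export
print.selection_gradient <- function(x, ...) {
  cat(sprintf("d(%s)/d(%s) = %.8g  [%s]\n",
              x$estimator, x$parameter, x$value, x$method))
  invisible(x)
}

# Integrand factor of the closed-form senescence-rate gradients:
# (G/R^2) (e^{Rx} - Rx e^{Rx} - 1) l(x), assembled in log space so that
# e^{Rx} overflow is absorbed by the survival term (the product underflows
# to 0 rather than producing Inf * 0).
.dR_weight <- function(G, R, M, x) {
  L <- .gm_log_survival(G, R, M, x)
  (G / R^2) * ((1 - R * x) * exp(R * x + L) - exp(L))
}

# R -> 0 limit of the same factor: -(G/2) x^2 l(x).
.dR_weight_r0 <- function(G, M, x) {
  -(G / 2) * x^2 * exp(-(G + M) * x)
}

#' Hamilton's classic selection gradient
#'
#' Sensitivity of the Euler-Lotka growth rate to a permanent additive
#' increment of mortality from onset age `a`:
#' \deqn{\frac{dr}{d\mu_{a..\infty}} =
#'   -\frac{\int_a^\infty (x-a) e^{-rx} l(x) m(x) dx}
#'         {\int_0^\infty x e^{-rx} l(x) m(x) dx}.}
#' It is non-positive, and constant in `a` for `a` at or below the
#' reproduction start-age.
#'
#' @param lh A [life_history()] object.
#' @param a Onset age of the mortality increment, `>= 0`.
#' @return The (non-positive) gradient value.
#' @export
hamilton_gradient <- function(lh, a) {
  stopifnot(inherits(lh, "life_history"), is.numeric(a), length(a) == 1L,
            a >= 0)
  p <- lh$params
  xt <- certain_mortality_age(p)
  if (a >= xt) return(0)
  r <- euler_lotka_r(lh)$value
  m <- .repro_fun(lh)
  w <- function(x) exp(-r * x + .gm_log_survival(p$G, p$R, p$M, x)) * m(x)
  num <- .quad(function(x) (x - a) * w(x), max(a, lh$xs), xt)$value
  den <- .quad(function(x) x * w(x), lh$xs, xt)$value
  -num / den
}

#' Closed-form gradient of LRS with respect to senescence rate
#'
#' Evaluates
#' \deqn{\frac{dLRS}{dR} = \frac{G}{R^2}
#'   \int_{x_s}^{\infty} (e^{Rx} - Rx e^{Rx} - 1)\, l(x) m(x)\, dx,}
#' the exact derivative of lifetime reproductive success in the senescence
#' rate. The value is non-positive: faster senescence never raises fitness.
#' Requires `R > 0`; at `R = 0` use [gradient_r0_limit()].
#'
#' @inheritParams lrs
#' @return A `selection_gradient` (`parameter = "R"`, `method =
#'   "closed_form"`).
#' @export
dlrs_dR <- function(lh, truncation_age = NULL) {
  stopifnot(inherits(lh, "life_history"))
  p <- lh$params
  if (p$R < .R_EPS)
    stop("R = 0: use gradient_r0_limit() for the negligible-senescence limit",
         call. = FALSE)
  xt <- truncation_age %||% certain_mortality_age(p)
  m <- .repro_fun(lh)
  v <- .quad(function(x) .dR_weight(p$G, p$R, p$M, x) * m(x), lh$xs, xt)$value
  .selection_gradient("R", "lrs", v, "closed_form")
}

#' Closed-form gradient of the Euler-Lotka growth rate in senescence rate
#'
#' Evaluates
#' \deqn{\frac{dr}{dR} = \frac{G}{R^2}
#'   \frac{\int_{x_s}^{\infty} (e^{Rx} - Rx e^{Rx} - 1) e^{-rx} l m\, dx}
#'        {\int_{x_s}^{\infty} x e^{-rx} l m\, dx},}
#' with `r` solved from the Euler-Lotka equation. Requires `R > 0`.
#'
#' @inheritParams lrs
#' @return A `selection_gradient` (`parameter = "R"`, `estimator =
#'   "euler_lotka_r"`).
#' @export
dr_dR <- function(lh, truncation_age = NULL) {
  stopifnot(inherits(lh, "life_history"))
  p <- lh$params
  if (p$R < .R_EPS)
    stop("R = 0: use gradient_r0_limit() for the negligible-senescence limit",
         call. = FALSE)
  xt <- truncation_age %||% certain_mortality_age(p)
  r <- euler_lotka_r(lh, truncation_age = xt)$value
  m <- .repro_fun(lh)
  num <- .quad(function(x) .dR_weight(p$G, p$R, p$M, x) * exp(-r * x) * m(x),
               lh$xs, xt)$value
  den <- .quad(function(x) {
    x * exp(-r * x + .gm_log_survival(p$G, p$R, p$M, x)) * m(x)
  }, lh$xs, xt)$value
  .selection_gradient("R", "euler_lotka_r", num / den, "closed_form")
}

#' Negligible-senescence limit of the senescence-rate gradient
#'
#' The `R -> 0` limit of [dlrs_dR()] or [dr_dR()]. The integrand factor
#' \eqn{(G/R^2)(e^{Rx} - Rx e^{Rx} - 1)} tends to \eqn{-(G/2) x^2}, so for
#' the LRS estimator with constant reproduction the limit has the closed
#' form
#' \deqn{-\frac{G\zeta}{2} e^{-c x_s}
#'   \left(\frac{x_s^2}{c} + \frac{2 x_s}{c^2} + \frac{2}{c^3}\right),
#'   \quad c = G + M,}
#' which the quadrature evaluation reproduces.
#'
#' @param lh A [life_history()] with `R = 0`.
#' @param estimator `"lrs"` or `"euler_lotka_r"`.
#' @return A `selection_gradient` with `method = "r0_limit"`.
#' @export
gradient_r0_limit <- function(lh, estimator = c("lrs", "euler_lotka_r")) {
  stopifnot(inherits(lh, "life_history"))
  estimator <- match.arg(estimator)
  p <- lh$params
  if (p$R >= .R_EPS)
    stop("gradient_r0_limit() requires a life history with R = 0",
         call. = FALSE)
  xt <- certain_mortality_age(p)
  m <- .repro_fun(lh)
  v <- if (estimator == "lrs") {
    .quad(function(x) .dR_weight_r0(p$G, p$M, x) * m(x), lh$xs, xt)$value
  } else {
    r <- euler_lotka_r(lh)$value
    num <- .quad(function(x) .dR_weight_r0(p$G, p$M, x) * exp(-r * x) * m(x),
                 lh$xs, xt)$value
    den <- .quad(function(x) x * exp(-r * x - (p$G + p$M) * x) * m(x),
                 lh$xs, xt)$value
    num / den
  }
  .selection_gradient("R", estimator, v, "r0_limit")
}

# Fitness value of a life history under one estimator (helper for the
# finite-difference machinery).
.fitness_value <- function(lh, estimator) {
  switch(estimator,
         lrs = lrs(lh)$value,
         euler_lotka_r = euler_lotka_r(lh)$value,
         stop("unknown estimator: ", estimator, call. = FALSE))
}

#' Finite-difference selection gradient for any model parameter
#'
#' Central finite difference (step `max(1e-6, 1e-4 |value|)`, one
#' Richardson extrapolation level) of the chosen fitness estimator with
#' respect to one of `G`, `M`, `xs`, `zeta` or `R`. Selection always favours
#' reducing `G`, `M` and `xs` and increasing `zeta`, so the returned value
#' is negative for the first three and positive for `zeta`.
#'
#' @param lh A [life_history()] (with constant `zeta` when
#'   `parameter = "zeta"`).
#' @param parameter One of `"G"`, `"M"`, `"xs"`, `"zeta"`, `"R"`.
#' @param estimator `"lrs"` or `"euler_lotka_r"`.
#' @return A `selection_gradient` with `method = "finite_difference"`.
#' @export
generic_gradient <- function(lh, parameter = c("G", "M", "xs", "zeta", "R"),
                             estimator = c("lrs", "euler_lotka_r")) {
  stopifnot(inherits(lh, "life_history"))
  parameter <- match.arg(parameter)
  estimator <- match.arg(estimator)
  if (parameter == "zeta" && is.null(lh$zeta))
    stop("zeta gradient requires a constant-rate reproduction schedule",
         call. = FALSE)
  x0 <- switch(parameter, G = lh$params$G, M = lh$params$M, R = lh$params$R,
               xs = lh$xs, zeta = lh$zeta)
  h <- .fd_step(x0)
  if (x0 - h < 0) h <- x0 / 2   # keep perturbed values in the domain
  if (h <= .Machine$double.eps * max(1, abs(x0)))
    stop(sprintf("finite-difference step underflow for %s at %g (step %g)",
                 parameter, x0, h), call. = FALSE)
  f <- function(v) {
    args <- stats::setNames(list(v), parameter)
    .fitness_value(do.call(.lh_modify, c(list(lh), args)), estimator)
  }
  val <- .fd_central(f, x0, h = h)
  .selection_gradient(parameter, estimator, val, "finite_difference")
}

# Scenario-aware senescence-rate gradient: the resident sits at senescence
# rate R (other parameters from `base`), the scenario's regulation is
# applied at that resident, and the closed-form gradient is evaluated on
# the regulated history. This is the curve traced by the gradient-vs-R
# profiles and the quantity differentiated by the feedback analysis.
.gradient_at_R <- function(base, R, estimator, scenario) {
  lh <- .lh_modify(base, R = R)
  lh <- apply_density_dependence(lh, scenario)
  if (R < .R_EPS) {
    gradient_r0_limit(lh, estimator)$value
  } else if (estimator == "lrs") {
    dlrs_dR(lh)$value
  } else {
    dr_dR(lh)$value
  }
}
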
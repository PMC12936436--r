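# Evolutionary feedback: second and mixed derivatives of fitness in the
# senescence rate, sign maps over parameter grids, the viability mask and
# the approximate feedback conditions.

# Step used when differentiating the gradient curve a second time.
.fd2_step <- function(x) max(1e-5, 1e-3 * abs(x))

#' Second derivative of fitness with respect to senescence rate
#'
#' Feedback on senescence-rate evolution is positive where the second
#' derivative of fitness in `R` is positive: slowing senescence then
#' strengthens selection for slowing it further. The derivative is taken
#' along the scenario-adjusted gradient curve — at every senescence rate
#' the resident population is regulated by `scenario` (for
#' `dd_reproduction` its reproduction is renormalised so LRS = 1, the
#' stationary-population construction of the feedback maps) — by central
#' differencing of the closed-form first derivative. At `R = 0` a one-sided
#' second-order scheme anchored at the negligible-senescence limit is used.
#'
#' @param lh A [life_history()]; its `R` is the evaluation point.
#' @param estimator `"lrs"` or `"euler_lotka_r"`.
#' @param scenario A [demographic_scenario()]; defaults to density
#'   dependence through reproduction (the stationary-population case).
#' @return The second-derivative value (positive = positive feedback).
#' @export
second_derivative_R <- function(lh, estimator = c("lrs", "euler_lotka_r"),
                                scenario = demographic_scenario("dd_reproduction")) {
  stopifnot(inherits(lh, "life_history"))
  estimator <- match.arg(estimator)
  R0 <- lh$params$R
  g <- function(R) .gradient_at_R(lh, R, estimator, scenario)
  if (R0 < .R_EPS) {
    h <- 1e-4
    (-3 * g(0) + 4 * g(h) - g(2 * h)) / (2 * h)
  } else {
    h <- min(.fd2_step(R0), R0 / 2)
    (g(R0 + h) - g(R0 - h)) / (2 * h)
  }
}

#' Mixed derivative of fitness in senescence rate and another parameter
#'
#' \eqn{\partial^2 fitness / \partial R\, \partial \theta} for
#' \eqn{\theta \in \{G, M, x_s, \zeta\}}, computed by central differencing
#' of the scenario-adjusted closed-form senescence-rate gradient in the
#' other parameter. The fitness estimators are smooth in all parameters,
#' so the mixed derivative is symmetric in the order of differentiation;
#' the test suite checks this against differentiating in the reverse
#' order.
#'
#' @inheritParams second_derivative_R
#' @param other The co-varying parameter: `"G"`, `"M"`, `"xs"` or
#'   `"zeta"`.
#' @return The mixed-derivative value.
#' @export
mixed_derivative <- function(lh, other = c("G", "M", "xs", "zeta"),
                             estimator = c("lrs", "euler_lotka_r"),
                             scenario = demographic_scenario("dd_reproduction")) {
  stopifnot(inherits(lh, "life_history"))
  other <- match.arg(other)
  estimator <- match.arg(estimator)
  x0 <- switch(other, G = lh$params$G, M = lh$params$M, xs = lh$xs,
               zeta = lh$zeta)
  h <- .fd_step(x0)
  if (x0 - h < 0) h <- x0 / 2
  if (h <= .Machine$double.eps * max(1, abs(x0)))
    stop(sprintf("finite-difference step underflow for %s at %g", other, x0),
         call. = FALSE)
  g <- function(v) {
    args <- stats::setNames(list(v), other)
    base <- do.call(.lh_modify, c(list(lh), args))
    .gradient_at_R(base, lh$params$R, estimator, scenario)
  }
  .fd_central(g, x0, h = h)
}

#' Feedback sign map over a parameter grid
#'
#' Evaluates a feedback derivative (the second derivative in `R`, or a
#' mixed derivative of `R` with `G`, `M`, `xs` or `zeta`) on the Cartesian
#' grid `x_spec` by `y_spec`. Grid cells where survival to the reproduction
#' start-age falls to `1e-4` or below are masked: no survivor reproduces,
#' fitness is treated as zero there and the derivative is `NA`.
#'
#' @param base A [life_history()] providing the off-grid parameters.
#' @param x_spec,y_spec Lists `list(param =, values =)` with `param` one of
#'   `"G"`, `"R"`, `"M"`, `"xs"`, `"zeta"` and `values` strictly
#'   increasing.
#' @param derivative `"second_R"`, `"mixed_G"`, `"mixed_M"`, `"mixed_xs"`
#'   or `"mixed_zeta"`.
#' @inheritParams second_derivative_R
#' @return A `feedback_map`: list with the grids, the value matrix
#'   (rows = `x_spec`, columns = `y_spec`), the logical viability `mask`
#'   and the transform tag. Use [log_modulus()] for display scaling and
#'   `as.data.frame()` for plotting.
#' @export
feedback_map <- function(base, x_spec, y_spec,
                         derivative = c("second_R", "mixed_G", "mixed_M",
                                        "mixed_xs", "mixed_zeta"),
                         estimator = c("lrs", "euler_lotka_r"),
                         scenario = demographic_scenario("dd_reproduction")) {
  stopifnot(inherits(base, "life_history"))
  derivative <- match.arg(derivative)
  estimator <- match.arg(estimator)
  .check_grid <- function(spec, nm) {
    if (!is.list(spec) || is.null(spec$param) || is.null(spec$values))
      stop(nm, " must be list(param =, values =)", call. = FALSE)
    if (!spec$param %in% c("G", "R", "M", "xs", "zeta"))
      stop(nm, ": unknown parameter '", spec$param, "'", call. = FALSE)
    v <- spec$values
    if (any(diff(v) <= 0))
      stop(nm, ": grid values must be strictly increasing", call. = FALSE)
    bad <- which(v < 0)
    if (length(bad))
      stop(nm, ": values outside the parameter domain at positions ",
           paste(bad, collapse = ", "), call. = FALSE)
    spec
  }
  x_spec <- .check_grid(x_spec, "x_spec")
  y_spec <- .check_grid(y_spec, "y_spec")

  nx <- length(x_spec$values); ny <- length(y_spec$values)
  values <- matrix(NA_real_, nx, ny)
  mask <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      args <- stats::setNames(list(x_spec$values[i], y_spec$values[j]),
                              c(x_spec$param, y_spec$param))
      lh <- do.call(.lh_modify, c(list(base), args))
      if (gm_survival(lh$params, lh$xs) <= 1e-4) {
        mask[i, j] <- TRUE
        next
      }
      values[i, j] <- switch(derivative,
        second_R = second_derivative_R(lh, estimator, scenario),
        mixed_G = mixed_derivative(lh, "G", estimator, scenario),
        mixed_M = mixed_derivative(lh, "M", estimator, scenario),
        mixed_xs = mixed_derivative(lh, "xs", estimator, scenario),
        mixed_zeta = mixed_derivative(lh, "zeta", estimator, scenario))
    }
  }
  structure(list(x_axis = x_spec, y_axis = y_spec, values = values,
                 mask = mask, derivative = derivative,
                 estimator = estimator, transform = "raw"),
            class = "feedback_map")
}

#' @export
print.feedback_map <- function(x, ...) {
  cat(sprintf("feedback map: %s of %s over %s (%d) x %s (%d); %d/%d cells masked\n",
              x$derivative, x$estimator, x$x_axis$param,
              length(x$x_axis$values), x$y_axis$param,
              length(x$y_axis$values), sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
as.data.frame.feedback_map <- function(x, ...) {
  g <- expand.grid(x = x$x_axis$values, y = x$y_axis$values,
                   KEEP.OUT.ATTRS = FALSE)
  names(g) <- c(x$x_axis$param, x$y_axis$param)
  g$value <- as.vector(x$values)
  g$mask <- as.vector(x$mask)
  g
}

#' Approximate conditions for positive feedback on senescence rate
#'
#' Advisory closed-form conditions for positive evolutionary feedback
#' under the LRS estimator:
#' * near `R = 0`: \eqn{G > (M/2) e^{-0.12 x_s}} (default reading of the
#'   condition; `reading = "squared"` uses \eqn{G > M^2 e^{-0.12 x_s}});
#' * away from `R = 0`: the reproduction start-age is far below the
#'   certain-mortality age, operationalised as \eqn{x_s < 0.5\, x_d}.
#'
#' These flags approximate the sign of [second_derivative_R()]; they never
#' replace the computed derivative.
#'
#' @param lh A [life_history()].
#' @param reading `"half"` (default) or `"squared"`, the two readings of
#'   the near-zero condition's threshold.
#' @return A list with logicals `near_zero_R` and `away_from_zero_R`.
#' @export
approx_positive_feedback_condition <- function(lh,
                                               reading = c("half", "squared")) {
  stopifnot(inherits(lh, "life_history"))
  reading <- match.arg(reading)
  p <- lh$params
  thr <- switch(reading,
                half = (p$M / 2) * exp(-0.12 * lh$xs),
                squared = p$M^2 * exp(-0.12 * lh$xs))
  xd <- certain_mortality_age(p)
  list(near_zero_R = p$G > thr,
       away_from_zero_R = lh$xs < 0.5 * xd)
}

#' Log-modulus transform
#'
#' \eqn{sign(v)\, \log_{10}(1 + |v|)}: compresses the magnitude of signed
#' values spanning orders of magnitude while preserving sign and zero.
#' Used to display feedback maps.
#'
#' @param v Numeric vector.
#' @return Transformed values, same sign as `v`.
#' @examples
#' log_modulus(c(-99, 0, 9)) # -2, 0, 1
#' @export
log_modulus <- function(v) sign(v) * log10(1 + abs(v))
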
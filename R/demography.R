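# Gompertz-Makeham hazard, survival and the certain-mortality age.

# Below this value the senescence rate is treated as exactly zero and the
# constant-hazard limit of the survival function is used, avoiding the 0/0
# in G/R * (e^{Rx} - 1).
.R_EPS <- 1e-10

#' Gompertz-Makeham parameter set
#'
#' Bundles the three parameters of the Gompertz-Makeham mortality model
#' \eqn{\mu(x) = G e^{Rx} + M}: `G`, the potential mortality risk from
#' internal damage (the hazard contributed by damage at age 0, per year);
#' `R`, the senescence rate (the exponential rate at which that risk grows
#' with age, per year); and `M`, the external, age-independent mortality
#' rate (per year). `R = 0` encodes negligible senescence (constant hazard).
#'
#' @param G Internal-damage risk coefficient at age 0 (per year), `>= 0`.
#' @param R Senescence rate (per year), `>= 0`.
#' @param M External mortality rate (per year), `>= 0`.
#'
#' @return An object of class `gm_params`.
#' @examples
#' gm_params(G = 0.00041, R = 0.071, M = 0.00001) # human-like
#' @export
gm_params <- function(G, R, M) {
  stopifnot(is.numeric(G), is.numeric(R), is.numeric(M),
            length(G) == 1L, length(R) == 1L, length(M) == 1L)
  if (G < 0 || R < 0 || M < 0)
    stop("G, R and M must all be non-negative", call. = FALSE)
  if (G == 0 && M == 0)
    stop("at least one of G and M must be positive for a proper lifespan distribution",
         call. = FALSE)
  structure(list(G = G, R = R, M = M), class = "gm_params")
}

#' @export
print.gm_params <- function(x, ...) {
  cat(sprintf("Gompertz-Makeham parameters: G = %g, R = %g, M = %g\n",
              x$G, x$R, x$M))
  invisible(x)
}

.as_gm_params <- function(x) {
  if (inherits(x, "life_history")) x$params
  else if (inherits(x, "gm_params")) x
  else stop("expected a 'gm_params' or 'life_history' object", call. = FALSE)
}

#' Gompertz-Makeham hazard
#'
#' The instantaneous mortality rate \eqn{\mu(x) = G e^{Rx} + M}.
#'
#' @param params A [gm_params()] (or [life_history()]) object.
#' @param x Age(s), non-negative, in years.
#' @return Mortality rate(s) at `x` (per year).
#' @examples
#' gm_hazard(gm_params(0.00041, 0.071, 0.00001), 0) # = G + M
#' @export
gm_hazard <- function(params, x) {
  p <- .as_gm_params(params)
  if (any(x < 0)) stop("age must be non-negative", call. = FALSE)
  p$G * exp(p$R * x) + p$M
}

# log l(x); vectorised in x. Uses expm1 so small R is handled without
# cancellation; at R below .R_EPS the analytic R -> 0 limit is used.
.gm_log_survival <- function(G, R, M, x) {
  if (R < .R_EPS) {
    -(G + M) * x
  } else {
    -(G / R) * expm1(R * x) - M * x
  }
}

#' Gompertz-Makeham survival function
#'
#' Probability of surviving from birth to age `x`:
#' \eqn{l(x) = \exp(-\frac{G}{R}(e^{Rx}-1) - Mx)} for `R > 0`, and the
#' constant-hazard limit \eqn{\exp(-(G+M)x)} at `R = 0`. The two branches
#' join continuously.
#'
#' @inheritParams gm_hazard
#' @return Survival probability/probabilities in `(0, 1]`.
#' @examples
#' gm_survival(gm_params(0.001, 0, 0.0025), 100) # exp(-0.35)
#' @export
gm_survival <- function(params, x) {
  p <- .as_gm_params(params)
  if (any(x < 0)) stop("age must be non-negative", call. = FALSE)
  exp(.gm_log_survival(p$G, p$R, p$M, x))
}

#' Age of certain mortality
#'
#' The age \eqn{x_d} at which survival falls to `threshold` (default
#' `1e-4`). This age doubles as the truncation point for all age integrals
#' in the package: integrals to infinity are evaluated on
#' `[lower, certain_mortality_age(params)]`.
#'
#' @inheritParams gm_hazard
#' @param threshold Survival probability defining "certain" mortality,
#'   in `(0, 1)`.
#' @return The unique age at which `gm_survival()` equals `threshold`.
#' @examples
#' certain_mortality_age(gm_params(0.001, 0, 0.0025)) # log(1e4)/0.0035
#' @export
certain_mortality_age <- function(params, threshold = 1e-4) {
  p <- .as_gm_params(params)
  stopifnot(length(threshold) == 1L, threshold > 0, threshold < 1)
  if (p$G == 0 && p$M == 0)
    stop("unbounded lifespan: G = M = 0 admits no finite certain-mortality age",
         call. = FALSE)
  target <- log(threshold)
  f <- function(x) .gm_log_survival(p$G, p$R, p$M, x) - target
  upper <- 1
  while (f(upper) > 0) {
    upper <- upper * 2
    if (upper > 1e12)
      stop("failed to bracket the certain-mortality age", call. = FALSE)
  }
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Life history: mortality plus reproduction schedule
#'
#' Combines Gompertz-Makeham mortality with a reproduction schedule that
#' starts at the reproduction start-age `xs`. Reproduction is either a
#' constant rate `zeta` (offspring per year, from `xs` on) or an arbitrary
#' non-negative rate function `mx(x)` of age, applied from `xs` on.
#'
#' @param params A [gm_params()] object.
#' @param xs Reproduction start-age (years), `>= 0`.
#' @param zeta Constant reproduction rate from `xs` (per year); mutually
#'   exclusive with `mx`.
#' @param mx Optional reproduction rate function of age; values before `xs`
#'   are forced to zero.
#' @return An object of class `life_history`.
#' @examples
#' human <- life_history(gm_params(0.00041, 0.071, 0.00001), xs = 13, zeta = 0.036)
#' reproduction_rate(human, c(12, 13, 40))
#' @export
life_history <- function(params, xs, zeta = NULL, mx = NULL) {
  stopifnot(inherits(params, "gm_params"), is.numeric(xs), length(xs) == 1L)
  if (xs < 0) stop("xs must be non-negative", call. = FALSE)
  if (is.null(zeta) == is.null(mx))
    stop("supply exactly one of 'zeta' and 'mx'", call. = FALSE)
  if (!is.null(zeta)) {
    stopifnot(is.numeric(zeta), length(zeta) == 1L)
    if (zeta < 0) stop("zeta must be non-negative", call. = FALSE)
  } else {
    stopifnot(is.function(mx))
  }
  structure(list(params = params, xs = xs, zeta = zeta, mx = mx),
            class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  print(x$params)
  if (!is.null(x$zeta)) {
    cat(sprintf("Reproduction: constant zeta = %g from start-age xs = %g\n",
                x$zeta, x$xs))
  } else {
    cat(sprintf("Reproduction: user function from start-age xs = %g\n", x$xs))
  }
  invisible(x)
}

# Convenience: copy of a life history with some parameters replaced.
.lh_modify <- function(lh, G = NULL, R = NULL, M = NULL, xs = NULL, zeta = NULL) {
  p <- lh$params
  params <- gm_params(G = G %||% p$G, R = R %||% p$R, M = M %||% p$M)
  life_history(params,
               xs = xs %||% lh$xs,
               zeta = if (is.null(lh$mx)) zeta %||% lh$zeta else NULL,
               mx = lh$mx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reproduction rate at given ages
#'
#' Evaluates the reproduction schedule `m(x)` of a life history: zero below
#' the reproduction start-age, the constant rate (or user function) at and
#' above it.
#'
#' @param lh A [life_history()] object.
#' @param x Age(s), non-negative.
#' @return Reproduction rate(s) at `x` (per year).
#' @export
reproduction_rate <- function(lh, x) {
  stopifnot(inherits(lh, "life_history"))
  if (any(x < 0)) stop("age must be non-negative", call. = FALSE)
  base <- if (!is.null(lh$zeta)) rep(lh$zeta, length(x)) else {
    v <- lh$mx(x)
    if (any(v < 0)) stop("reproduction rate function returned negative values",
                         call. = FALSE)
    v
  }
  ifelse(x < lh$xs, 0, base)
}

# Reproduction schedule as a vectorised function of age.
.repro_fun <- function(lh) {
  function(x) reproduction_rate(lh, x)
}
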
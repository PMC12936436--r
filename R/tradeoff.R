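# Senescence-reproduction trade-off: allocation mapping, ESS search,
# brute-force fitting of the trade-off shape, and the implied maximal
# reproduction rate.

#' Senescence-reproduction trade-off specification
#'
#' A single allocation variable `z` in `[0, 1]` sets both traits:
#' \deqn{R(z) = (R_{max} - R_{min}) z^{\alpha} + R_{min}, \qquad
#'       \zeta(z) = (\zeta_{max} - \zeta_{min}) (1 - (1-z)^{\beta}) +
#'       \zeta_{min}.}
#' Both rise with `z`: allocating towards reproduction buys a higher
#' reproduction rate at the cost of faster senescence. The shape exponents
#' satisfy `alpha >= 1`, `beta >= 1`; higher values steepen early gains and
#' flatten the approach to the biological limits.
#'
#' @param alpha Shape exponent of the senescence branch, `>= 1`.
#' @param beta Shape exponent of the reproduction branch, `>= 1`.
#' @param Rmin,Rmax Senescence-rate bounds (per year), `0 <= Rmin < Rmax`.
#' @param zeta_min,zeta_max Reproduction-rate bounds (per year),
#'   `0 <= zeta_min < zeta_max`.
#' @return An object of class `tradeoff_spec`.
#' @export
tradeoff_spec <- function(alpha, beta = 1, Rmin = 1e-4, Rmax,
                          zeta_min = 0, zeta_max) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            is.numeric(Rmin), is.numeric(Rmax),
            is.numeric(zeta_min), is.numeric(zeta_max))
  if (alpha < 1 || beta < 1)
    stop("alpha and beta must be >= 1", call. = FALSE)
  if (!(Rmin >= 0 && Rmin < Rmax))
    stop("need 0 <= Rmin < Rmax", call. = FALSE)
  if (!(zeta_min >= 0 && zeta_min < zeta_max))
    stop("need 0 <= zeta_min < zeta_max", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, Rmin = Rmin, Rmax = Rmax,
                 zeta_min = zeta_min, zeta_max = zeta_max),
            class = "tradeoff_spec")
}

#' @export
print.tradeoff_spec <- function(x, ...) {
  cat(sprintf(
    "trade-off: R in [%g, %g] (alpha = %g), zeta in [%g, %g] (beta = %g)\n",
    x$Rmin, x$Rmax, x$alpha, x$zeta_min, x$zeta_max, x$beta))
  invisible(x)
}

#' Map an allocation value to (R, zeta)
#'
#' @param spec A [tradeoff_spec()].
#' @param z Allocation value(s) in `[0, 1]`.
#' @return A list with components `R` and `zeta` (vectorised over `z`).
#' @examples
#' sp <- tradeoff_spec(alpha = 1.2, Rmax = 0.8, zeta_max = 0.5)
#' tradeoff_map(sp, c(0, 0.5, 1))
#' @export
tradeoff_map <- function(spec, z) {
  stopifnot(inherits(spec, "tradeoff_spec"))
  if (any(z < 0 | z > 1))
    stop("allocation z must lie in [0, 1]", call. = FALSE)
  list(R = (spec$Rmax - spec$Rmin) * z^spec$alpha + spec$Rmin,
       zeta = (spec$zeta_max - spec$zeta_min) * (1 - (1 - z)^spec$beta) +
         spec$zeta_min)
}

# d(R)/dz and d(zeta)/dz at z.
.tradeoff_slopes <- function(spec, z) {
  list(dR = spec$alpha * (spec$Rmax - spec$Rmin) * z^(spec$alpha - 1),
       dzeta = spec$beta * (spec$zeta_max - spec$zeta_min) *
         (1 - z)^(spec$beta - 1))
}

# LRS along the trade-off and its z-gradient, sharing one truncation-age
# solve per evaluation. Constant-rate reproduction only (the trade-off is
# defined on the constant rate zeta).
.tradeoff_eval <- function(base, spec, z) {
  tz <- tradeoff_map(spec, z)
  G <- base$params$G; M <- base$params$M; xs <- base$xs
  R <- tz$R
  xd <- certain_mortality_age(gm_params(G, R, M))
  I <- .quad(function(x) exp(.gm_log_survival(G, R, M, x)), xs, xd)$value
  J <- if (R < .R_EPS) {
    .quad(function(x) .dR_weight_r0(G, M, x), xs, xd)$value
  } else {
    .quad(function(x) .dR_weight(G, R, M, x), xs, xd)$value
  }
  sl <- .tradeoff_slopes(spec, z)
  list(lrs = tz$zeta * I,
       dlrs_dz = tz$zeta * J * sl$dR + I * sl$dzeta,
       R = R, zeta = tz$zeta)
}

#' Evolutionarily stable senescence rate under the trade-off
#'
#' Scans `dLRS/dz` (assembled by the chain rule from the closed-form
#' senescence-rate gradient and the linear zeta-gradient of LRS) for sign
#' changes over `z` in `(0, 1)`, refines each bracket by root search to a
#' `z`-tolerance of `1e-8`, and reports the interior root at which the
#' curvature `d2LRS/dz2` (central second difference, step `1e-4`) is
#' negative — the ESS. If no interior root with negative curvature exists,
#' a boundary optimum (`z = 0` or `z = 1`) is reported and flagged as not
#' an ESS.
#'
#' @param base A [life_history()] supplying `G`, `M` and `xs` (its own `R`
#'   and `zeta` are replaced by the trade-off).
#' @param spec A [tradeoff_spec()].
#' @param n_scan Number of scan points over `(0, 1)`.
#' @return An object of class `ess_result`: `z_star`, `R_star`,
#'   `zeta_star`, `gradient_at_root`, `curvature`, and the logical
#'   `is_ess` (with `boundary` set when `is_ess` is `FALSE`).
#' @export
ess_find <- function(base, spec, n_scan = 201L) {
  stopifnot(inherits(base, "life_history"), inherits(spec, "tradeoff_spec"))
  eps <- 1e-6
  zg <- seq(eps, 1 - eps, length.out = n_scan)
  gv <- vapply(zg, function(z) .tradeoff_eval(base, spec, z)$dlrs_dz,
               numeric(1))
  flips <- which(gv[-1] * gv[-length(gv)] < 0)
  h <- 1e-4
  L <- function(z) .tradeoff_eval(base, spec, z)$lrs
  for (i in flips) {
    z0 <- stats::uniroot(function(z) .tradeoff_eval(base, spec, z)$dlrs_dz,
                         c(zg[i], zg[i + 1]), tol = 1e-8)$root
    hh <- min(h, z0 / 2, (1 - z0) / 2)
    curv <- (L(z0 + hh) - 2 * L(z0) + L(z0 - hh)) / hh^2
    if (curv < 0) {
      ev <- .tradeoff_eval(base, spec, z0)
      return(structure(list(z_star = z0, R_star = ev$R, zeta_star = ev$zeta,
                            gradient_at_root = ev$dlrs_dz, curvature = curv,
                            is_ess = TRUE, boundary = NULL),
                       class = "ess_result"))
    }
  }
  # no interior ESS: fitness is monotone (or only minima exist) -> boundary
  side <- if (L(1 - eps) >= L(eps)) 1 else 0
  ev <- .tradeoff_eval(base, spec, max(eps, min(1 - eps, side)))
  structure(list(z_star = NA_real_, R_star = ev$R, zeta_star = ev$zeta,
                 gradient_at_root = NA_real_, curvature = NA_real_,
                 is_ess = FALSE, boundary = side),
            class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  if (x$is_ess) {
    cat(sprintf(
      "ESS: z* = %.6f -> R* = %.6f, zeta* = %.6f (gradient %.2e, curvature %.4g)\n",
      x$z_star, x$R_star, x$zeta_star, x$gradient_at_root, x$curvature))
  } else {
    cat(sprintf("no interior ESS: boundary optimum at z = %d (R = %.6f)\n",
                x$boundary, x$R_star))
  }
  invisible(x)
}

#' Maximal senescence rate compatible with reaching maturity
#'
#' The upper bound `Rmax` of the trade-off is set so that reproduction
#' start-age precedes death: `Rmax` solves
#' `certain_mortality_age(G, R, M) = xs` under the package's truncation
#' convention (survival threshold `1e-4`), i.e. it is the largest
#' senescence rate at which any survivor reaches the reproduction
#' start-age.
#'
#' @param base A [life_history()] with `xs > 0`.
#' @param threshold Survival threshold defining death (default `1e-4`).
#' @return The senescence rate `Rmax`.
#' @export
rmax_rule <- function(base, threshold = 1e-4) {
  stopifnot(inherits(base, "life_history"))
  p <- base$params; xs <- base$xs
  if (xs <= 0)
    stop("Rmax is unbounded when xs = 0: any senescence rate permits maturation",
         call. = FALSE)
  target <- log(threshold)
  f <- function(R) .gm_log_survival(p$G, R, p$M, xs) - target
  if (f(0) <= 0)
    stop("survival to xs is already at or below the threshold at R = 0",
         call. = FALSE)
  upper <- 1
  while (f(upper) > 0) {
    upper <- upper * 2
    if (upper > 1e9) stop("failed to bracket Rmax", call. = FALSE)
  }
  stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}

#' Brute-force fit of the trade-off shape exponent
#'
#' Searches `alpha` on a grid (`[1, 3]` step `0.01`, then refined at step
#' `0.001` around the best point) for the value whose ESS senescence rate
#' equals the observed rate of `base`, assuming the observed life history
#' sits at the trade-off equilibrium. Fitting uses `beta = 1`,
#' `zeta_min = 0` and a placeholder `zeta_max = 1`: under constant-rate
#' reproduction the ESS allocation is independent of `zeta_max`, which is
#' recovered afterwards by [infer_zeta_max()].
#'
#' @param base A [life_history()] whose `R` (within `(Rmin, Rmax)`) is the
#'   fitting target.
#' @param beta Reproduction-branch exponent (default 1).
#' @param Rmin Lower senescence-rate bound (default `1e-4`).
#' @param Rmax Upper bound; defaults to [rmax_rule()] of `base`.
#' @param grid,refine_step Coarse grid of `alpha` values and the refinement
#'   step.
#' @param n_scan Scan resolution passed to [ess_find()].
#' @return The fitted `alpha`, with attributes `R_star` (the ESS rate it
#'   produces) and `Rmax`.
#' @export
fit_alpha <- function(base, beta = 1, Rmin = 1e-4, Rmax = NULL,
                      grid = seq(1, 3, by = 0.01), refine_step = 0.001,
                      n_scan = 61L) {
  stopifnot(inherits(base, "life_history"))
  Rmax <- Rmax %||% rmax_rule(base)
  R_obs <- base$params$R
  if (!(R_obs > Rmin && R_obs < Rmax))
    stop(sprintf("observed R = %g must lie inside (Rmin, Rmax) = (%g, %g)",
                 R_obs, Rmin, Rmax), call. = FALSE)
  obj <- function(alpha) {
    spec <- tradeoff_spec(alpha, beta, Rmin, Rmax, 0, 1)
    e <- ess_find(base, spec, n_scan = n_scan)
    if (!e$is_ess) Inf else abs(e$R_star - R_obs)
  }
  coarse <- vapply(grid, obj, numeric(1))
  if (all(!is.finite(coarse)))
    stop("no alpha on the search grid yields an interior ESS", call. = FALSE)
  a0 <- grid[which.min(coarse)]
  step <- if (length(grid) > 1) grid[2] - grid[1] else 0.01
  fine <- seq(max(1, a0 - step), a0 + step, by = refine_step)
  fv <- vapply(fine, obj, numeric(1))
  a <- fine[which.min(fv)]
  e <- ess_find(base, tradeoff_spec(a, beta, Rmin, Rmax, 0, 1),
                n_scan = n_scan)
  structure(a, R_star = e$R_star, Rmax = Rmax)
}

#' Implied maximal reproduction rate
#'
#' Given the fitted trade-off shape, the observed life history pins down
#' `zeta_max`: the observed senescence rate inverts to the allocation
#' `z_obs = ((R_obs - Rmin)/(Rmax - Rmin))^(1/alpha)`, and
#' `zeta_max = zeta_obs / (1 - (1 - z_obs)^beta)` (with `zeta_min = 0`;
#' for `beta = 1` this is `zeta_obs / z_obs`).
#'
#' @param base A [life_history()] with observed `R` and constant `zeta`.
#' @param alpha Fitted trade-off shape exponent (see [fit_alpha()]).
#' @param beta Reproduction-branch exponent (default 1).
#' @param Rmin Lower senescence-rate bound (default `1e-4`).
#' @param Rmax Upper bound; defaults to [rmax_rule()] of `base`.
#' @return The implied `zeta_max` (per year).
#' @export
infer_zeta_max <- function(base, alpha, beta = 1, Rmin = 1e-4, Rmax = NULL) {
  stopifnot(inherits(base, "life_history"))
  if (is.null(base$zeta))
    stop("infer_zeta_max requires a constant-rate reproduction schedule",
         call. = FALSE)
  Rmax <- Rmax %||% rmax_rule(base)
  z_obs <- ((base$params$R - Rmin) / (Rmax - Rmin))^(1 / alpha)
  if (!(z_obs > 0 && z_obs <= 1))
    stop(sprintf("inconsistent parameters: implied allocation z = %g outside (0, 1]",
                 z_obs), call. = FALSE)
  base$zeta / (1 - (1 - z_obs)^beta)
}
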
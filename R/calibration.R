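# Calibration of Gompertz-Makeham parameters and the effective
# reproduction rate from life tables.

# Model survivorship conditional on being alive at age x0:
# l(x)/l(x0) under GM parameters.
.cond_survival <- function(G, R, M, x, x0) {
  exp(.gm_log_survival(G, R, M, x) - .gm_log_survival(G, R, M, x0))
}

#' Fit Gompertz-Makeham parameters to a life table
#'
#' Least-squares nonlinear regression of the model survival curve against
#' observed survivorship from the reproduction start-age on. Observed
#' survivorship is renormalised to 1 at the first tabulated age at or
#' above `xs`, and the model curve is the survival conditional on reaching
#' that age, so juvenile mortality (which the model excludes) cannot bias
#' the adult fit. The optimiser is Levenberg-Marquardt with multi-start
#' over a log-spaced grid of initial values
#' (`G` in {1e-4, 1e-3, 1e-2}, `R` in {0.01, 0.1, 0.5},
#' `M` in {1e-5, 1e-2, 0.1}); the best converged start is returned.
#'
#' @param table A [life_table()].
#' @param xs Reproduction start-age: the fit uses ages `>= xs`.
#' @param starts Optional data frame of starting values with columns
#'   `G`, `R`, `M`, replacing the default grid.
#' @return A `gm_fit` list: `params` ([gm_params()]), `zeta` (the
#'   effective reproduction rate, see [effective_reproduction_rate()],
#'   `NA` if the table has no usable fecundity), `xs`, `sse` and
#'   `converged`.
#' @export
fit_gompertz_makeham <- function(table, xs, starts = NULL) {
  stopifnot(inherits(table, "life_table"))
  keep <- table$age >= xs & table$lx > 0
  if (sum(keep) < 4L)
    stop("need at least 4 ages at or above xs with positive survivorship",
         call. = FALSE)
  age <- table$age[keep]
  x0 <- age[1L]
  y <- table$lx[keep] / table$lx[keep][1L]

  if (diff(range(y)) < 1e-12) {
    # Degenerate: constant survivorship carries no mortality signal.
    warning("constant survivorship: parameters non-identifiable, ",
            "returning an M-only fit", call. = FALSE)
    params <- gm_params(0, 0, 1e-12)
    zeta <- tryCatch(effective_reproduction_rate(table, xs),
                     error = function(e) NA_real_)
    return(structure(list(params = params, zeta = zeta, xs = xs,
                          sse = 0, converged = FALSE), class = "gm_fit"))
  }

  if (is.null(starts)) {
    starts <- expand.grid(G = c(1e-4, 1e-3, 1e-2),
                          R = c(0.01, 0.1, 0.5),
                          M = c(1e-5, 1e-2, 0.1))
  }
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500L,
                                     ftol = 1e-15, ptol = 1e-15)
  resid_fun <- function(par) {
    .cond_survival(par[1L], par[2L], par[3L], age, x0) - y
  }
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, c("G", "R", "M")]),
                         lower = c(0, 0, 0), fn = resid_fun,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)
  params <- gm_params(best$par[1L], best$par[2L], best$par[3L])
  zeta <- if (any(table$mx[keep] > 0, na.rm = TRUE))
    effective_reproduction_rate(table, xs) else NA_real_
  structure(list(params = params, zeta = zeta, xs = xs,
                 sse = best$sse, converged = best$converged),
            class = "gm_fit")
}

#' @export
print.gm_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("zeta = %s, xs = %g, SSE = %.4g, converged: %s\n",
              format(x$zeta), x$xs, x$sse, x$converged))
  invisible(x)
}

#' Effective reproduction rate from a life table
#'
#' The mean observed fecundity at ages at or above `xs`, adjusted for
#' juvenile mortality when the table carries a juvenile-inclusive
#' survivorship column: with `l(xs)` the adult-model survivorship and
#' `l*(xs)` the survivorship including juvenile deaths,
#' \deqn{\zeta = (1 - l(x_s) + l^*(x_s))\, \bar m,}
#' which reduces to the plain mean \eqn{\bar m} when no extra juvenile
#' mortality occurred (`l* = l`). The alternative ratio reading
#' \eqn{\zeta = (l^*(x_s)/l(x_s))\, \bar m} is available via
#' `adjustment = "ratio"`.
#'
#' @param table A [life_table()].
#' @param xs Reproduction start-age.
#' @param adjustment `"additive"` (default) or `"ratio"`: how the juvenile
#'   survival deficit discounts the mean fecundity.
#' @return The effective reproduction rate `zeta` (per year).
#' @export
effective_reproduction_rate <- function(table, xs,
                                        adjustment = c("additive", "ratio")) {
  stopifnot(inherits(table, "life_table"))
  adjustment <- match.arg(adjustment)
  keep <- table$age >= xs & !is.na(table$mx)
  if (!any(keep))
    stop("no fecundity observations at or above xs", call. = FALSE)
  mbar <- mean(table$mx[keep])
  if (is.null(table$lx_star)) return(mbar)
  i0 <- which(table$age >= xs)[1L]
  l_xs <- table$lx[i0]
  l_star_xs <- table$lx_star[i0]
  switch(adjustment,
         additive = (1 - l_xs + l_star_xs) * mbar,
         ratio = (l_star_xs / l_xs) * mbar)
}
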
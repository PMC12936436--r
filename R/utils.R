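# Shared numerical helpers.

# Adaptive quadrature over an age interval, tight tolerances. All integrals
# to "infinity" in the model are evaluated on [lower, truncation age], the
# age where survival drops to 1e-4.
.quad <- function(f, lower, upper) {
  if (upper <= lower) return(list(value = 0, abs.error = 0))
  q <- stats::integrate(f, lower, upper,
                        rel.tol = 1e-10, abs.tol = 1e-13,
                        subdivisions = 1000L, stop.on.error = FALSE)
  if (!q$message %in% c("OK", "roundoff error was detected"))
    stop("quadrature failed on [", signif(lower, 6), ", ", signif(upper, 6),
         "]: ", q$message, call. = FALSE)
  q
}

# Central finite difference with one level of Richardson extrapolation.
# Default step follows h = max(1e-6, 1e-4 * |x|).
.fd_step <- function(x) max(1e-6, 1e-4 * abs(x))

.fd_central <- function(f, x, h = .fd_step(x), richardson = TRUE) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  if (!richardson) return(d1)
  h2 <- h / 2
  d2 <- (f(x + h2) - f(x - h2)) / (2 * h2)
  (4 * d2 - d1) / 3
}
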
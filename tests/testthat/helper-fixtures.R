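# Shared fixtures and small oracles used across the test files.

# The four bundled species parameterisations.
fixture_species <- function() {
  nm <- c("human", "killer_whale", "yellow_baboon", "lion")
  stats::setNames(lapply(nm, species_history), nm)
}

# Copy of a life history with some parameters replaced (exported-API path).
lh_with <- function(lh, G = NULL, R = NULL, M = NULL, xs = NULL,
                    zeta = NULL) {
  p <- lh$params
  life_history(gm_params(if (is.null(G)) p$G else G,
                         if (is.null(R)) p$R else R,
                         if (is.null(M)) p$M else M),
               xs = if (is.null(xs)) lh$xs else xs,
               zeta = if (is.null(zeta)) lh$zeta else zeta)
}

# Random valid life histories (viable: survival to xs above the mask).
random_life_histories <- function(n, seed) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    lh <- life_history(
      gm_params(10^stats::runif(1, -4, -2),
                stats::runif(1, 0.03, 0.3),
                10^stats::runif(1, -4, -1.5)),
      xs = stats::runif(1, 2, 14),
      zeta = stats::runif(1, 0.05, 0.4))
    if (gm_survival(lh$params, lh$xs) > 1e-3) out[[length(out) + 1L]] <- lh
  }
  out
}

# Dense trapezoid integral of f over [a, b].
trapezoid <- function(f, a, b, step = 1e-3) {
  x <- seq(a, b, by = step)
  y <- f(x)
  sum((y[-1] + y[-length(y)]) / 2) * step
}

# Plain bisection root finder, independent of stats::uniroot.
bisect <- function(f, lo, hi, tol = 1e-10) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
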
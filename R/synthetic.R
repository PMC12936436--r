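# Synthetic life tables with known Gompertz-Makeham truth, for
# parameter-recovery experiments.

#' Simulate a life table from known truth
#'
#' Builds a life table from a [life_history()] with known
#' Gompertz-Makeham parameters. In deterministic mode
#' (`n_individuals = NULL`) the survivorship column is the closed-form
#' survival at the grid ages and fecundity equals the reproduction rate.
#' In stochastic mode a cohort of `n_individuals` is followed through the
#' age grid: deaths per interval are binomial with the interval death
#' probability `1 - l(x + step)/l(x)`, survivorship is the surviving
#' fraction, and observed fecundity is Poisson-sampled around the true
#' rate (`NA` once the cohort is extinct). An optional constant extra
#' hazard on `[0, xs)` adds a juvenile-inclusive survivorship column
#' `lx_star`.
#'
#' @param truth A [life_history()] with constant `zeta`.
#' @param age_step Grid step in years (default 1; annual life table).
#' @param n_individuals Cohort size for stochastic sampling, or `NULL`
#'   for the deterministic table.
#' @param juvenile_hazard Optional constant extra mortality rate (per
#'   year) acting before `xs`.
#' @param max_age Last tabulated age; defaults to the certain-mortality
#'   age of `truth`.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   table and the caller's RNG state is left untouched.
#' @return A [life_table()].
#' @export
simulate_life_table <- function(truth, age_step = 1, n_individuals = NULL,
                                juvenile_hazard = NULL, max_age = NULL,
                                seed = NULL) {
  stopifnot(inherits(truth, "life_history"))
  if (age_step <= 0) stop("age_step must be positive", call. = FALSE)
  if (!is.null(n_individuals) &&
      (n_individuals < 1 || n_individuals != round(n_individuals)))
    stop("n_individuals must be a positive integer", call. = FALSE)
  if (!is.null(juvenile_hazard) && juvenile_hazard < 0)
    stop("juvenile_hazard must be non-negative", call. = FALSE)

  p <- truth$params
  xmax <- max_age %||% certain_mortality_age(p)
  ages <- seq(0, xmax, by = age_step)
  lx_true <- gm_survival(p, ages)
  mx_true <- reproduction_rate(truth, ages)
  juv_factor <- if (is.null(juvenile_hazard)) NULL else
    exp(-juvenile_hazard * pmin(ages, truth$xs))

  if (is.null(n_individuals)) {
    return(life_table(ages, lx_true, mx_true,
                      survivorship_with_juvenile =
                        if (!is.null(juv_factor)) lx_true * juv_factor))
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }

  n <- length(ages)
  N <- as.integer(n_individuals)
  alive <- integer(n)           # adult-hazard-only cohort
  alive_full <- integer(n)      # including juvenile extra hazard
  alive[1L] <- N
  alive_full[1L] <- N
  for (i in seq_len(n - 1L)) {
    q <- 1 - lx_true[i + 1L] / lx_true[i]
    deaths <- stats::rbinom(1L, alive[i], q)
    alive[i + 1L] <- alive[i] - deaths
    if (!is.null(juv_factor)) {
      qj <- 1 - juv_factor[i + 1L] / juv_factor[i]
      # juvenile extra deaths among those the adult hazard spared
      surv_ratio <- if (alive[i] > 0) alive[i + 1L] / alive[i] else 0
      adult_surv <- stats::rbinom(1L, alive_full[i],
                                  surv_ratio)
      alive_full[i + 1L] <- adult_surv -
        stats::rbinom(1L, adult_surv, qj)
    } else {
      alive_full[i + 1L] <- alive[i + 1L]
    }
  }
  lx_obs <- alive / N
  counts <- if (is.null(juv_factor)) alive else alive_full
  mx_obs <- rep(NA_real_, n)
  repro <- ages >= truth$xs
  for (i in which(repro)) {
    if (counts[i] > 0) {
      births <- stats::rpois(1L, counts[i] * mx_true[i] * age_step)
      mx_obs[i] <- births / (counts[i] * age_step)
    }
  }
  mx_obs[!repro] <- 0
  life_table(ages, lx_obs, mx_obs,
             survivorship_with_juvenile =
               if (!is.null(juv_factor)) alive_full / N)
}
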
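# High-level interface: gradient-vs-R profiles and the one-shot species
# report tying the pipeline together. Time units are years throughout the
# package (the bundled species parameters are annual rates); the unit is
# fixed, not configurable, to avoid silent mixing.

#' Selection-gradient profile over senescence rate
#'
#' Sweeps the senescence rate over a grid holding the other parameters of
#' `lh` fixed. At every grid value the resident population is regulated by
#' `scenario` and the closed-form gradient of the chosen fitness estimator
#' is evaluated on the regulated history (at `R = 0` the
#' negligible-senescence limit). Grid values where survival to the
#' reproduction start-age drops to `1e-4` or below are reported as `NA`
#' (zero fitness) with a warning.
#'
#' @param lh A [life_history()] (e.g. [species_history()]).
#' @param R_values Senescence-rate grid (non-negative, increasing).
#' @param estimator `"lrs"` or `"euler_lotka_r"`.
#' @param scenario A [demographic_scenario()].
#' @return A data frame with columns `R`, `gradient`, `estimator`,
#'   `regime`; one row per grid value.
#' @export
run_gradient_profile <- function(lh, R_values,
                                 estimator = c("euler_lotka_r", "lrs"),
                                 scenario = demographic_scenario("none")) {
  stopifnot(inherits(lh, "life_history"),
            inherits(scenario, "demographic_scenario"))
  estimator <- match.arg(estimator)
  if (any(R_values < 0)) stop("R grid must be non-negative", call. = FALSE)
  grad <- vapply(R_values, function(R) {
    if (gm_survival(gm_params(lh$params$G, R, lh$params$M), lh$xs) <= 1e-4)
      return(NA_real_)
    .gradient_at_R(lh, R, estimator, scenario)
  }, numeric(1))
  if (anyNA(grad))
    warning("some grid values fall in the non-viable region ",
            "(survival to xs <= 1e-4); gradients set to NA", call. = FALSE)
  data.frame(R = R_values, gradient = grad, estimator = estimator,
             regime = scenario$regime)
}

#' One-shot species report
#'
#' Runs the full pipeline for one parameter set: fitness under every
#' density-dependence regime, selection gradients for all five model
#' parameters, feedback diagnostics, and — when a trade-off is supplied —
#' the ESS. Sections fail independently: an error in one is recorded in
#' its place and the rest of the report is still produced.
#'
#' @param config A list with exactly one of `species` (a name from
#'   [list_species()]) or `params` (a list with `G`, `R`, `M`, `xs`,
#'   `zeta`); optional `estimator` (default `"lrs"`), `theta_growing`,
#'   `theta_declining`, and `tradeoff` (a [tradeoff_spec()] or a list of
#'   its arguments; `Rmax` defaults to [rmax_rule()]).
#' @return A list of class `species_report`; serialise with
#'   [report_json()].
#' @export
run_full_species_report <- function(config) {
  errs <- character(0)
  if (!is.list(config)) errs <- c(errs, "config must be a list")
  has_species <- !is.null(config$species)
  has_params <- !is.null(config$params)
  if (has_species == has_params)
    errs <- c(errs, "supply exactly one of 'species' and 'params'")
  estimator <- config$estimator %||% "lrs"
  if (!estimator %in% c("lrs", "euler_lotka_r"))
    errs <- c(errs, paste0("unknown estimator '", estimator, "'"))
  if (length(errs))
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)

  lh <- if (has_species) species_history(config$species) else
    with(config$params,
         life_history(gm_params(G, R, M), xs = xs, zeta = zeta))

  sect <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))

  fitness <- sect({
    out <- list(lrs = lrs(lh)$value, euler_lotka_r = euler_lotka_r(lh)$value)
    for (reg in c("dd_reproduction", "dd_external", "growing", "declining")) {
      th <- switch(reg, growing = config$theta_growing %||% 10,
                   declining = config$theta_declining %||% 0.1, NULL)
      adj <- sect({
        a <- apply_density_dependence(lh, demographic_scenario(reg, th))
        if (reg == "dd_external") euler_lotka_r(a)$value else
          if (reg == "dd_reproduction") lrs(a)$value else
            euler_lotka_r(a)$value
      })
      out[[reg]] <- adj
    }
    out
  })

  gradients <- sect({
    g <- list()
    g$R <- if (estimator == "lrs") dlrs_dR(lh)$value else dr_dR(lh)$value
    for (par in c("G", "M", "xs", "zeta"))
      g[[par]] <- generic_gradient(lh, par, estimator)$value
    g
  })

  feedback <- sect({
    flags <- approx_positive_feedback_condition(lh)
    list(second_derivative_R = second_derivative_R(lh, "lrs"),
         near_zero_R_positive = flags$near_zero_R,
         away_from_zero_R_positive = flags$away_from_zero_R)
  })

  ess <- if (!is.null(config$tradeoff)) sect({
    spec <- config$tradeoff
    if (!inherits(spec, "tradeoff_spec")) {
      spec$Rmax <- spec$Rmax %||% rmax_rule(lh)
      spec$zeta_max <- spec$zeta_max %||% 1
      spec <- do.call(tradeoff_spec, spec)
    }
    e <- ess_find(lh, spec)
    list(z_star = e$z_star, R_star = e$R_star, zeta_star = e$zeta_star,
         is_ess = e$is_ess)
  }) else NULL

  structure(list(
    species = if (has_species) config$species else NULL,
    parameters = list(G = lh$params$G, R = lh$params$R, M = lh$params$M,
                      xs = lh$xs, zeta = lh$zeta),
    estimator = estimator,
    truncation_age = certain_mortality_age(lh$params),
    fitness = fitness,
    gradients = gradients,
    feedback = feedback,
    ess = ess
  ), class = "species_report")
}

#' @export
print.species_report <- function(x, ...) {
  cat("Species report", if (!is.null(x$species)) paste0("(", x$species, ")"),
      "\n")
  with(x$parameters, cat(sprintf(
    "  G = %g, R = %g, M = %g, xs = %g, zeta = %g\n", G, R, M, xs, zeta)))
  cat(sprintf("  truncation age: %.2f years\n", x$truncation_age))
  if (is.null(x$fitness$error))
    cat(sprintf("  LRS = %.4f, r = %.5f\n",
                x$fitness$lrs, x$fitness$euler_lotka_r))
  if (is.null(x$gradients$error))
    cat(sprintf(
      "  gradients (%s): dR = %.4g, dG = %.4g, dM = %.4g, dxs = %.4g, dzeta = %.4g\n",
      x$estimator, x$gradients$R, x$gradients$G, x$gradients$M,
      x$gradients$xs, x$gradients$zeta))
  if (is.null(x$feedback$error))
    cat(sprintf("  feedback d2/dR2 = %.4g (near-zero-R condition: %s)\n",
                x$feedback$second_derivative_R,
                x$feedback$near_zero_R_positive))
  if (!is.null(x$ess) && is.null(x$ess$error) && isTRUE(x$ess$is_ess))
    cat(sprintf("  ESS: z* = %.4f, R* = %.5f, zeta* = %.5f\n",
                x$ess$z_star, x$ess$R_star, x$ess$zeta_star))
  invisible(x)
}

#' Serialise a species report to JSON
#'
#' @param report A `species_report` from [run_full_species_report()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "species_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                         null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
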
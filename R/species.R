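# Bundled species parameterisations and flat key-value config I/O.

#' Bundled species parameterisations
#'
#' Gompertz-Makeham and reproduction parameters estimated for wild
#' populations of four mammals, shipped as flat key-value configs
#' (`G`, `R`, `M`, `xs`, `zeta`):
#' human (`G = 0.00041, R = 0.071, M = 0.00001, xs = 13, zeta = 0.036`),
#' killer whale (`G = 0.00094, R = 0.048, M = 0.00001, xs = 11,
#' zeta = 0.051`), yellow baboon (`G = 0.003, R = 0.208, M = 0.05,
#' xs = 5, zeta = 0.182`) and lion (`G = 0.0025, R = 0.325, M = 0.0522,
#' xs = 2, zeta = 0.2`).
#'
#' @param name One of `list_species()`.
#' @return A [life_history()]; the species name is kept in attribute
#'   `"species"`.
#' @examples
#' species_history("human")
#' @export
species_history <- function(name) {
  name <- match.arg(name, list_species())
  path <- system.file("extdata", "species", paste0(name, ".yaml"),
                      package = "senesce", mustWork = TRUE)
  read_life_history(path, species = name)
}

#' @rdname species_history
#' @export
list_species <- function() {
  dir <- system.file("extdata", "species", package = "senesce",
                     mustWork = TRUE)
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Read or write a life history as a flat key-value config
#'
#' The config is YAML with the scalar keys `G`, `R`, `M`, `xs`, `zeta`.
#'
#' @param path Config file path.
#' @param species Optional name stored in the `"species"` attribute.
#' @return `read_life_history()` returns a [life_history()];
#'   `write_life_history()` returns `path` invisibly.
#' @export
read_life_history <- function(path, species = NULL) {
  cfg <- yaml::read_yaml(path)
  need <- c("G", "R", "M", "xs", "zeta")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lh <- life_history(gm_params(cfg$G, cfg$R, cfg$M), xs = cfg$xs,
                     zeta = cfg$zeta)
  attr(lh, "species") <- species
  lh
}

#' @rdname read_life_history
#' @param lh A [life_history()] with constant `zeta`.
#' @export
write_life_history <- function(lh, path) {
  stopifnot(inherits(lh, "life_history"))
  if (is.null(lh$zeta))
    stop("only constant-rate life histories can be written as configs",
         call. = FALSE)
  yaml::write_yaml(list(G = lh$params$G, R = lh$params$R, M = lh$params$M,
                        xs = lh$xs, zeta = lh$zeta), path)
  invisible(path)
}
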
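# Life-table container and delimited-text I/O.

#' Life table
#'
#' A tabulated cohort schedule: ages (interval left endpoints),
#' survivorship `lx` (probability of being alive at the start of the
#' interval, excluding juvenile mortality), per-age fecundity `mx`, and
#' optionally the survivorship including juvenile mortality (`lx_star`).
#'
#' @param ages Strictly increasing ages (years).
#' @param survivorship `lx` values in `[0, 1]`, non-increasing, starting at
#'   most at 1.
#' @param fecundity `mx` values `>= 0` (`NA` allowed where unobserved).
#' @param survivorship_with_juvenile Optional `lx*` values including
#'   juvenile mortality, same constraints as `survivorship`.
#' @return A data frame of class `life_table` with columns `age`, `lx`,
#'   `mx` and optionally `lx_star`.
#' @export
life_table <- function(ages, survivorship, fecundity,
                       survivorship_with_juvenile = NULL) {
  n <- length(ages)
  if (length(survivorship) != n || length(fecundity) != n)
    stop("ages, survivorship and fecundity must have equal length",
         call. = FALSE)
  if (any(diff(ages) <= 0))
    stop("ages must be strictly increasing", call. = FALSE)
  .check_lx <- function(lx, nm) {
    bad <- which(lx < 0 | lx > 1)
    if (length(bad))
      stop(nm, " outside [0, 1] at rows ", paste(bad, collapse = ", "),
           call. = FALSE)
    inc <- which(diff(lx) > 1e-12)
    if (length(inc))
      stop(nm, " increases at rows ", paste(inc + 1L, collapse = ", "),
           call. = FALSE)
  }
  .check_lx(survivorship, "survivorship")
  if (any(fecundity < 0, na.rm = TRUE))
    stop("fecundity must be non-negative", call. = FALSE)
  tab <- data.frame(age = ages, lx = survivorship, mx = fecundity)
  if (!is.null(survivorship_with_juvenile)) {
    if (length(survivorship_with_juvenile) != n)
      stop("survivorship_with_juvenile must match the other columns",
           call. = FALSE)
    .check_lx(survivorship_with_juvenile, "survivorship_with_juvenile")
    tab$lx_star <- survivorship_with_juvenile
  }
  class(tab) <- c("life_table", "data.frame")
  tab
}

#' Read a life table from delimited text
#'
#' Expects a header with columns `age`, `lx`, `mx` and optionally
#' `lx_star`; the delimiter (comma or tab) is detected from the header
#' line. All [life_table()] invariants are validated with offending rows
#' reported.
#'
#' @param path Path to a CSV or TSV file.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("age", "lx", "mx")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("life table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  life_table(d$age, d$lx, d$mx,
             survivorship_with_juvenile = if ("lx_star" %in% names(d))
               d$lx_star)
}

#' Write a life table to delimited text
#'
#' @param table A [life_table()].
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "life_table"))
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
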
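# Internal helpers shared across the package.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all reported money and percent
#' figures. Base R's `round()` rounds half to even, which disagrees with the
#' convention used in published cost tables (e.g. 7492.5 must report as 7493).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(7492.5)   # 7493
#' round_half_up(0.295, 2) # 0.3
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cea <- function(fmt, ..., class = "trialcea_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_cea("`%s` must be a single non-missing number", name)
  }
  if (x < min || x > max) {
    stop_cea("`%s` = %g is outside the allowed range [%g, %g]", name, x, min, max)
  }
  invisible(x)
}

assert_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    stop_cea("`%s` must be one of: %s (got %s)", name,
             paste(choices, collapse = ", "),
             if (is.character(x) && length(x) == 1L) sQuote(x) else "a non-string")
  }
  invisible(x)
}

# Look up a year-indexed entry in a table that may be a named list or a
# named vector; returns NULL when absent instead of erroring.
lookup_year <- function(table, year) {
  key <- as.character(year)
  if (is.null(table)) return(NULL)
  if (is.list(table)) return(table[[key]])
  if (!(key %in% names(table))) return(NULL)
  unname(table[[key]])
}

# Run `expr` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
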
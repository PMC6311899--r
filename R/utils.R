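#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize gene symbols
#'
#' Symbols are compared case-insensitively throughout the package: every
#' reader and constructor upper-cases and trims identifiers on the way in.
#'
#' @param x character vector of gene symbols.
#' @param drop_empty drop entries that are empty after trimming.
#' @return upper-cased, trimmed character vector.
#' @keywords internal
normalize_symbols <- function(x, drop_empty = TRUE) {
  if (!is.character(x)) {
    stop("gene symbols must be character, got ", class(x)[1], call. = FALSE)
  }
  x <- toupper(trimws(x))
  if (drop_empty) x <- x[nzchar(x)]
  x
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
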
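#' Validate a table of scored protein-protein interactions
#'
#' Interactions follow the STRING convention: an undirected protein pair
#' plus an integer `combined_score` between 1 and 999 summarizing the
#' interaction confidence.  Self-interactions are rejected because a
#' signaling step must connect two distinct molecules.
#'
#' @param df data frame with columns `a`, `b`, `combined_score` (extra
#'   columns dropped; the first three columns are used if the names differ).
#' @return a validated `data.frame` with columns `a`, `b`,
#'   `combined_score`, symbols upper-cased.
#' @export
as_interactions <- function(df) {
  if (!is.data.frame(df) || ncol(df) < 3L) {
    stop("interactions must be a data frame with >= 3 columns", call. = FALSE)
  }
  if (!all(c("a", "b", "combined_score") %in% names(df))) {
    df <- df[, 1:3]
    names(df) <- c("a", "b", "combined_score")
  }
  out <- data.frame(
    a = normalize_symbols(as.character(df$a), drop_empty = FALSE),
    b = normalize_symbols(as.character(df$b), drop_empty = FALSE),
    combined_score = as.numeric(df$combined_score),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$a) | !nzchar(out$b))) {
    stopf("interaction row %d has an empty protein symbol",
          which(!nzchar(out$a) | !nzchar(out$b))[1])
  }
  if (anyNA(out$combined_score) ||
      any(out$combined_score != floor(out$combined_score))) {
    stopf("interaction row %d has a non-integer combined_score",
          which(is.na(out$combined_score) |
                  out$combined_score != floor(out$combined_score))[1])
  }
  out$combined_score <- as.integer(out$combined_score)
  if (any(out$combined_score < 1L | out$combined_score > 999L)) {
    stopf("interaction row %d has combined_score outside [1, 999]",
          which(out$combined_score < 1L | out$combined_score > 999L)[1])
  }
  if (any(out$a == out$b)) {
    stopf("interaction row %d is a self-interaction (%s)",
          which(out$a == out$b)[1], out$a[out$a == out$b][1])
  }
  rownames(out) <- NULL
  out
}

# Collapse duplicate unordered pairs to a single row keeping the maximum
# score and the first-seen orientation/order.
dedup_interactions <- function(interactions) {
  if (nrow(interactions) == 0L) return(interactions)
  key <- paste(pmin(interactions$a, interactions$b),
               pmax(interactions$a, interactions$b), sep = "\r")
  best <- tapply(interactions$combined_score, key, max)
  first <- !duplicated(key)
  out <- interactions[first, , drop = FALSE]
  out$combined_score <- as.integer(best[key[first]])
  rownames(out) <- NULL
  out
}

#' Filter interactions by confidence score
#'
#' Keeps high-confidence interactions (default `combined_score >= 700`,
#' the STRING "high confidence" band).  Duplicate records of the same
#' unordered pair are collapsed to a single row carrying the maximum score
#' before thresholding; input order is otherwise preserved.
#'
#' @param interactions interaction data frame (see [as_interactions()]).
#' @param min_score minimum `combined_score` to retain, in \[1, 999\].
#' @return filtered interaction data frame.
#' @examples
#' ppi <- as_interactions(data.frame(a = c("A", "A"), b = c("B", "C"),
#'                                   combined_score = c(700L, 699L)))
#' filter_interactions(ppi)          # keeps only A-B
#' @export
filter_interactions <- function(interactions, min_score = 700L) {
  interactions <- as_interactions(interactions)
  if (length(min_score) != 1L || is.na(min_score) ||
      min_score < 1 || min_score > 999) {
    stop("min_score must be a single value in [1, 999]", call. = FALSE)
  }
  interactions <- dedup_interactions(interactions)
  out <- interactions[interactions$combined_score >= min_score, ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two species' interaction sets into one namespace
#'
#' Interactions measured in two organisms are pooled on a shared symbol
#' namespace.  An optional one-to-one ortholog map translates the second
#' column's symbols to the first column's; without a map, identical
#' symbols are assumed orthologous.  A pair present in both inputs keeps
#' the larger of the two scores.  The result is returned in a canonical
#' sort order, which makes the operation symmetric in its two arguments.
#'
#' @param interactions_a,interactions_b interaction data frames.
#' @param ortholog_map optional two-column data frame (`symbol_a`,
#'   `symbol_b`); symbols found in either column are rewritten to the
#'   `symbol_a` form in both inputs.  Must be one-to-one.
#' @return merged interaction data frame, sorted by pair.
#' @export
merge_species <- function(interactions_a, interactions_b,
                          ortholog_map = NULL) {
  a <- as_interactions(interactions_a)
  b <- as_interactions(interactions_b)
  if (!is.null(ortholog_map)) {
    map <- validate_ortholog_map(ortholog_map)
    translate <- function(x) {
      hit <- match(x, map$symbol_b)
      x[!is.na(hit)] <- map$symbol_a[hit[!is.na(hit)]]
      x
    }
    a$a <- translate(a$a); a$b <- translate(a$b)
    b$a <- translate(b$a); b$b <- translate(b$b)
  }
  merged <- dedup_interactions(rbind(a, b))
  # canonical orientation + order so merge(x, y) == merge(y, x) elementwise
  swap <- merged$a > merged$b
  tmp <- merged$a[swap]; merged$a[swap] <- merged$b[swap]
  merged$b[swap] <- tmp
  merged <- merged[order(merged$a, merged$b), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

validate_ortholog_map <- function(ortholog_map) {
  if (!is.data.frame(ortholog_map) || ncol(ortholog_map) < 2L) {
    stop("ortholog map must be a two-column data frame", call. = FALSE)
  }
  map <- data.frame(
    symbol_a = normalize_symbols(as.character(ortholog_map[[1]]),
                                 drop_empty = FALSE),
    symbol_b = normalize_symbols(as.character(ortholog_map[[2]]),
                                 drop_empty = FALSE),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(map$symbol_a) || anyDuplicated(map$symbol_b)) {
    stop("mapping not one-to-one", call. = FALSE)
  }
  map
}
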
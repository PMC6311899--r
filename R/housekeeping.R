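#' Construct an expression panel
#'
#' A panel is a genes-by-samples matrix of `log2(FPKM + 1)`-scale values
#' over many tissues or cell types, used solely to identify housekeeping
#' genes.  Samples are treated as distinct unreplicated conditions.
#'
#' @param values numeric matrix, rownames = gene symbols, colnames =
#'   sample ids; all values finite and non-negative.
#' @return an `expression_panel` (the validated matrix).
#' @export
expression_panel <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("panel must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("panel needs gene rownames and sample colnames", call. = FALSE)
  }
  rownames(values) <- normalize_symbols(rownames(values),
                                        drop_empty = FALSE)
  if (anyDuplicated(rownames(values))) {
    stopf("duplicate gene symbol in panel: %s",
          rownames(values)[duplicated(rownames(values))][1])
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("panel values must be finite and >= 0", call. = FALSE)
  }
  if (ncol(values) < 2L) {
    stop("panel needs at least 2 samples", call. = FALSE)
  }
  structure(values, class = c("expression_panel", class(values)))
}

#' Genes expressed in one panel sample
#'
#' @param panel an [expression_panel()].
#' @param sample a sample id (column name).
#' @param cutoff expression cutoff on the `log2(FPKM + 1)` scale; a value
#'   equal to the cutoff counts as expressed. Default 1.5.
#' @return character vector of expressed gene symbols.
#' @export
expressed_in_sample <- function(panel, sample, cutoff = 1.5) {
  stopifnot(inherits(panel, "expression_panel"))
  if (!sample %in% colnames(panel)) {
    stopf("unknown sample id: %s", sample)
  }
  rownames(panel)[panel[, sample] >= cutoff]
}

#' Identify housekeeping genes from a multi-tissue panel
#'
#' A gene is designated housekeeping when it is expressed (value >=
#' `cutoff`) in at least the `prevalence` fraction of the panel's samples
#' — by default at least 75% of tissues/cell types at the
#' `log2(FPKM + 1) >= 1.5` cutoff.  Both comparisons are inclusive.
#'
#' @inheritParams expressed_in_sample
#' @param prevalence required fraction of samples, in (0, 1].
#' @return object of class `housekeeping_set`: list with `genes`
#'   (character) and `prevalence` (named numeric, observed fraction per
#'   member).
#' @export
identify_housekeeping <- function(panel, cutoff = 1.5, prevalence = 0.75) {
  stopifnot(inherits(panel, "expression_panel"))
  if (length(prevalence) != 1L || is.na(prevalence) ||
      prevalence <= 0 || prevalence > 1) {
    stop("prevalence must be in (0, 1]", call. = FALSE)
  }
  frac <- rowMeans(panel >= cutoff)
  keep <- frac >= prevalence
  structure(
    list(genes = rownames(panel)[keep], prevalence = frac[keep]),
    class = "housekeeping_set"
  )
}

#' Combine two housekeeping sets across species
#'
#' The per-species lists are merged into one unique background list,
#' optionally translating the second set through a one-to-one ortholog
#' map first (as in [merge_species()]).  The recorded prevalence of a
#' gene present in both sets is the larger of the two.
#'
#' @param set_a,set_b `housekeeping_set` objects.
#' @param ortholog_map optional two-column data frame (`symbol_a`,
#'   `symbol_b`).
#' @return combined `housekeeping_set`, genes sorted.
#' @export
combine_housekeeping <- function(set_a, set_b, ortholog_map = NULL) {
  stopifnot(inherits(set_a, "housekeeping_set"),
            inherits(set_b, "housekeeping_set"))
  translate <- identity
  if (!is.null(ortholog_map)) {
    map <- validate_ortholog_map(ortholog_map)
    translate <- function(x) {
      hit <- match(x, map$symbol_b)
      x[!is.na(hit)] <- map$symbol_a[hit[!is.na(hit)]]
      x
    }
  }
  ga <- translate(set_a$genes); gb <- translate(set_b$genes)
  pa <- stats::setNames(set_a$prevalence, ga)
  pb <- stats::setNames(set_b$prevalence, gb)
  genes <- sort(unique(c(ga, gb)))
  prev <- pmax(pa[genes], pb[genes], na.rm = TRUE)
  names(prev) <- genes
  structure(list(genes = genes, prevalence = prev),
            class = "housekeeping_set")
}

#' @export
print.housekeeping_set <- function(x, ...) {
  cat(sprintf("housekeeping set: %d genes\n", length(x$genes)))
  invisible(x)
}
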
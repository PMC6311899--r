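#' Build an expression profile
#'
#' A profile maps gene symbols to a single (replicate-averaged) log2-scale
#' expression value plus the cutoff separating expressed from silent
#' genes.  Genes absent from the profile are treated as not expressed by
#' all downstream operations.
#'
#' @param values named numeric vector (names = gene symbols), finite and
#'   non-negative.
#' @param cutoff expression cutoff on the log2 scale. Default 1.5.
#' @return an `expression_profile` object.
#' @export
expression_profile <- function(values, cutoff = 1.5) {
  if (!is.numeric(values) || is.null(names(values))) {
    stop("profile values must be a named numeric vector", call. = FALSE)
  }
  names(values) <- normalize_symbols(names(values), drop_empty = FALSE)
  if (anyDuplicated(names(values))) {
    stopf("duplicate gene symbol in profile: %s",
          names(values)[duplicated(names(values))][1])
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("profile values must be finite and >= 0", call. = FALSE)
  }
  structure(list(values = values, cutoff = cutoff),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression profile: %d genes, %d expressed at cutoff %.3g\n",
              length(x$values), sum(x$values >= x$cutoff), x$cutoff))
  invisible(x)
}

#' Average replicate columns into per-condition profiles
#'
#' Query RNA-seq matrices arrive as genes x replicate samples on a log2
#' RPKM/FPKM/CPM scale; the first processing step is the per-condition
#' arithmetic mean of each gene's replicates.
#'
#' @param mat numeric matrix, rownames = genes, colnames = samples.
#' @param groups either a named character vector `sample -> condition` or
#'   a two-column data frame (sample, condition).  Every column of `mat`
#'   must be assigned.
#' @param cutoff expression cutoff stored in each resulting profile.
#' @return named list of [expression_profile()]s, one per condition.
#' @export
average_replicates <- function(mat, groups, cutoff = 1.5) {
  if (!is.matrix(mat) || is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2]]),
                              as.character(groups[[1]]))
  }
  missing <- setdiff(colnames(mat), names(groups))
  if (length(missing)) {
    stopf("sample(s) missing from replicate grouping: %s",
          paste(missing, collapse = ", "))
  }
  cond <- groups[colnames(mat)]
  out <- lapply(split(seq_len(ncol(mat)), cond), function(idx) {
    expression_profile(rowMeans(mat[, idx, drop = FALSE]), cutoff = cutoff)
  })
  out[sort(names(out))]
}

#' Restrict the background to fully expressed paths
#'
#' A background path is *potential* for a profile when every one of its
#' member genes is expressed (profile value >= cutoff).  Genes absent
#' from the profile count as not expressed.  Receptors whose pathway
#' loses all paths are dropped.
#'
#' @param background a `pathway_background`.
#' @param profile an [expression_profile()].
#' @return filtered `pathway_background`.
#' @export
filter_potential_paths <- function(background, profile) {
  stopifnot(inherits(background, "pathway_background"),
            inherits(profile, "expression_profile"))
  if (nrow(background) == 0L) return(background)
  expressed <- names(profile$values)[profile$values >= profile$cutoff]
  keep <- vapply(path_nodes(background),
                 function(p) all(p %in% expressed), logical(1))
  out <- background[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pathway_background", "data.frame")
  out
}

#' Default high-expression threshold from the profile's density peak
#'
#' The activity score needs a "highly expressed" threshold; by default it
#' is taken at the peak (mode) of the expression distribution of the
#' *expressed* genes, located as the argmax of a Gaussian kernel density
#' estimate evaluated on a 512-point grid spanning the observed range
#' (bandwidth by Silverman's rule-of-thumb, the [stats::density()]
#' default).  Callers with knowledge of their data should override it
#' with an explicit value.
#'
#' @param profile an [expression_profile()].
#' @return a single number: the estimated density peak.
#' @export
default_high_threshold <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  x <- profile$values[profile$values >= profile$cutoff]
  if (length(x) < 10L) {
    stop(paste("fewer than 10 expressed genes; supply an explicit",
               "high_threshold"), call. = FALSE)
  }
  if (diff(range(x)) == 0) return(unname(x[1]))
  d <- stats::density(x, n = 512L, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Score pathway activity
#'
#' For each retained path i the proportion of active molecules is
#' `p_i = (#nodes with value >= high_threshold) / (#nodes)`; a pathway
#' with n retained paths (one per distinct downstream TF) gets the
#' activity score `A_s = sum(p_i) / n`, i.e. the mean active proportion
#' across its paths.  `A_s` lies in \[0, 1\] and reaches 1 only when every
#' member of every path is highly expressed.
#'
#' @param potential a `pathway_background` already filtered with
#'   [filter_potential_paths()].
#' @param profile the [expression_profile()] used for the filtering.
#' @param high_threshold the high-expression threshold (see
#'   [default_high_threshold()]).
#' @return object of class `pathway_activity`: data frame with columns
#'   `receptor`, `n` (number of retained paths = distinct downstream
#'   TFs), `activity_score`; attribute `"detail"` holds the per-path
#'   table (`receptor`, `path`, `terminal_tf`, `p`).
#' @export
pathway_activity <- function(potential, profile, high_threshold) {
  stopifnot(inherits(potential, "pathway_background"),
            inherits(profile, "expression_profile"))
  if (nrow(potential) == 0L) {
    out <- data.frame(receptor = character(), n = integer(),
                      activity_score = numeric(), stringsAsFactors = FALSE)
    attr(out, "detail") <- data.frame(
      receptor = character(), path = character(),
      terminal_tf = character(), p = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("pathway_activity", "data.frame")
    return(out)
  }
  vals <- profile$values
  p <- vapply(path_nodes(potential), function(nodes) {
    v <- vals[nodes]
    v[is.na(v)] <- 0
    mean(v >= high_threshold)
  }, numeric(1))
  detail <- data.frame(receptor = potential$receptor,
                       path = potential$path,
                       terminal_tf = potential$terminal_tf,
                       p = p, stringsAsFactors = FALSE)
  agg_n <- tapply(p, potential$receptor, length)
  agg_s <- tapply(p, potential$receptor, mean)
  out <- data.frame(receptor = names(agg_n),
                    n = as.integer(agg_n),
                    activity_score = as.numeric(agg_s),
                    stringsAsFactors = FALSE)
  out <- out[order(out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "detail") <- detail
  class(out) <- c("pathway_activity", "data.frame")
  out
}

#' Rank pathways by activity score
#'
#' Sorts by `A_s` descending, ties by `n` (downstream TF count)
#' descending, then receptor symbol ascending, and attaches a `rank`
#' column.  The (`n`, `A_s`) pair per receptor is the plotting table
#' used to display top-ranked active pathways in the upper positions.
#'
#' @param activities a [pathway_activity()] table.
#' @return the table sorted, with a leading `rank` column.
#' @export
rank_pathways <- function(activities) {
  stopifnot(inherits(activities, "pathway_activity"))
  detail <- attr(activities, "detail")
  ord <- order(-activities$activity_score, -activities$n,
               activities$receptor)
  out <- activities[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "detail") <- detail
  class(out) <- c("pathway_activity", "data.frame")
  out
}

#' Select the highly ranked active pathways
#'
#' A pathway counts as highly ranked when its activity score reaches the
#' `score_quantile` quantile of all pathway scores *and* it retains at
#' least `min_tfs` downstream TFs.  This is the selection used by the
#' permutation false-positive-rate assessment; both knobs are deliberate,
#' documented choices (no universal definition exists).
#'
#' @param activities a [pathway_activity()] table.
#' @param score_quantile quantile of `A_s` required, in (0, 1).
#' @param min_tfs minimum number of downstream TFs.
#' @param score_threshold optional absolute `A_s` bar overriding the
#'   quantile; used by [false_positive_rate()], which derives the bar
#'   from the original profile once and holds it fixed across
#'   permutations.
#' @return the selected subset, same class.
#' @export
select_high_ranked <- function(activities, score_quantile = 0.75,
                               min_tfs = 5L, score_threshold = NULL) {
  stopifnot(inherits(activities, "pathway_activity"))
  if (score_quantile <= 0 || score_quantile >= 1) {
    stop("score_quantile must be in (0, 1)", call. = FALSE)
  }
  if (nrow(activities) == 0L) return(activities)
  q <- score_threshold %||%
    stats::quantile(activities$activity_score, score_quantile,
                    names = FALSE)
  out <- activities[activities$activity_score >= q &
                      activities$n >= min_tfs, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "detail") <- attr(activities, "detail")
  class(out) <- c("pathway_activity", "data.frame")
  out
}
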
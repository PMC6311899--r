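#' Permute gene labels against expression values
#'
#' Randomly reassigns the profile's expression values among its gene
#' symbols, conserving the value multiset exactly.  The permutation is a
#' deterministic function of `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param profile an [expression_profile()].
#' @param seed integer seed driving the permutation.
#' @return a permuted `expression_profile` over the same genes.
#' @export
permute_profile <- function(profile, seed) {
  stopifnot(inherits(profile, "expression_profile"))
  v <- profile$values
  perm <- with_seed(seed, sample.int(length(v)))
  expression_profile(stats::setNames(unname(v)[perm], names(v)),
                     cutoff = profile$cutoff)
}

count_high_ranked <- function(background, profile, high_threshold = NULL,
                              score_quantile = 0.75, min_tfs = 5L,
                              score_threshold = NULL) {
  potential <- filter_potential_paths(background, profile)
  if (nrow(potential) == 0L) return(list(n = 0L, bar = NA_real_))
  ht <- high_threshold %||% default_high_threshold(profile)
  act <- pathway_activity(potential, profile, ht)
  sel <- select_high_ranked(act, score_quantile = score_quantile,
                            min_tfs = min_tfs,
                            score_threshold = score_threshold)
  list(n = nrow(sel),
       bar = score_threshold %||%
         stats::quantile(act$activity_score, score_quantile,
                         names = FALSE))
}

#' Permutation-based false-positive-rate estimate
#'
#' Runs the full scoring pipeline (potential-path filter, high-expression
#' threshold, activity scoring, high-ranked selection) on the original
#' profile and on `repetitions` label-permuted copies.  Each repetition's
#' false-positive ratio is the permuted high-ranked count divided by the
#' original count; the reported rate is their mean.
#'
#' The calling rule is *fixed from the original sample*: the `A_s`
#' selection bar is the `score_quantile` quantile of the original
#' profile's pathway scores, and permuted profiles are counted against
#' that same absolute bar (together with the `min_tfs` requirement).
#' Re-deriving a relative quantile inside each permuted dataset would
#' select a fixed fraction of pathways by construction and pin the
#' apparent FPR near 1 regardless of signal, which would make the
#' assessment meaningless.  The high-expression threshold is likewise
#' recomputed per profile, which leaves it unchanged under permutation
#' because the value multiset is conserved.  Ratios can exceed 1; no
#' capping is applied.
#'
#' @param background a `pathway_background`.
#' @param profile the original [expression_profile()].
#' @param repetitions number of permutations (default 10).
#' @param seed master integer seed; repetition i uses `seed + i`.
#' @param score_quantile,min_tfs high-ranked selection parameters, see
#'   [select_high_ranked()].
#' @param high_threshold optional explicit threshold (otherwise
#'   [default_high_threshold()] per profile).
#' @param permute_fun the permutation function; replaceable by a test
#'   hook such as `function(p, seed) p` (identity).
#' @return object of class `fpr_result`: list with `n_high_original`,
#'   `n_high_permuted` (integer vector), `ratios`, `mean_fpr`,
#'   `score_bar` (the fixed `A_s` bar), `seeds`.
#' @export
false_positive_rate <- function(background, profile, repetitions = 10L,
                                seed = 1L, score_quantile = 0.75,
                                min_tfs = 5L, high_threshold = NULL,
                                permute_fun = permute_profile) {
  stopifnot(repetitions >= 1L)
  orig <- count_high_ranked(background, profile, high_threshold,
                            score_quantile, min_tfs)
  if (orig$n == 0L) {
    stop("FPR undefined (division by zero): no high-ranked pathway in the original profile",
         call. = FALSE)
  }
  seeds <- as.integer(seed) + seq_len(repetitions)
  n_perm <- vapply(seeds, function(s) {
    count_high_ranked(background, permute_fun(profile, s), high_threshold,
                      score_quantile, min_tfs,
                      score_threshold = orig$bar)$n
  }, integer(1))
  ratios <- n_perm / orig$n
  structure(
    list(n_high_original = orig$n, n_high_permuted = n_perm,
         ratios = ratios, mean_fpr = mean(ratios),
         score_bar = as.numeric(orig$bar), seeds = seeds),
    class = "fpr_result"
  )
}

#' @export
print.fpr_result <- function(x, ...) {
  cat(sprintf(
    "false-positive rate: mean %.3f over %d permutations (original high-ranked: %d)\n",
    x$mean_fpr, length(x$ratios), x$n_high_original))
  invisible(x)
}
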
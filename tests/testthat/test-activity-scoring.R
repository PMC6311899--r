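test_that("replicate averaging is the per-condition arithmetic mean", {
  mat <- matrix(c(2, 4, 1,
                  0, 1, 5), nrow = 2, byrow = TRUE,
                dimnames = list(c("G1", "G2"), c("A1", "A2", "B1")))
  groups <- c(A1 = "A", A2 = "A", B1 = "B")
  profs <- average_replicates(mat, groups)
  expect_equal(profs$A$values, c(G1 = 3, G2 = 0.5))
  expect_equal(profs$B$values, c(G1 = 1, G2 = 5))   # single replicate

  expect_error(average_replicates(mat, c(A1 = "A", A2 = "A")),
               "missing from replicate grouping")

  # several conditions vs per-column brute force
  set.seed(3)
  big <- matrix(runif(60, 0, 8), nrow = 5,
                dimnames = list(sprintf("G%d", 1:5),
                                sprintf("S%d", 1:12)))
  grp <- setNames(rep(c("X", "Y", "Z"), each = 4), colnames(big))
  profs <- average_replicates(big, grp)
  expect_identical(names(profs), c("X", "Y", "Z"))
  for (cond in names(profs)) {
    idx <- names(grp)[grp == cond]
    brute <- apply(big[, idx], 1, function(r) sum(r) / length(r))
    expect_equal(profs[[cond]]$values, brute)
    expect_identical(names(profs[[cond]]$values), rownames(big))
  }
})

test_that("potential-path filtering keeps only fully expressed paths (T1 + E1)", {
  bg <- shortest_rk_tf_paths(toy_graph())
  pot <- filter_potential_paths(bg, toy_profile())
  # TF2 (1.0) and R2 (0.5) fall below the 1.5 cutoff, leaving one path
  expect_identical(pot$path, "R1>K1>TF1")

  full <- expression_profile(
    setNames(rep(5, 6), c("R1", "R2", "K1", "K2", "TF1", "TF2")))
  expect_identical(filter_potential_paths(bg, full)$path, bg$path)

  empty <- expression_profile(c(ZZZ = 9))
  expect_identical(nrow(filter_potential_paths(bg, empty)), 0L)

  # genes absent from the profile count as not expressed
  partial <- expression_profile(c(R1 = 5, K1 = 5))
  expect_identical(nrow(filter_potential_paths(bg, partial)), 0L)
})

test_that("default high threshold sits at the KDE peak of expressed genes", {
  set.seed(1)
  vals <- c(rnorm(200, 4.0, 0.15), runif(30, 1.6, 8))
  vals <- pmax(0, vals)
  prof <- expression_profile(setNames(vals, sprintf("G%d", seq_along(vals))))
  got <- default_high_threshold(prof)
  # brute-force argmax of the same KDE on a 10x finer grid
  x <- vals[vals >= prof$cutoff]
  fine <- stats::density(x, n = 5120L, from = min(x), to = max(x))
  want <- fine$x[which.max(fine$y)]
  grid_step <- diff(range(x)) / 511
  expect_lt(abs(got - want), grid_step + 1e-12)
  expect_lt(abs(got - 4.0), 0.25)

  same <- expression_profile(setNames(rep(3, 12), sprintf("G%d", 1:12)))
  expect_identical(default_high_threshold(same), 3)

  few <- expression_profile(setNames(rep(3, 5), sprintf("G%d", 1:5)))
  expect_error(default_high_threshold(few), "fewer than 10 expressed")
})

test_that("activity score is the mean active proportion across paths", {
  bg <- shortest_rk_tf_paths(toy_graph())
  prof <- toy_profile()
  pot <- filter_potential_paths(bg, prof)
  act <- pathway_activity(pot, prof, high_threshold = 4.5)
  expect_identical(act$receptor, "R1")
  expect_identical(act$n, 1L)
  expect_equal(act$activity_score, 2 / 3)   # R1=5, TF1=6 active; K1=4 not
  expect_equal(attr(act, "detail")$p, 2 / 3)

  # two paths with p = 1.0 (3/3) and 0.5 (2/4) average to 0.75
  roles <- load_molecule_roles("R1", c("KA", "KB"), c("T1", "T2"))
  ppi <- as_interactions(data.frame(
    a = c("R1", "KA", "KA", "KB"), b = c("KA", "T1", "KB", "T2"),
    combined_score = c(900L, 900L, 900L, 900L)))
  bg2 <- shortest_rk_tf_paths(build_signaling_graph(ppi, roles))
  prof2 <- expression_profile(c(R1 = 9, KA = 9, T1 = 9, KB = 2, T2 = 2))
  act2 <- pathway_activity(bg2, prof2, high_threshold = 5)
  expect_identical(act2$n, 2L)
  expect_equal(act2$activity_score, 0.75)
  expect_equal(sort(attr(act2, "detail")$p), c(0.5, 1.0))

  # nothing above threshold: every p_i and A_s is zero
  act3 <- pathway_activity(bg2, prof2, high_threshold = 99)
  expect_equal(act3$activity_score, 0)
  expect_equal(attr(act3, "detail")$p, c(0, 0))
})

test_that("A_s respects its bounds and n counts distinct TFs", {
  for (s in 1:8) {
    spec <- synthetic_spec(n_receptors = 6L, n_kinases = 12L, n_tfs = 8L,
                           n_planted = 1L, routes_per_planted = 5L,
                           seed = s)
    run <- run_synthetic_ranking(spec)
    act <- run$ranked
    expect_true(all(act$activity_score >= 0 & act$activity_score <= 1))
    detail <- attr(act, "detail")
    expect_true(all(detail$p >= 0 & detail$p <= 1))
    ntfs <- tapply(detail$terminal_tf, detail$receptor,
                   function(x) length(unique(x)))
    expect_identical(act$n[order(act$receptor)],
                     as.integer(ntfs[sort(act$receptor)]))
    expect_equal(act$activity_score,
                 as.numeric(tapply(detail$p, detail$receptor, mean)[
                   act$receptor]))
  }
})

test_that("ranking sorts by score, then TF count, then symbol", {
  act <- structure(
    data.frame(receptor = c("Z", "X", "Y"),
               n = c(9L, 5L, 2L),
               activity_score = c(0.3, 0.9, 0.9),
               stringsAsFactors = FALSE),
    class = c("pathway_activity", "data.frame"))
  ranked <- rank_pathways(act)
  expect_identical(ranked$receptor, c("X", "Y", "Z"))
  expect_identical(ranked$rank, 1:3)

  # brute-force comparator sort on random tables
  for (s in 1:5) {
    set.seed(s)
    n <- 12
    tab <- structure(
      data.frame(receptor = sample(sprintf("R%02d", 1:n)),
                 n = sample(1:6, n, replace = TRUE),
                 activity_score = sample(seq(0, 1, 0.25), n,
                                         replace = TRUE),
               stringsAsFactors = FALSE),
      class = c("pathway_activity", "data.frame"))
    ranked <- rank_pathways(tab)
    better <- function(i, j) {
      if (ranked$activity_score[i] != ranked$activity_score[j])
        ranked$activity_score[i] > ranked$activity_score[j]
      else if (ranked$n[i] != ranked$n[j]) ranked$n[i] > ranked$n[j]
      else ranked$receptor[i] < ranked$receptor[j]
    }
    for (i in seq_len(n - 1)) expect_true(better(i, i + 1))
  }

  empty <- structure(
    data.frame(receptor = character(), n = integer(),
               activity_score = numeric(), stringsAsFactors = FALSE),
    class = c("pathway_activity", "data.frame"))
  expect_identical(nrow(rank_pathways(empty)), 0L)
  one <- structure(
    data.frame(receptor = "R", n = 1L, activity_score = 0.5,
               stringsAsFactors = FALSE),
    class = c("pathway_activity", "data.frame"))
  expect_identical(rank_pathways(one)$rank, 1L)
})

test_that("high-ranked selection equals the stated two-predicate filter", {
  mk <- function(df) structure(df, class = c("pathway_activity",
                                             "data.frame"))
  same <- mk(data.frame(receptor = sprintf("R%d", 1:4),
                        n = c(7L, 4L, 9L, 5L),
                        activity_score = rep(0.6, 4),
                        stringsAsFactors = FALSE))
  got <- select_high_ranked(same)
  expect_identical(got$receptor, c("R1", "R3", "R4"))  # all with n >= 5

  one <- mk(data.frame(receptor = "R", n = 6L, activity_score = 0.2,
                       stringsAsFactors = FALSE))
  expect_identical(nrow(select_high_ranked(one)), 1L)

  for (s in 1:5) {
    set.seed(s)
    tab <- mk(data.frame(receptor = sprintf("R%02d", 1:15),
                         n = sample(1:10, 15, replace = TRUE),
                         activity_score = round(runif(15), 3),
                         stringsAsFactors = FALSE))
    got <- select_high_ranked(tab, score_quantile = 0.6, min_tfs = 4L)
    thr <- quantile(tab$activity_score, 0.6, names = FALSE)
    want <- tab[tab$activity_score >= thr & tab$n >= 4L, ]
    expect_identical(got$receptor, want$receptor)
  }
  expect_error(select_high_ranked(same, score_quantile = 1), "quantile")
})

test_that("scoring is monotone in cutoff and high threshold", {
  spec <- synthetic_spec(seed = 5)
  run <- run_synthetic_ranking(spec)
  bg <- run$background
  vals <- run$profile$values

  kept <- vapply(c(0.5, 1.5, 3, 5), function(cut) {
    nrow(filter_potential_paths(bg, expression_profile(vals, cutoff = cut)))
  }, 0L)
  expect_true(all(diff(kept) <= 0L))

  pot <- filter_potential_paths(bg, run$profile)
  scores <- lapply(c(2, 4, 6, 8), function(ht) {
    pathway_activity(pot, run$profile, ht)$activity_score
  })
  for (i in seq_len(length(scores) - 1)) {
    expect_true(all(scores[[i + 1]] <= scores[[i]]))
  }
})

test_that("scores are invariant to input row order", {
  spec <- synthetic_spec(n_receptors = 6L, n_kinases = 10L, n_tfs = 8L,
                         n_planted = 1L, routes_per_planted = 5L, seed = 2)
  run <- run_synthetic_ranking(spec)
  pot <- filter_potential_paths(run$background, run$profile)
  base <- pathway_activity(pot, run$profile, 5)
  set.seed(1)
  shuf_bg <- pot[sample(nrow(pot)), ]
  class(shuf_bg) <- c("pathway_background", "data.frame")
  v <- run$profile$values
  shuf_prof <- expression_profile(v[sample(length(v))],
                                  cutoff = run$profile$cutoff)
  redo <- pathway_activity(shuf_bg, shuf_prof, 5)
  expect_equal(base$receptor, redo$receptor)
  expect_equal(base$activity_score, redo$activity_score)
})
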
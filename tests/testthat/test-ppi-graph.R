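test_that("role lists are cleaned, case-normalized and may overlap", {
  roles <- load_molecule_roles(c("R1", "R2"), c("K1", "K2"),
                               c("TF1", "TF2"))
  expect_length(unique(unlist(roles[c("receptors", "kinases", "tfs")])), 6L)

  roles <- load_molecule_roles(c("egfr"), c("EGFR", "MAPK1"), c("JUN"))
  expect_true("EGFR" %in% roles$receptors && "EGFR" %in% roles$kinases)

  expect_error(load_molecule_roles(character(0), "K1", "TF1"),
               "receptor list empty")
  expect_error(load_molecule_roles(c("  ", ""), "K1", "TF1"),
               "receptor list empty")
  expect_error(load_molecule_roles(list(1L), "K1", "TF1"),
               "not a character")
})

test_that("interaction validation rejects malformed records", {
  expect_error(as_interactions(data.frame(a = "A", b = "A",
                                          combined_score = 500L)),
               "self-interaction")
  expect_error(as_interactions(data.frame(a = "A", b = "B",
                                          combined_score = 1000L)),
               "outside \\[1, 999\\]")
  expect_error(as_interactions(data.frame(a = "A", b = "B",
                                          combined_score = 0L)),
               "outside \\[1, 999\\]")
})

test_that("score filtering keeps the boundary, collapses duplicates, is idempotent", {
  ppi <- as_interactions(data.frame(
    a = c("A", "A"), b = c("B", "C"), combined_score = c(700L, 699L)))
  kept <- filter_interactions(ppi, 700L)
  expect_identical(kept$b, "B")

  expect_identical(formals(filter_interactions)$min_score, 700L)

  dup <- as_interactions(data.frame(a = c("A", "B"), b = c("B", "A"),
                                    combined_score = c(800L, 750L)))
  got <- filter_interactions(dup, 700L)
  expect_identical(got, as_interactions(
    data.frame(a = "A", b = "B", combined_score = 800L)))

  expect_error(filter_interactions(ppi, 0), "min_score")
  expect_error(filter_interactions(ppi, 1000), "min_score")

  for (s in 1:5) {
    net <- random_role_network(s)
    once <- filter_interactions(net$interactions, 400L)
    expect_identical(filter_interactions(once, 400L), once)
  }
})

test_that("species merge takes the larger score and is commutative", {
  x <- as_interactions(data.frame(a = "A", b = "B", combined_score = 800L))
  y <- as_interactions(data.frame(a = "A", b = "B", combined_score = 750L))
  expect_identical(merge_species(x, y)$combined_score, 800L)

  z <- as_interactions(data.frame(a = "C", b = "D", combined_score = 900L))
  expect_identical(nrow(merge_species(x, z)), 2L)

  for (s in 1:10) {
    set.seed(s)
    mk <- function() {
      n <- sample(1:6, 1)
      pairs <- t(utils::combn(LETTERS[1:5], 2))
      idx <- sample(nrow(pairs), n, replace = TRUE)
      as_interactions(data.frame(
        a = pairs[idx, 1], b = pairs[idx, 2],
        combined_score = sample(1:999, n, replace = TRUE)))
    }
    u <- mk(); v <- mk()
    expect_identical(merge_species(u, v), merge_species(v, u))
    expect_identical(merge_species(u, u), merge_species(u, u[1:0, ]))
  }

  bad_map <- data.frame(symbol_a = c("A", "B"), symbol_b = c("X", "X"))
  expect_error(merge_species(x, y, bad_map), "not one-to-one")

  map <- data.frame(symbol_a = c("A", "B"), symbol_b = c("AA", "BB"))
  w <- as_interactions(data.frame(a = "AA", b = "BB",
                                  combined_score = 900L))
  got <- merge_species(x, w, map)
  expect_identical(got, as_interactions(
    data.frame(a = "A", b = "B", combined_score = 900L)))
})

test_that("graph construction applies the category and weight rules (toy T1)", {
  g <- toy_graph()
  expect_identical(
    g$edges,
    data.frame(
      from = c("K1", "K1", "K2", "K2", "R1", "R2"),
      to = c("K2", "TF1", "K1", "TF2", "K1", "R1"),
      category = c("KK", "KT", "KK", "KT", "RK", "RR"),
      weight = c(250L, 200L, 250L, 100L, 100L, 280L),
      stringsAsFactors = FALSE))
  expect_identical(unname(g$discarded), c(0L, 0L))
})

test_that("inadmissible interactions are dropped and tallied", {
  roles <- toy_roles()
  # TF-TF: no category; TF can never source and TF targets need a K source
  g <- build_signaling_graph(
    as_interactions(data.frame(a = "TF1", b = "TF2",
                               combined_score = 900L)), roles)
  expect_identical(nrow(g$edges), 0L)
  expect_identical(g$discarded[["no_category"]], 1L)

  # unknown symbol
  g2 <- build_signaling_graph(
    as_interactions(data.frame(a = "R1", b = "XYZ",
                               combined_score = 900L)), roles)
  expect_identical(g2$discarded[["unknown_role"]], 1L)

  # R-R between two kinase-connected receptors: no admissible category
  ppi <- as_interactions(data.frame(
    a = c("R1", "R2", "R1"), b = c("K1", "K1", "R2"),
    combined_score = c(900L, 900L, 800L)))
  g3 <- build_signaling_graph(ppi, roles)
  expect_false(any(g3$edges$category == "RR"))
  expect_identical(g3$discarded[["no_category"]], 1L)
})

test_that("weights are 1000 - combined_score and edges obey the category table", {
  g <- build_signaling_graph(
    as_interactions(data.frame(a = "R1", b = "K1",
                               combined_score = 999L)), toy_roles())
  expect_identical(g$edges$weight, 1L)

  for (s in 1:10) {
    net <- random_role_network(s)
    g <- build_signaling_graph(net$interactions, net$roles)
    expect_true(all(g$edges$weight >= 1L & g$edges$weight <= 999L))
    expect_true(all((1000L - g$edges$weight) %in%
                      net$interactions$combined_score))
    roles <- net$roles
    cat_roles <- list(RR = c("R", "R"), RK = c("R", "K"),
                      KK = c("K", "K"), KT = c("K", "TF"))
    for (i in seq_len(nrow(g$edges))) {
      rr <- cat_roles[[g$edges$category[i]]]
      src_set <- switch(rr[1], R = roles$receptors, K = roles$kinases)
      dst_set <- switch(rr[2], R = roles$receptors, K = roles$kinases,
                        TF = roles$tfs)
      expect_true(g$edges$from[i] %in% src_set)
      expect_true(g$edges$to[i] %in% dst_set)
    }
    expect_false(any(g$edges$from %in%
                       setdiff(roles$tfs,
                               c(roles$receptors, roles$kinases))))
  }
})

test_that("graph construction is invariant to interaction order", {
  for (s in 1:5) {
    net <- random_role_network(s)
    g1 <- build_signaling_graph(net$interactions, net$roles)
    set.seed(s + 1000)
    shuffled <- net$interactions[sample(nrow(net$interactions)), ]
    g2 <- build_signaling_graph(shuffled, net$roles)
    expect_identical(g1$edges, g2$edges)
  }
})
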
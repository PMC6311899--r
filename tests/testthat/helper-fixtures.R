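# Shared fixtures and independent oracles, built in code (no data files).

toy_roles <- function() {
  load_molecule_roles(c("R1", "R2"), c("K1", "K2"), c("TF1", "TF2"))
}

toy_ppi <- function() {
  as_interactions(data.frame(
    a = c("R2", "R1", "K1", "K1", "K2"),
    b = c("R1", "K1", "K2", "TF1", "TF2"),
    combined_score = c(720L, 900L, 750L, 800L, 900L),
    stringsAsFactors = FALSE))
}

toy_graph <- function() build_signaling_graph(toy_ppi(), toy_roles())

toy_profile <- function() {
  expression_profile(c(R1 = 5, K1 = 4, K2 = 2, TF1 = 6, TF2 = 1.0,
                       R2 = 0.5), cutoff = 1.5)
}

# Random role-labelled interaction set (<= 30 nodes), with occasional
# multi-role symbols, for property and oracle tests.
random_role_network <- function(seed, overlap = 0.15) {
  set.seed(seed)
  nr <- sample(3:6, 1); nk <- sample(6:12, 1); nt <- sample(4:8, 1)
  R <- sprintf("R%d", seq_len(nr))
  K <- sprintf("K%d", seq_len(nk))
  TFs <- sprintf("T%d", seq_len(nt))
  if (stats::runif(1) < overlap) R <- c(R, sample(K, 1))
  if (stats::runif(1) < overlap) TFs <- c(TFs, sample(K, 1))
  roles <- load_molecule_roles(R, K, TFs)
  syms <- unique(c(R, K, TFs))
  pairs <- t(utils::combn(syms, 2))
  keep <- stats::runif(nrow(pairs)) < 0.15
  if (!any(keep)) keep[1] <- TRUE
  ppi <- as_interactions(data.frame(
    a = pairs[keep, 1], b = pairs[keep, 2],
    combined_score = sample(1:999, sum(keep), replace = TRUE),
    stringsAsFactors = FALSE))
  list(interactions = ppi, roles = roles)
}

# ---- independent path oracle -------------------------------------------
# Exhaustively enumerates every constraint-satisfying simple path by plain
# recursion over the edge table, then keeps the minimum-weight
# (lexicographically smallest) path per (receptor, TF) pair.  Shares no
# machinery with shortest_rk_tf_paths().

oracle_background <- function(graph, max_nodes = 7, max_r = 2, max_k = 5) {
  ed <- graph$edges
  src_role <- c(RR = "R", RK = "R", KK = "K", KT = "K")[ed$category]
  dst_role <- c(RR = "R", RK = "K", KK = "K", KT = "TF")[ed$category]
  found <- list()
  record <- function(nodes, roles, weight) {
    nr <- sum(roles == "R"); nk <- sum(roles == "K")
    if (length(nodes) < 3 || length(nodes) > max_nodes) return()
    if (nr < 1 || nr > max_r || nk < 1 || nk > max_k) return()
    if (roles[length(roles)] != "TF") return()
    key <- paste(nodes[1], nodes[length(nodes)])
    cand <- list(nodes = nodes, weight = weight,
                 cmp = paste(nodes, collapse = "\r"))
    cur <- found[[key]]
    if (is.null(cur) || cand$weight < cur$weight ||
        (cand$weight == cur$weight && cand$cmp < cur$cmp)) {
      found[[key]] <<- cand
    }
  }
  grow <- function(nodes, roles, weight) {
    if (length(nodes) >= max_nodes) return()
    cur <- nodes[length(nodes)]
    role <- roles[length(roles)]
    idx <- which(ed$from == cur & src_role == role)
    for (i in idx) {
      nxt <- ed$to[i]
      if (nxt %in% nodes) next
      nroles <- c(roles, dst_role[i])
      nnodes <- c(nodes, nxt)
      nw <- weight + ed$weight[i]
      if (dst_role[i] == "TF") record(nnodes, nroles, nw)
      else grow(nnodes, nroles, nw)
    }
  }
  for (r in intersect(graph$roles$receptors, unique(ed$from))) {
    grow(r, "R", 0L)
  }
  if (length(found) == 0) return(empty_df_background())
  rows <- do.call(rbind, lapply(found, function(x) {
    data.frame(receptor = x$nodes[1],
               path = paste(x$nodes, collapse = ">"),
               total_weight = x$weight,
               terminal_tf = x$nodes[length(x$nodes)],
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$receptor, rows$terminal_tf), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

empty_df_background <- function() {
  data.frame(receptor = character(), path = character(),
             total_weight = integer(), terminal_tf = character(),
             stringsAsFactors = FALSE)
}

# comparable plain-data view of a pathway_background
background_core <- function(bg) {
  out <- as.data.frame(bg)[, c("receptor", "path", "total_weight",
                               "terminal_tf")]
  out <- out[order(out$receptor, out$terminal_tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# midpoint high-expression threshold for the synthetic world: above the
# bystander peak, below the active class (see the methods vignette)
synthetic_high_threshold <- function(spec) {
  (spec$expressed_mean + spec$active_mean) / 2
}

run_synthetic_ranking <- function(spec) {
  net <- generate_network(spec)
  graph <- build_signaling_graph(filter_interactions(net$interactions),
                                 net$roles)
  bg <- shortest_rk_tf_paths(graph)
  expr <- generate_expression(net, spec)
  profile <- average_replicates(expr$matrix, expr$groups)[[1]]
  potential <- filter_potential_paths(bg, profile)
  act <- pathway_activity(potential, profile, synthetic_high_threshold(spec))
  list(network = net, background = bg, profile = profile,
       ranked = rank_pathways(act))
}
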
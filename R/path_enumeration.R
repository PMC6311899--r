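#' Enumerate shortest complete receptor-to-TF signaling paths
#'
#' For every (receptor, transcription factor) pair the function returns at
#' most one *complete path*: a simple node chain following the role
#' pattern `R` (optionally preceded by one bridging `R`) then one or more
#' `K` layers then a single terminal `TF`, minimizing the summed edge
#' weight (`1000 - combined_score`).  The collection of paths rooted at
#' one receptor constitutes that receptor's pathway; the full map is the
#' background pathway data scored later against expression profiles.
#'
#' Two search modes are offered:
#'
#' * `"layered"` (default) — an exact hop- and layer-bounded Dijkstra-type
#'   dynamic program: the returned path is the cheapest path that
#'   *satisfies* the length/layer constraints (at most `max_nodes` nodes,
#'   `max_r_layers` leading receptors, `max_k_layers` kinases, one TF).
#' * `"two-step"` — the literal two-stage procedure: take the globally
#'   cheapest path ignoring the length budget, then discard the
#'   (receptor, TF) pair if that path violates the constraints.  This can
#'   drop pairs for which a slightly costlier but valid route exists.
#'
#' Ties in total weight are broken by the lexicographically smallest node
#' sequence, which makes the output independent of input ordering.
#'
#' @param graph a [build_signaling_graph()] object.
#' @param max_nodes maximum nodes per path (complete paths have 3 to
#'   `max_nodes` nodes).
#' @param max_r_layers maximum leading receptor layers.
#' @param max_k_layers maximum kinase layers.
#' @param mode `"layered"` or `"two-step"`, see above.
#' @return object of class `pathway_background`: a data frame with one
#'   row per retained (receptor, TF) pair and columns `receptor`, `path`
#'   (`>`-joined node chain), `roles` (`>`-joined role letters),
#'   `total_weight`, `terminal_tf`.
#' @export
shortest_rk_tf_paths <- function(graph, max_nodes = 7L, max_r_layers = 2L,
                                 max_k_layers = 5L,
                                 mode = c("layered", "two-step")) {
  stopifnot(inherits(graph, "signaling_graph"))
  mode <- match.arg(mode)
  if (max_nodes < 3L) stop("max_nodes must be >= 3", call. = FALSE)

  nodes <- graph_nodes(graph)
  N <- length(nodes)
  if (N == 0L) return(empty_background())
  ed <- graph$edges
  ed$from_i <- match(ed$from, nodes)
  ed$to_i <- match(ed$to, nodes)
  by_cat <- split(ed, ed$category)
  for (cat in c("RR", "RK", "KK", "KT")) {
    if (is.null(by_cat[[cat]])) {
      by_cat[[cat]] <- ed[0, , drop = FALSE]
    }
  }

  H <- if (mode == "layered") max_nodes - 1L else max(N - 1L, 2L)
  rmax <- if (mode == "layered") max_r_layers else 2L
  kmax <- if (mode == "layered") max_k_layers else H

  tf_targets <- intersect(unique(by_cat$KT$to), graph$roles$tfs)
  receptors <- intersect(nodes,
                         unique(c(by_cat$RK$from, by_cat$RR$from)))
  receptors <- intersect(receptors, graph$roles$receptors)
  if (length(tf_targets) == 0L || length(receptors) == 0L) {
    return(empty_background())
  }

  rows <- list()
  for (t in sort(tf_targets)) {
    dp <- backward_dp(t, nodes, by_cat, H, rmax)
    for (r in sort(receptors)) {
      if (r == t) next
      ri <- match(r, nodes)
      cand <- dp_candidates(dp, ri, H, rmax, kmax, max_nodes, mode)
      if (nrow(cand) == 0L) next
      res <- reconstruct_path(dp, cand, r, t, nodes, by_cat)
      if (anyDuplicated(res$nodes)) {
        # a multi-role node was reused along the cheapest walk; fall back
        # to an exact simple-path search for this pair
        res <- best_simple_path(r, t, nodes, by_cat,
                                if (mode == "layered") max_nodes else N,
                                rmax, kmax)
        if (is.null(res)) next
      }
      if (mode == "two-step" &&
          !validate_path(res$nodes, res$roles, max_nodes = max_nodes,
                         max_r_layers = max_r_layers,
                         max_k_layers = max_k_layers)) {
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        receptor = r,
        path = paste(res$nodes, collapse = ">"),
        roles = paste(res$roles, collapse = ">"),
        total_weight = as.integer(res$weight),
        terminal_tf = t,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_background())
  out <- do.call(rbind, rows)
  out <- out[order(out$receptor, out$terminal_tf), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pathway_background", "data.frame")
  out
}

empty_background <- function() {
  out <- data.frame(receptor = character(), path = character(),
                    roles = character(), total_weight = integer(),
                    terminal_tf = character(), stringsAsFactors = FALSE)
  class(out) <- c("pathway_background", "data.frame")
  out
}

# Backward dynamic program from terminal TF `t` over walk states.
# B_K[h, v]        : min weight of a K...K>TF suffix from v (as kinase), h edges
# B_R[[rs]][h, v]  : min weight suffix from v (as receptor) containing rs
#                    receptor-role nodes in total (v included)
backward_dp <- function(t, nodes, by_cat, H, rmax) {
  N <- length(nodes)
  ti <- match(t, nodes)
  B_K <- matrix(Inf, nrow = H, ncol = N)
  kt <- by_cat$KT[by_cat$KT$to_i == ti, , drop = FALSE]
  if (nrow(kt)) B_K[1, kt$from_i] <- kt$weight
  kk <- by_cat$KK
  if (H >= 2L && nrow(kk)) {
    for (h in 2:H) {
      cand <- kk$weight + B_K[h - 1L, kk$to_i]
      fin <- is.finite(cand)
      if (any(fin)) {
        agg <- tapply(cand[fin], kk$from_i[fin], min)
        B_K[h, as.integer(names(agg))] <- as.numeric(agg)
      }
    }
  }
  B_R <- vector("list", rmax)
  rk <- by_cat$RK
  B1 <- matrix(Inf, nrow = H, ncol = N)
  if (H >= 2L && nrow(rk)) {
    for (h in 2:H) {
      cand <- rk$weight + B_K[h - 1L, rk$to_i]
      fin <- is.finite(cand)
      if (any(fin)) {
        agg <- tapply(cand[fin], rk$from_i[fin], min)
        B1[h, as.integer(names(agg))] <- as.numeric(agg)
      }
    }
  }
  B_R[[1]] <- B1
  rr <- by_cat$RR
  if (rmax >= 2L) {
    for (rs in 2:rmax) {
      Bp <- matrix(Inf, nrow = H, ncol = N)
      if (nrow(rr)) {
        for (h in seq_len(H)[-1]) {
          cand <- rr$weight + B_R[[rs - 1L]][h - 1L, rr$to_i]
          fin <- is.finite(cand)
          if (any(fin)) {
            agg <- tapply(cand[fin], rr$from_i[fin], min)
            Bp[h, as.integer(names(agg))] <- as.numeric(agg)
          }
        }
      }
      B_R[[rs]] <- Bp
    }
  }
  list(B_K = B_K, B_R = B_R, ti = ti)
}

# Admissible (rs, h) start states at receptor index ri achieving the
# minimal total weight under the active constraints.
dp_candidates <- function(dp, ri, H, rmax, kmax, max_nodes, mode) {
  grid <- expand.grid(rs = seq_len(rmax), h = seq_len(H))
  grid$k <- grid$h - grid$rs          # kinase-layer count
  if (mode == "layered") {
    ok <- (grid$h + 1L) >= 3L & (grid$h + 1L) <= max_nodes &
      grid$k >= 1L & grid$k <= kmax
  } else {
    ok <- grid$k >= 1L
  }
  grid <- grid[ok, , drop = FALSE]
  grid$w <- mapply(function(rs, h) dp$B_R[[rs]][h, ri], grid$rs, grid$h)
  grid <- grid[is.finite(grid$w), , drop = FALSE]
  if (nrow(grid) == 0L) return(grid)
  grid[grid$w == min(grid$w), , drop = FALSE]
}

# Greedy forward reconstruction of the lexicographically smallest
# minimum-weight walk, carrying the set of tied DP states.
reconstruct_path <- function(dp, cand, r, t, nodes, by_cat) {
  total <- cand$w[1]
  # alive states: data.frame(type, node_i, rs, h); value of each equals the
  # optimal remaining weight (identical across the set)
  alive <- data.frame(type = "R", node_i = match(r, nodes),
                      rs = cand$rs, h = cand$h, stringsAsFactors = FALSE)
  path <- r
  roles <- "R"
  repeat {
    if (all(alive$type == "TF")) break
    succ <- list()
    for (i in seq_len(nrow(alive))) {
      s <- alive[i, ]
      val <- state_value(dp, s)
      if (s$type == "R" && s$rs >= 2L) {
        e <- by_cat$RR[by_cat$RR$from_i == s$node_i, , drop = FALSE]
        if (nrow(e)) {
          nxt <- e$weight +
            dp$B_R[[s$rs - 1L]][cbind(rep(s$h - 1L, nrow(e)), e$to_i)]
          keep <- is.finite(nxt) & nxt == val
          if (any(keep)) {
            succ[[length(succ) + 1L]] <- data.frame(
              type = "R", node_i = e$to_i[keep], rs = s$rs - 1L,
              h = s$h - 1L, stringsAsFactors = FALSE)
          }
        }
      } else if (s$type == "R") {
        e <- by_cat$RK[by_cat$RK$from_i == s$node_i, , drop = FALSE]
        if (nrow(e)) {
          nxt <- e$weight + dp$B_K[cbind(rep(s$h - 1L, nrow(e)), e$to_i)]
          keep <- is.finite(nxt) & nxt == val
          if (any(keep)) {
            succ[[length(succ) + 1L]] <- data.frame(
              type = "K", node_i = e$to_i[keep], rs = 0L,
              h = s$h - 1L, stringsAsFactors = FALSE)
          }
        }
      } else if (s$type == "K") {
        if (s$h == 1L) {
          e <- by_cat$KT[by_cat$KT$from_i == s$node_i &
                           by_cat$KT$to_i == dp$ti, , drop = FALSE]
          if (nrow(e) && any(e$weight == val)) {
            succ[[length(succ) + 1L]] <- data.frame(
              type = "TF", node_i = dp$ti, rs = 0L, h = 0L,
              stringsAsFactors = FALSE)
          }
        } else {
          e <- by_cat$KK[by_cat$KK$from_i == s$node_i, , drop = FALSE]
          if (nrow(e)) {
            nxt <- e$weight + dp$B_K[cbind(rep(s$h - 1L, nrow(e)), e$to_i)]
            keep <- is.finite(nxt) & nxt == val
            if (any(keep)) {
              succ[[length(succ) + 1L]] <- data.frame(
                type = "K", node_i = e$to_i[keep], rs = 0L,
                h = s$h - 1L, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    succ <- unique(do.call(rbind, succ))
    w_sym <- min(nodes[succ$node_i])
    alive <- succ[nodes[succ$node_i] == w_sym, , drop = FALSE]
    path <- c(path, w_sym)
    roles <- c(roles, alive$type[1])
  }
  list(nodes = path, roles = roles, weight = total)
}

state_value <- function(dp, s) {
  if (s$type == "R") dp$B_R[[s$rs]][s$h, s$node_i]
  else if (s$type == "K") dp$B_K[s$h, s$node_i]
  else 0
}

# Exact bounded DFS over *simple* paths r -> t; returns the minimum-weight
# (then lexicographically smallest) constraint-satisfying path, or NULL.
# Only invoked when the walk DP reused a multi-role node.
best_simple_path <- function(r, t, nodes, by_cat, max_nodes, rmax, kmax) {
  ti <- match(t, nodes)
  best <- NULL
  consider <- function(path_i, roles, weight) {
    cand <- list(nodes = nodes[path_i], roles = roles, weight = weight)
    if (is.null(best) || weight < best$weight ||
        (weight == best$weight &&
           paste(cand$nodes, collapse = "\r") <
             paste(best$nodes, collapse = "\r"))) {
      best <<- cand
    }
  }
  recurse <- function(v_i, role, path_i, roles, weight, r_used, k_used) {
    if (length(path_i) > max_nodes) return()
    if (role == "TF") {
      if (v_i == ti && length(path_i) >= 3L) consider(path_i, roles, weight)
      return()
    }
    cats <- if (role == "R") c("RR", "RK") else c("KK", "KT")
    for (cat in cats) {
      e <- by_cat[[cat]][by_cat[[cat]]$from_i == v_i, , drop = FALSE]
      for (j in seq_len(nrow(e))) {
        w_i <- e$to_i[j]
        if (w_i %in% path_i) next
        tr <- category_roles(cat)[2]
        nr <- r_used + (tr == "R"); nk <- k_used + (tr == "K")
        if (nr > rmax || nk > kmax) next
        recurse(w_i, tr, c(path_i, w_i), c(roles, tr),
                weight + e$weight[j], nr, nk)
      }
    }
  }
  recurse(match(r, nodes), "R", match(r, nodes), "R", 0, 1L, 0L)
  best
}

#' Check the complete-path constraints
#'
#' A complete path runs receptor-first, kinases in the middle, one
#' terminal transcription factor, with 3 to `max_nodes` nodes, at most
#' `max_r_layers` leading receptors and at most `max_k_layers` kinases,
#' and no repeated node.
#'
#' @param nodes character vector, the ordered node chain.
#' @param roles character vector of `"R"`, `"K"`, `"TF"` aligned to
#'   `nodes`.
#' @param max_nodes,max_r_layers,max_k_layers the budgets.
#' @return `TRUE` or `FALSE`.
#' @export
validate_path <- function(nodes, roles, max_nodes = 7L, max_r_layers = 2L,
                          max_k_layers = 5L) {
  n <- length(nodes)
  if (n != length(roles)) stop("nodes and roles differ in length",
                               call. = FALSE)
  if (n < 3L || n > max_nodes) return(FALSE)
  if (anyDuplicated(nodes) > 0L) return(FALSE)
  runs <- rle(roles)
  if (!identical(runs$values, c("R", "K", "TF"))) return(FALSE)
  runs$lengths[1] >= 1L && runs$lengths[1] <= max_r_layers &&
    runs$lengths[2] >= 1L && runs$lengths[2] <= max_k_layers &&
    runs$lengths[3] == 1L
}

#' Drop paths composed entirely of housekeeping genes
#'
#' Paths whose every member is a housekeeping gene carry no cell-type
#' information and are removed from the background; receptors left with
#' no path disappear from the map.  A single non-housekeeping member is
#' enough to retain a path.
#'
#' @param background a `pathway_background`.
#' @param hk character vector of housekeeping gene symbols, or a
#'   `housekeeping_set`.
#' @return filtered `pathway_background`.
#' @export
remove_housekeeping_paths <- function(background, hk) {
  stopifnot(inherits(background, "pathway_background"))
  if (inherits(hk, "housekeeping_set")) hk <- hk$genes
  hk <- normalize_symbols(as.character(hk))
  if (nrow(background) == 0L || length(hk) == 0L) return(background)
  all_hk <- vapply(strsplit(background$path, ">", fixed = TRUE),
                   function(p) all(p %in% hk), logical(1))
  out <- background[!all_hk, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pathway_background", "data.frame")
  out
}

#' @export
print.pathway_background <- function(x, ...) {
  cat(sprintf("pathway background: %d paths across %d receptor pathways\n",
              nrow(x), length(unique(x$receptor))))
  if (nrow(x)) {
    NextMethod()
  }
  invisible(x)
}

path_nodes <- function(background) {
  strsplit(background$path, ">", fixed = TRUE)
}
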
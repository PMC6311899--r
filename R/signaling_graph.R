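#' Build the role-constrained directed signaling graph
#'
#' Each undirected, confidence-filtered interaction is expanded into the
#' directed edges whose (source role, target role) pair is biologically
#' admissible for signal flow:
#'
#' * `RR` — receptor to receptor, only from a receptor with *no* direct
#'   kinase interaction towards a receptor that has one (a bridging hop
#'   that lets kinase-disconnected receptors join the cascade);
#' * `RK` — receptor to kinase;
#' * `KK` — kinase to kinase, in both directions;
#' * `KT` — kinase to transcription factor.
#'
#' Transcription factors never source an edge.  A symbol holding several
#' roles generates edges for every applicable category; the category tag
#' on each edge records the role each endpoint plays there.  Edge weight
#' is `1000 - combined_score`, so Dijkstra-style minimization prefers
#' high-confidence routes.  Interactions admitting no category are
#' dropped and tallied, not raised as errors.
#'
#' @param interactions confidence-filtered interaction data frame.
#' @param roles a [load_molecule_roles()] object.
#' @return object of class `signaling_graph`: list with
#'   `edges` (data frame `from`, `to`, `category`, `weight`),
#'   `roles`, and `discarded` (named counts `unknown_role`,
#'   `no_category` of dropped interactions).
#' @examples
#' roles <- load_molecule_roles(c("R1", "R2"), c("K1", "K2"),
#'                              c("TF1", "TF2"))
#' ppi <- as_interactions(data.frame(
#'   a = c("R2", "R1", "K1", "K1", "K2"),
#'   b = c("R1", "K1", "K2", "TF1", "TF2"),
#'   combined_score = c(720L, 900L, 750L, 800L, 900L)))
#' g <- build_signaling_graph(ppi, roles)
#' g$edges
#' @export
build_signaling_graph <- function(interactions, roles) {
  interactions <- dedup_interactions(as_interactions(interactions))
  stopifnot(inherits(roles, "molecule_roles"))

  R <- roles$receptors; K <- roles$kinases; TFs <- roles$tfs
  known <- unique(c(R, K, TFs))
  a <- interactions$a; b <- interactions$b
  unknown <- !(a %in% known) | !(b %in% known)

  # receptors with at least one direct kinase partner (self never counts:
  # an R that is itself also a kinase is not thereby "connected with K")
  partner_of <- function(x, y) unique(x[y %in% K & x != y])
  k_connected <- intersect(R, c(partner_of(a, b), partner_of(b, a)))

  w <- 1000L - interactions$combined_score
  pieces <- list()
  add <- function(mask, from, to, category) {
    if (!any(mask)) return()
    pieces[[length(pieces) + 1L]] <<- data.frame(
      from = from[mask], to = to[mask], category = category,
      weight = w[mask], stringsAsFactors = FALSE)
  }
  used <- rep(FALSE, nrow(interactions))
  for (dir in list(list(x = a, y = b), list(x = b, y = a))) {
    x <- dir$x; y <- dir$y
    m_rk <- x %in% R & y %in% K
    m_kk <- x %in% K & y %in% K
    m_kt <- x %in% K & y %in% TFs
    m_rr <- x %in% R & y %in% R &
      !(x %in% k_connected) & (y %in% k_connected)
    add(m_rk, x, y, "RK")
    add(m_kk, x, y, "KK")
    add(m_kt, x, y, "KT")
    add(m_rr, x, y, "RR")
    used <- used | m_rk | m_kk | m_kt | m_rr
  }

  edges <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(from = character(), to = character(),
               category = character(), weight = integer(),
               stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to, edges$category), , drop = FALSE]
  rownames(edges) <- NULL

  structure(
    list(
      edges = edges,
      roles = roles,
      discarded = c(unknown_role = sum(unknown),
                    no_category = sum(!used & !unknown))
    ),
    class = "signaling_graph"
  )
}

#' @export
print.signaling_graph <- function(x, ...) {
  nodes <- unique(c(x$edges$from, x$edges$to))
  cat(sprintf("signaling graph: %d nodes, %d directed edges\n",
              length(nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    tab <- table(x$edges$category)
    cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("  discarded interactions: %d unknown-role, %d no-category\n",
              x$discarded[["unknown_role"]], x$discarded[["no_category"]]))
  invisible(x)
}

graph_nodes <- function(graph) {
  sort(unique(c(graph$edges$from, graph$edges$to)))
}

# roles implied by an edge category for (source, target)
category_roles <- function(category) {
  switch(category,
         RR = c("R", "R"),
         RK = c("R", "K"),
         KK = c("K", "K"),
         KT = c("K", "TF"),
         stop("unknown edge category: ", category))
}
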
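#' Specification for the synthetic-data generator
#'
#' Describes a simulated world standing in for the real inputs (a scored
#' interactome, curated role lists, a multi-tissue expression panel and a
#' query RNA-seq matrix): a role-labelled random network with explicitly
#' wired signal-carrying routes under a few *planted* receptors, an
#' expression matrix in which every member of a planted receptor's
#' background pathway is highly expressed, and a tissue panel with a
#' configurable housekeeping fraction.
#'
#' Default sizes (20 R / 40 K / 30 TF, 3 planted receptors) and sparse
#' edge densities give a subcritical kinase layer in which a typical
#' receptor reaches a handful of TFs, so one receptor's cascade — like a
#' real signaling program — involves a minority of the genome rather
#' than most of it.  Expression classes
#' are Gaussian on the log2 scale, truncated at 0: silent genes at mean
#' 0.5 (below the 1.5 cutoff), expressed bystanders at mean 4, active
#' pathway members at mean 7 (three noise SDs above the bystanders), all
#' with SD 1.
#'
#' @param n_receptors,n_kinases,n_tfs role set sizes.
#' @param edge_density list with per-category interaction probabilities
#'   `rr`, `rk`, `kk`, `kt`.
#' @param score_range integer interval within \[1, 999\] for uniform
#'   `combined_score` sampling.
#' @param n_planted number of receptors given guaranteed active routes.
#' @param routes_per_planted number of TFs wired under each planted
#'   receptor (through two dedicated kinases); at least 5 so planted
#'   pathways can pass the default high-ranked selection.
#' @param hk_fraction fraction of genes that are housekeeping in the
#'   panel.
#' @param expressed_fraction per-gene probability that a non-active
#'   network gene is expressed (rather than silent) in the query.
#' @param silent_mean,expressed_mean,active_mean,noise_sd expression
#'   class parameters (log2 scale).
#' @param cutoff,prevalence expression cutoff and housekeeping prevalence
#'   used when constructing the panel.
#' @param n_panel_samples,n_replicates panel width and query replicate
#'   count.
#' @param seed master seed; the network, panel and query use streams
#'   `seed`, `seed + 1`, `seed + 2`.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_receptors = 20L, n_kinases = 40L,
                           n_tfs = 30L,
                           edge_density = list(rr = 0.03, rk = 0.03,
                                               kk = 0.015, kt = 0.03),
                           score_range = c(700L, 999L),
                           n_planted = 3L, routes_per_planted = 6L,
                           hk_fraction = 0.3, expressed_fraction = 0.6,
                           silent_mean = 0.5, expressed_mean = 4,
                           active_mean = 7, noise_sd = 1,
                           cutoff = 1.5, prevalence = 0.75,
                           n_panel_samples = 20L, n_replicates = 3L,
                           seed = 1L) {
  spec <- list(n_receptors = as.integer(n_receptors),
               n_kinases = as.integer(n_kinases),
               n_tfs = as.integer(n_tfs),
               edge_density = edge_density,
               score_range = as.integer(score_range),
               n_planted = as.integer(n_planted),
               routes_per_planted = as.integer(routes_per_planted),
               hk_fraction = hk_fraction,
               expressed_fraction = expressed_fraction,
               silent_mean = silent_mean, expressed_mean = expressed_mean,
               active_mean = active_mean, noise_sd = noise_sd,
               cutoff = cutoff, prevalence = prevalence,
               n_panel_samples = as.integer(n_panel_samples),
               n_replicates = as.integer(n_replicates),
               seed = as.integer(seed))
  if (spec$n_receptors < 1L || spec$n_kinases < 1L || spec$n_tfs < 1L) {
    stop("each role needs at least one gene", call. = FALSE)
  }
  dens <- unlist(spec$edge_density[c("rr", "rk", "kk", "kt")])
  if (length(dens) != 4L || any(dens < 0) || any(dens > 1)) {
    stop("edge_density must give rr/rk/kk/kt fractions in [0, 1]",
         call. = FALSE)
  }
  if (any(spec$score_range < 1L) || any(spec$score_range > 999L) ||
      spec$score_range[1] > spec$score_range[2]) {
    stop("score_range must be an increasing interval within [1, 999]",
         call. = FALSE)
  }
  if (spec$n_planted > 0L) {
    if (spec$n_kinases < 2L * spec$n_planted) {
      stop("impossible spec: need 2 kinases per planted receptor",
           call. = FALSE)
    }
    if (spec$n_tfs < spec$routes_per_planted * spec$n_planted) {
      stop("impossible spec: not enough TFs for the planted routes",
           call. = FALSE)
    }
    if (spec$n_planted > spec$n_receptors) {
      stop("impossible spec: more planted receptors than receptors",
           call. = FALSE)
    }
  }
  if (!(spec$silent_mean < spec$expressed_mean &&
          spec$expressed_mean < spec$active_mean)) {
    stop("means must satisfy silent < expressed < active", call. = FALSE)
  }
  stopifnot(spec$hk_fraction >= 0, spec$hk_fraction <= 1,
            spec$expressed_fraction >= 0, spec$expressed_fraction <= 1,
            spec$n_panel_samples >= 2L, spec$n_replicates >= 1L)
  structure(spec, class = "synthetic_spec")
}

# sample() treats a length-1 numeric vector as 1:n; this never does
sample_from <- function(v, n, replace = FALSE) {
  v[sample.int(length(v), n, replace = replace)]
}

sample_pairs <- function(x, y, density) {
  # undirected pairs between x and y (x == y: unordered distinct pairs)
  if (length(x) == 0L || length(y) == 0L || density <= 0) {
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  if (identical(x, y)) {
    idx <- which(upper.tri(matrix(0, length(x), length(x))), arr.ind = TRUE)
    pairs <- data.frame(a = x[idx[, 1]], b = x[idx[, 2]],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- expand.grid(a = x, b = y, stringsAsFactors = FALSE)
  }
  pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
}

#' Generate a role-labelled synthetic interaction network
#'
#' Random interactions are drawn independently per permitted category
#' (R-R, R-K, K-K, K-TF) at the spec's densities, with uniform scores in
#' `score_range`.  On top of the random background, every planted
#' receptor is wired with an explicit route set — two dedicated kinases
#' feeding `routes_per_planted` dedicated TFs — so a constraint-
#' satisfying path to each of those TFs is guaranteed, never left to
#' chance.  Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_network` with elements
#'   `interactions`, `roles`, `planted` (list: `receptors`, `routes` —
#'   per-receptor member gene vectors).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  R <- sprintf("R%02d", seq_len(spec$n_receptors))
  K <- sprintf("K%02d", seq_len(spec$n_kinases))
  TFs <- sprintf("TF%02d", seq_len(spec$n_tfs))
  roles <- load_molecule_roles(R, K, TFs)

  with_seed(spec$seed, {
    pairs <- rbind(
      sample_pairs(R, R, spec$edge_density$rr),
      sample_pairs(R, K, spec$edge_density$rk),
      sample_pairs(K, K, spec$edge_density$kk),
      sample_pairs(K, TFs, spec$edge_density$kt)
    )
    planted_receptors <- sort(sample(R, spec$n_planted))
    routes <- list()
    if (spec$n_planted > 0L) {
      ks <- sample(K, 2L * spec$n_planted)
      ts <- sample(TFs, spec$routes_per_planted * spec$n_planted)
      for (i in seq_len(spec$n_planted)) {
        r <- planted_receptors[i]
        ka <- ks[2L * i - 1L]; kb <- ks[2L * i]
        tfs_i <- ts[seq.int((i - 1L) * spec$routes_per_planted + 1L,
                            i * spec$routes_per_planted)]
        half <- ceiling(length(tfs_i) / 2)
        wired <- rbind(
          data.frame(a = r, b = ka, stringsAsFactors = FALSE),
          data.frame(a = ka, b = kb, stringsAsFactors = FALSE),
          data.frame(a = ka, b = tfs_i[seq_len(half)],
                     stringsAsFactors = FALSE),
          data.frame(a = kb, b = tfs_i[seq.int(half + 1L, length(tfs_i))],
                     stringsAsFactors = FALSE)
        )
        pairs <- rbind(pairs, wired)
        routes[[r]] <- unique(c(r, ka, kb, tfs_i))
      }
    }
    score <- sample_from(seq.int(spec$score_range[1], spec$score_range[2]),
                         nrow(pairs), replace = TRUE)
    interactions <- dedup_interactions(
      as_interactions(data.frame(a = pairs$a, b = pairs$b,
                                 combined_score = score,
                                 stringsAsFactors = FALSE)))
    structure(
      list(interactions = interactions, roles = roles,
           planted = list(receptors = planted_receptors, routes = routes)),
      class = "synthetic_network"
    )
  })
}

#' Generate a query expression matrix with planted active pathways
#'
#' Builds the background pathway map for the network, collects every gene
#' appearing in a path rooted at a planted receptor, and draws those
#' genes from the *active* class (`Normal(active_mean, noise_sd)`,
#' truncated at 0).  Each remaining network gene is expressed
#' (`Normal(expressed_mean, noise_sd)`) with probability
#' `expressed_fraction`, otherwise silent (`Normal(silent_mean,
#' noise_sd)`), mimicking a transcriptome in which one signaling program
#' is switched on over a partially expressed background.  `n_replicates`
#' replicate columns of a single condition are emitted.
#'
#' @param network a [generate_network()] result.
#' @param spec the [synthetic_spec()] used to build it.
#' @return list with `matrix` (genes x replicates), `groups` (named
#'   vector sample -> condition, ready for [average_replicates()]),
#'   `truth` (data frame `gene`, `class` in
#'   silent/expressed/active), `planted_receptors`.
#' @export
generate_expression <- function(network, spec) {
  stopifnot(inherits(network, "synthetic_network"),
            inherits(spec, "synthetic_spec"))
  genes <- all_role_symbols(network$roles)
  graph <- build_signaling_graph(
    filter_interactions(network$interactions, min_score = 700L),
    network$roles)
  background <- shortest_rk_tf_paths(graph)
  planted_paths <- background[
    background$receptor %in% network$planted$receptors, , drop = FALSE]
  active <- unique(c(unlist(path_nodes(planted_paths)),
                     unlist(network$planted$routes)))

  with_seed(spec$seed + 2L, {
    class <- ifelse(
      genes %in% active, "active",
      ifelse(stats::runif(length(genes)) < spec$expressed_fraction,
             "expressed", "silent"))
    mu <- c(silent = spec$silent_mean, expressed = spec$expressed_mean,
            active = spec$active_mean)[class]
    mat <- vapply(seq_len(spec$n_replicates), function(j) {
      pmax(0, stats::rnorm(length(genes), mean = mu, sd = spec$noise_sd))
    }, numeric(length(genes)))
    mat <- matrix(mat, nrow = length(genes),
                  dimnames = list(genes,
                                  sprintf("QUERY_%d",
                                          seq_len(spec$n_replicates))))
    list(matrix = mat,
         groups = stats::setNames(rep("QUERY", ncol(mat)), colnames(mat)),
         truth = data.frame(gene = genes, class = unname(class),
                            stringsAsFactors = FALSE),
         planted_receptors = network$planted$receptors)
  })
}

#' Generate a multi-tissue panel with a known housekeeping set
#'
#' `hk_fraction` of the genes are made housekeeping by construction:
#' each housekeeping gene is expressed (value >= `cutoff`) in at least
#' `prevalence` of the samples, every other gene in strictly fewer, so
#' [identify_housekeeping()] at the same cutoff/prevalence recovers the
#' intended set exactly.
#'
#' @param roles a [load_molecule_roles()] object providing the gene
#'   universe.
#' @param spec a [synthetic_spec()].
#' @return list with `panel` (an [expression_panel()]) and
#'   `housekeeping` (character vector, the true set).
#' @export
generate_panel <- function(roles, spec) {
  stopifnot(inherits(roles, "molecule_roles"),
            inherits(spec, "synthetic_spec"))
  genes <- all_role_symbols(roles)
  S <- spec$n_panel_samples
  min_count <- ceiling(spec$prevalence * S - 1e-9)
  with_seed(spec$seed + 1L, {
    n_hk <- round(spec$hk_fraction * length(genes))
    hk <- sort(sample(genes, n_hk))
    counts <- ifelse(genes %in% hk,
                     sample_from(seq.int(min_count, S), length(genes),
                                 replace = TRUE),
                     sample_from(seq.int(0L, min_count - 1L),
                                 length(genes), replace = TRUE))
    mat <- t(vapply(seq_along(genes), function(i) {
      on <- sample.int(S, counts[i])
      v <- pmin(spec$cutoff - 1e-6,
                pmax(0, stats::rnorm(S, spec$silent_mean, spec$noise_sd)))
      v[on] <- pmax(spec$cutoff,
                    stats::rnorm(counts[i], spec$expressed_mean,
                                 spec$noise_sd))
      v
    }, numeric(S)))
    dimnames(mat) <- list(genes, sprintf("TISSUE_%02d", seq_len(S)))
    list(panel = expression_panel(mat), housekeeping = hk)
  })
}
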
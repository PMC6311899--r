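#' Read a gene list (one symbol per line)
#'
#' Blank lines and `#` comments are ignored; symbols are upper-cased and
#' de-duplicated.
#'
#' @param path file path.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stopf("gene list file is empty: %s", path)
  unique(normalize_symbols(lines))
}

#' @rdname read_gene_list
#' @param symbols character vector to write.
#' @export
write_gene_list <- function(symbols, path) {
  writeLines(normalize_symbols(symbols), path)
  invisible(path)
}

split_fields <- function(lines) {
  strsplit(trimws(lines), "[ \t]+")
}

#' Read a scored interaction table
#'
#' Whitespace- or tab-separated, three columns
#' `protein1 protein2 combined_score`; `#` comments skipped and a header
#' line auto-detected (third field not numeric).
#'
#' @param path file path.
#' @return interaction data frame (see [as_interactions()]).
#' @export
read_ppi_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stopf("interaction file is empty: %s", path)
  fields <- split_fields(lines)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stopf("interaction file %s: line %d has fewer than 3 fields",
                         path, bad[1])
  if (is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    fields <- fields[-1]            # header
    if (length(fields) == 0L) stopf("interaction file is empty: %s", path)
  }
  scores <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(scores)) {
    stopf("interaction file %s: non-numeric score on data line %d",
          path, which(is.na(scores))[1])
  }
  as_interactions(data.frame(
    a = vapply(fields, `[`, "", 1L),
    b = vapply(fields, `[`, "", 2L),
    combined_score = scores, stringsAsFactors = FALSE))
}

#' @rdname read_ppi_tsv
#' @param interactions interaction data frame.
#' @param header write a header line.
#' @export
write_ppi_tsv <- function(interactions, path, header = TRUE) {
  interactions <- as_interactions(interactions)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (header) writeLines("protein1\tprotein2\tcombined_score", con)
  writeLines(sprintf("%s\t%s\t%d", interactions$a, interactions$b,
                     interactions$combined_score), con)
  invisible(path)
}

#' Read a two-column ortholog map
#' @param path file path (TSV `symbol_a symbol_b`).
#' @return validated two-column data frame.
#' @export
read_ortholog_map <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- split_fields(lines)
  if (any(lengths(fields) < 2L)) {
    stopf("ortholog map %s: line %d has fewer than 2 fields", path,
          which(lengths(fields) < 2L)[1])
  }
  validate_ortholog_map(data.frame(
    symbol_a = vapply(fields, `[`, "", 1L),
    symbol_b = vapply(fields, `[`, "", 2L), stringsAsFactors = FALSE))
}

#' Read a genes-by-samples expression TSV
#'
#' First column gene symbol, one column per sample, header row required.
#' Duplicate gene rows and non-numeric cells are errors.
#'
#' @param path file path.
#' @return numeric matrix, genes as rownames (upper-cased).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stopf("expression file %s needs a gene column plus samples",
                           path)
  genes <- normalize_symbols(as.character(df[[1]]), drop_empty = FALSE)
  if (anyDuplicated(genes)) {
    stopf("expression file %s: duplicate gene symbol %s", path,
          genes[duplicated(genes)][1])
  }
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
                dimnames = list(genes, colnames(df)[-1]))
  for (j in seq.int(2L, ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      stopf("expression file %s: non-numeric value at row %d, column %s",
            path, which(is.na(v))[1], colnames(df)[j])
    }
    mat[, j - 1L] <- v
  }
  mat
}

#' @rdname read_expression_tsv
#' @param mat numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read/write the background path table
#'
#' Tab-separated with header
#' `receptor path total_weight terminal_tf roles`; the `path` and `roles`
#' columns are `>`-joined chains (e.g. `R1>K1>TF1`).
#'
#' @param path file path.
#' @return a `pathway_background`.
#' @export
read_background_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("receptor", "path", "total_weight", "terminal_tf", "roles")
  if (!all(need %in% names(df))) {
    stopf("background file %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- df[, c("receptor", "path", "roles", "total_weight", "terminal_tf")]
  class(out) <- c("pathway_background", "data.frame")
  out
}

#' @rdname read_background_tsv
#' @param background a `pathway_background`.
#' @export
write_background_tsv <- function(background, path) {
  stopifnot(inherits(background, "pathway_background"))
  df <- background[, c("receptor", "path", "total_weight", "terminal_tf",
                       "roles")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the ranked pathway table
#' @param ranked a [rank_pathways()] result.
#' @param path file path.
#' @export
write_ranked_tsv <- function(ranked, path) {
  cols <- intersect(c("rank", "receptor", "n", "activity_score"),
                    names(ranked))
  utils::write.table(as.data.frame(ranked)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read/write a housekeeping list
#'
#' One symbol per line, or two tab-separated columns
#' (`gene    prevalence`) when `with_prevalence`.
#'
#' @param hk a `housekeeping_set`.
#' @param path file path.
#' @param with_prevalence also write the observed prevalence fraction.
#' @export
write_housekeeping <- function(hk, path, with_prevalence = FALSE) {
  stopifnot(inherits(hk, "housekeeping_set"))
  if (with_prevalence) {
    writeLines(sprintf("%s\t%.6g", hk$genes,
                       as.numeric(hk$prevalence[hk$genes])), path)
  } else {
    writeLines(hk$genes, path)
  }
  invisible(path)
}

#' Serialize a signaling graph to JSON
#'
#' Nodes with their role labels plus the directed weighted edge list and
#' the discard tally, round-trippable through [read_graph_json()].
#'
#' @param graph a [build_signaling_graph()] object.
#' @param path file path.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "signaling_graph"))
  obj <- list(
    roles = list(receptors = graph$roles$receptors,
                 kinases = graph$roles$kinases,
                 tfs = graph$roles$tfs),
    edges = graph$edges,
    discarded = as.list(graph$discarded)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roles <- load_molecule_roles(obj$roles$receptors, obj$roles$kinases,
                               obj$roles$tfs)
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  edges$weight <- as.integer(edges$weight)
  structure(
    list(edges = edges, roles = roles,
         discarded = c(unknown_role = as.integer(obj$discarded$unknown_role),
                       no_category = as.integer(obj$discarded$no_category))),
    class = "signaling_graph")
}

#' Write a false-positive-rate result to JSON
#' @param fpr an [false_positive_rate()] result.
#' @param path file path.
#' @export
write_fpr_json <- function(fpr, path) {
  stopifnot(inherits(fpr, "fpr_result"))
  jsonlite::write_json(unclass(fpr), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
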
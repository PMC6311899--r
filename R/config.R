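config_defaults <- list(
  min_score = 700L, cutoff = 1.5, prevalence = 0.75,
  max_nodes = 7L, max_r_layers = 2L, max_k_layers = 5L,
  quantile = 0.75, min_tfs = 5L, reps = 10L, seed = 1L
)

#' Pipeline run configuration
#'
#' Collects every tunable parameter with its default: `min_score` 700
#' (STRING high confidence), `cutoff` 1.5 (log2 expression), `prevalence`
#' 0.75 (housekeeping), path budgets `max_nodes` 7 / `max_r_layers` 2 /
#' `max_k_layers` 5, high-ranked selection `quantile` 0.75 / `min_tfs` 5,
#' permutation `reps` 10, and `seed`.  Serializes losslessly to a flat
#' `key = value` text file.
#'
#' @param ... overrides of the defaults (unknown keys are errors).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(config_defaults))
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(config_defaults, over)
  int_keys <- c("min_score", "max_nodes", "max_r_layers", "max_k_layers",
                "min_tfs", "reps", "seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("cutoff", "prevalence", "quantile")) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  stopifnot(cfg$min_score >= 1L, cfg$min_score <= 999L,
            cfg$prevalence > 0, cfg$prevalence <= 1,
            cfg$quantile > 0, cfg$quantile < 1,
            cfg$max_nodes >= 3L, cfg$reps >= 1L)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path file path of a `key = value` configuration file.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stopf("config %s: cannot parse line %d", path, bad[1])
  vals <- lapply(kv, function(m) utils::type.convert(m[3], as.is = TRUE))
  names(vals) <- vapply(kv, `[`, "", 2L)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, format, "", scientific = FALSE)), path)
  invisible(path)
}
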
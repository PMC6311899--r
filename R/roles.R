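#' Assemble receptor / kinase / transcription-factor role sets
#'
#' Signaling cascades are modelled as directed chains running from a
#' membrane receptor (R) through one or more kinases (K) to a terminal
#' transcription factor (TF).  This constructor collects the three curated
#' role lists into a single validated object.  A symbol may legitimately
#' carry several roles (e.g. a receptor with intrinsic kinase activity);
#' overlapping sets are kept as-is and downstream code considers every
#' applicable role.
#'
#' @param receptors character vector of receptor gene symbols.
#' @param kinases character vector of kinase gene symbols.
#' @param tfs character vector of transcription-factor gene symbols.
#' @return an object of class `molecule_roles`: a list with character
#'   vector elements `receptors`, `kinases` and `tfs`, each unique and
#'   upper-cased.
#' @examples
#' roles <- load_molecule_roles(c("EGFR", "FGFR1"), c("MAPK1"), c("JUN"))
#' roles$receptors
#' @export
load_molecule_roles <- function(receptors, kinases, tfs) {
  clean <- function(x, what) {
    if (!is.character(x)) {
      bad <- which(!vapply(x, is.character, logical(1)))[1]
      stopf("%s list: entry %d is not a character string", what,
            if (is.na(bad)) 1L else bad)
    }
    x <- unique(normalize_symbols(x))
    if (length(x) == 0L) stopf("%s list empty after cleaning", what)
    x
  }
  structure(
    list(
      receptors = clean(receptors, "receptor"),
      kinases   = clean(kinases, "kinase"),
      tfs       = clean(tfs, "transcription factor")
    ),
    class = "molecule_roles"
  )
}

#' @export
print.molecule_roles <- function(x, ...) {
  cat(sprintf(
    "molecule roles: %d receptors, %d kinases, %d transcription factors\n",
    length(x$receptors), length(x$kinases), length(x$tfs)))
  ov <- intersect(x$receptors, x$kinases)
  if (length(ov)) {
    cat(sprintf("  %d symbol(s) carry both R and K roles\n", length(ov)))
  }
  invisible(x)
}

all_role_symbols <- function(roles) {
  sort(unique(c(roles$receptors, roles$kinases, roles$tfs)))
}
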
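#' Gene universe
#'
#' The ordered set of gene identifiers over which profiles are ranked and
#' scores computed. In L1000-style perturbation profiling this is the set of
#' directly measured "landmark" genes (978 in the standard panel); restricting
#' scoring to directly measured genes avoids artefacts from computationally
#' imputed expression.
#'
#' @param genes Character vector of unique, non-empty gene identifiers.
#'   Order is preserved as given.
#' @return A `gene_universe` object (a classed character vector).
#' @examples
#' u <- gene_universe(c("TP53", "MYC", "EGFR"))
#' length(u)
#' @export
gene_universe <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene universe is empty", call. = FALSE)
  if (anyNA(genes) || !all(nzchar(genes))) {
    stop("gene universe contains missing or blank identifiers", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("gene universe contains duplicated identifiers, e.g.: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  structure(genes, class = c("gene_universe", "character"))
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("<gene_universe> %d genes: %s%s\n", length(x),
              paste(utils::head(unclass(x), 5), collapse = ", "),
              if (length(x) > 5) ", ..." else ""))
  invisible(x)
}

#' Read / write a gene universe (one identifier per line)
#'
#' @param path File path.
#' @return `read_universe()` returns a [gene_universe()];
#'   `write_universe()` returns `path` invisibly.
#' @export
read_universe <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  gene_universe(lines[nzchar(lines)])
}

#' @rdname read_universe
#' @param universe A [gene_universe()].
#' @export
write_universe <- function(universe, path) {
  writeLines(as.character(universe), path)
  invisible(path)
}
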
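#' Build a disease expression signature from a differential-expression table
#'
#' Selects the significantly up- and downregulated genes of a disease
#' comparison (typically tumour versus adjacent normal tissue) that fall
#' inside the scoring gene universe. A gene enters the signature when its
#' adjusted P value is below `padj_cut` and its absolute log2 fold change
#' exceeds `lfc_cut`; the sign of the fold change assigns the direction.
#' Both inequalities are strict.
#'
#' The fold-change threshold is applied to the absolute value and split by
#' sign: a single cut produces both the up and the down set, which is how
#' disease signatures in signature-reversal screening are constructed.
#'
#' @param de A data frame with columns `gene`, `log2fc`, `padj`
#'   (one row per gene; `padj` in \[0,1\], `NA` rows are excluded).
#' @param universe A [gene_universe()]; genes outside it are silently
#'   excluded (a count is logged).
#' @param lfc_cut Positive log2 fold-change threshold (default 1.5).
#' @param padj_cut Adjusted-P threshold in (0, 1\] (default 0.001).
#' @return A `disease_signature`: list with `up` and `down` gene vectors,
#'   a `stats` data frame (`gene`, `direction`, `log2fc`, `padj`) and the
#'   `universe`.
#' @details A warning is emitted when the signature has 50 or fewer genes in
#'   total: small signatures give unstable enrichment scores, and reversal
#'   screens are usually restricted to diseases with more than 50
#'   differentially expressed landmark genes.
#' @examples
#' u <- gene_universe(c("gA", "gB", "gC", "gD"))
#' de <- data.frame(gene = c("gA", "gB", "gC", "gD"),
#'                  log2fc = c(2.0, -1.7, 1.6, 1.2),
#'                  padj = c(1e-5, 1e-4, 0.01, 1e-6))
#' sig <- suppressWarnings(build_signature(de, u))
#' sig$up    # "gA"
#' sig$down  # "gB"
#' @export
build_signature <- function(de, universe, lfc_cut = 1.5, padj_cut = 0.001) {
  require_columns(de, c("gene", "log2fc", "padj"), "differential-expression table")
  if (nrow(de) == 0) stop("differential-expression table is empty", call. = FALSE)
  if (!is.numeric(lfc_cut) || length(lfc_cut) != 1 || lfc_cut <= 0) {
    stop("lfc_cut must be a single value > 0", call. = FALSE)
  }
  if (!is.numeric(padj_cut) || length(padj_cut) != 1 ||
      padj_cut <= 0 || padj_cut > 1) {
    stop("padj_cut must be in (0, 1]", call. = FALSE)
  }
  de$gene <- as.character(de$gene)
  if (anyDuplicated(de$gene)) {
    stop("differential-expression table must have one row per gene",
         call. = FALSE)
  }
  if (any(!is.finite(de$log2fc))) {
    stop("log2fc contains non-finite values", call. = FALSE)
  }
  bad_p <- !is.na(de$padj) & (de$padj < 0 | de$padj > 1)
  if (any(bad_p)) stop("padj values outside [0, 1]", call. = FALSE)

  n_na <- sum(is.na(de$padj))
  if (n_na > 0) {
    rges_log("excluding %d gene(s) with missing adjusted P", n_na)
    de <- de[!is.na(de$padj), , drop = FALSE]
  }
  outside <- !(de$gene %in% universe)
  if (any(outside)) {
    rges_log("excluding %d gene(s) absent from the %d-gene universe",
             sum(outside), length(universe))
    de <- de[!outside, , drop = FALSE]
  }

  is_up <- de$log2fc > lfc_cut & de$padj < padj_cut
  is_down <- de$log2fc < -lfc_cut & de$padj < padj_cut
  up <- de$gene[is_up]
  down <- de$gene[is_down]
  n_sig <- length(up) + length(down)
  if (n_sig == 0) {
    stop("empty signature: no genes pass |log2fc| > ", lfc_cut,
         " and padj < ", padj_cut, call. = FALSE)
  }
  rges_log("signature: %d up, %d down of %d candidate genes",
           length(up), length(down), nrow(de))
  if (n_sig <= 50) {
    warning(sprintf(paste0("signature has only %d genes (<= 50); reversal ",
                           "scores may be unstable"), n_sig), call. = FALSE)
  }

  keep <- is_up | is_down
  stats <- data.frame(
    gene = de$gene[keep],
    direction = ifelse(is_up[keep], "up", "down"),
    log2fc = de$log2fc[keep],
    padj = de$padj[keep],
    stringsAsFactors = FALSE
  )
  structure(list(up = up, down = down, stats = stats, universe = universe),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat(sprintf("<disease_signature> %d up, %d down (universe: %d genes)\n",
              length(x$up), length(x$down), length(x$universe)))
  invisible(x)
}

#' Swap the up and down sets of a signature
#'
#' Exchanging the directed sets negates the reversal score of every profile
#' exactly; mostly useful for sanity checks and null analyses.
#'
#' @param signature A `disease_signature`.
#' @return A `disease_signature` with directions exchanged.
#' @export
swap_direction <- function(signature) {
  stopifnot(inherits(signature, "disease_signature"))
  stats <- signature$stats
  stats$direction <- ifelse(stats$direction == "up", "down", "up")
  structure(list(up = signature$down, down = signature$up, stats = stats,
                 universe = signature$universe),
            class = "disease_signature")
}

#' Read / write disease signatures and differential-expression tables
#'
#' Tab-separated with headers. A signature file has columns
#' `gene  direction  log2fc  padj` and round-trips exactly; a DE table has
#' `gene  log2fc  padj`.
#'
#' @param path File path.
#' @param signature A `disease_signature`.
#' @param universe The [gene_universe()] the signature refers to.
#' @return `read_signature()` returns a `disease_signature`;
#'   `read_de_table()` a data frame; writers return `path` invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "disease_signature"))
  out <- signature$stats
  out$log2fc <- fmt_double(out$log2fc)
  out$padj <- fmt_double(out$padj)
  write_tsv_atomic(out, path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path, universe) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  stats <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(stats, c("gene", "direction", "log2fc", "padj"), "signature file")
  if (!all(stats$direction %in% c("up", "down"))) {
    stop("signature direction must be 'up' or 'down'", call. = FALSE)
  }
  if (!all(stats$gene %in% universe)) {
    stop("signature file contains genes outside the universe", call. = FALSE)
  }
  structure(list(up = stats$gene[stats$direction == "up"],
                 down = stats$gene[stats$direction == "down"],
                 stats = stats, universe = universe),
            class = "disease_signature")
}

#' @rdname write_signature
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(de, c("gene", "log2fc", "padj"), "differential-expression table")
  de
}

#' @rdname write_signature
#' @param de A data frame with columns `gene`, `log2fc`, `padj`.
#' @export
write_de_table <- function(de, path) {
  require_columns(de, c("gene", "log2fc", "padj"), "differential-expression table")
  out <- de[, c("gene", "log2fc", "padj")]
  out$log2fc <- fmt_double(out$log2fc)
  out$padj <- fmt_double(out$padj)
  write_tsv_atomic(out, path)
}
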
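#' Rank a perturbation profile
#'
#' Orders the genes of one profile by their differential-expression value so
#' that rank 1 is the most upregulated gene and rank n the most
#' downregulated. Ties are broken by ascending gene identifier (byte order),
#' so the ranking is fully deterministic.
#'
#' @param values Named numeric vector of differential-expression values over
#'   the universe (names = gene ids). All values must be finite.
#' @return A `ranked_profile`: named integer vector of positions 1..n with
#'   attribute `n`.
#' @examples
#' rank_profile(c(gA = 2.1, gB = -0.5, gC = 0, gD = 0.9))
#' @export
rank_profile <- function(values) {
  if (is.null(names(values)) || !all(nzchar(names(values)))) {
    stop("profile values must be named by gene", call. = FALSE)
  }
  bad <- !is.finite(values)
  if (any(bad)) {
    stop("non-finite expression value for gene(s): ",
         paste(utils::head(names(values)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(-values, names(values), method = "radix")
  pos <- integer(length(values))
  pos[ord] <- seq_along(values)
  names(pos) <- names(values)
  structure(pos, n = length(pos), class = "ranked_profile")
}

# Kolmogorov-Smirnov-type enrichment maxima for a sorted position vector V
# (ascending) in a ranked list of n genes:
#   a = max_j ( j/m - V(j)/n ),  b = max_j ( V(j)/n - (j-1)/m )
# es = a if a > b else -b.
#' @keywords internal
ks_es <- function(V, n) {
  m <- length(V)
  j <- seq_len(m)
  a <- max(j / m - V / n)
  b <- max(V / n - (j - 1) / m)
  if (a > b) a else -b
}

#' Enrichment score of a gene set in a ranked profile
#'
#' A signed Kolmogorov-Smirnov-style statistic of the positional bias of
#' `geneset` in the ranking: positive when the set piles up near the top
#' (most upregulated end), negative near the bottom. Computed from the two
#' one-sided running-maximum deviations `a` and `b` of the set's empirical
#' position distribution against the uniform; returns `a` when `a > b`,
#' otherwise `-b`. Always in \[-1, 1\].
#'
#' @param ranked A [rank_profile()] result.
#' @param geneset Character vector of genes, all inside the universe.
#' @return A single numeric enrichment score.
#' @examples
#' r <- rank_profile(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))
#' enrichment_score(r, "g1")  # 0.75
#' enrichment_score(r, "g4")  # -1
#' @export
enrichment_score <- function(ranked, geneset) {
  stopifnot(inherits(ranked, "ranked_profile"))
  geneset <- unique(as.character(geneset))
  if (length(geneset) == 0) stop("gene set is empty", call. = FALSE)
  outside <- setdiff(geneset, names(ranked))
  if (length(outside) > 0) {
    stop("gene set contains genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  n <- attr(ranked, "n")
  V <- sort(unname(unclass(ranked)[geneset]))
  ks_es(V, n)
}

#' Reverse Gene Expression Score of one profile against a signature
#'
#' Computes the enrichment score of the signature's up set (`es_up`) and
#' down set (`es_down`) in the value-ranked profile and returns
#' `rges = es_up - es_down`, with no zero-clamping when the two components
#' share a sign (unlike the classic connectivity score, the difference is
#' kept so that the score remains informative for correlation with drug
#' efficacy). A strongly negative RGES means the profile pushes
#' disease-upregulated genes toward the bottom of the ranking and
#' disease-downregulated genes toward the top, i.e. it reverses the disease
#' signature.
#'
#' @param values Named numeric vector: one profile's differential-expression
#'   values over the universe.
#' @param signature A [build_signature()] result.
#' @param min_overlap Minimum genes required per direction after
#'   intersecting with the profile's universe (default 3).
#' @return A list (`rges_record`) with `es_up`, `es_down`, `rges`, `m_up`,
#'   `m_down`.
#' @export
compute_rges <- function(values, signature, min_overlap = 3) {
  stopifnot(inherits(signature, "disease_signature"))
  ranked <- rank_profile(values)
  rges_from_ranked(ranked, signature, min_overlap)
}

#' @keywords internal
signature_overlap <- function(signature, genes, min_overlap, quiet = FALSE) {
  up <- intersect(signature$up, genes)
  down <- intersect(signature$down, genes)
  for (side in c("up", "down")) {
    full <- signature[[side]]
    kept <- if (side == "up") up else down
    miss <- setdiff(full, kept)
    if (length(miss) > 0 && !quiet) {
      rges_log("dropping %d %s-signature gene(s) absent from the universe",
               length(miss), side)
    }
    if (length(kept) < min_overlap) {
      stop(sprintf(paste0("%s signature set overlaps the universe in only ",
                          "%d gene(s) (< %d); missing: %s"),
                   side, length(kept), min_overlap,
                   paste(utils::head(miss, 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  list(up = up, down = down)
}

#' @keywords internal
rges_from_ranked <- function(ranked, signature, min_overlap = 3,
                             overlap = NULL) {
  if (is.null(overlap)) {
    overlap <- signature_overlap(signature, names(ranked), min_overlap)
  }
  es_up <- enrichment_score(ranked, overlap$up)
  es_down <- enrichment_score(ranked, overlap$down)
  structure(list(es_up = es_up, es_down = es_down, rges = es_up - es_down,
                 m_up = length(overlap$up), m_down = length(overlap$down)),
            class = "rges_record")
}

#' Score every profile of a matrix against a disease signature
#'
#' @param pm A [profile_matrix()].
#' @param signature A [build_signature()] result.
#' @param quality_only Drop profiles whose `quality_flag` is `FALSE`
#'   (default `TRUE`, mirroring the restriction to high-quality "gold"
#'   perturbation signatures).
#' @param min_overlap Passed to [compute_rges()].
#' @return A data frame (one row per retained profile, in input order) with
#'   columns `profile_id`, `compound_id`, `cell_line`, `dose_um`, `time_h`,
#'   `es_up`, `es_down`, `rges`, `m_up`, `m_down`.
#' @export
batch_score <- function(pm, signature, quality_only = TRUE, min_overlap = 3) {
  stopifnot(inherits(pm, "profile_matrix"),
            inherits(signature, "disease_signature"))
  keep <- if (quality_only) pm$meta$quality_flag else rep(TRUE, nrow(pm$meta))
  if (!any(keep)) {
    stop("no profiles left after quality filtering", call. = FALSE)
  }
  if (quality_only && any(!pm$meta$quality_flag)) {
    rges_log("dropping %d low-quality profile(s) of %d",
             sum(!pm$meta$quality_flag), nrow(pm$meta))
  }
  meta <- pm$meta[keep, , drop = FALSE]
  overlap <- signature_overlap(signature, rownames(pm$values), min_overlap)
  recs <- lapply(meta$profile_id, function(id) {
    ranked <- rank_profile(pm$values[, id])
    rges_from_ranked(ranked, signature, min_overlap, overlap = overlap)
  })
  out <- data.frame(
    profile_id = meta$profile_id,
    compound_id = meta$compound_id,
    cell_line = meta$cell_line,
    dose_um = meta$dose_um,
    time_h = meta$time_h,
    es_up = vapply(recs, `[[`, numeric(1), "es_up"),
    es_down = vapply(recs, `[[`, numeric(1), "es_down"),
    rges = vapply(recs, `[[`, numeric(1), "rges"),
    m_up = vapply(recs, `[[`, integer(1), "m_up"),
    m_down = vapply(recs, `[[`, integer(1), "m_down"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Correlation-type reversal similarity between a profile and a signature
#'
#' Alternative to the rank-enrichment RGES: Spearman or Pearson correlation,
#' or cosine similarity, between the profile's differential-expression
#' values and the signature's log2 fold changes over the signature genes.
#' Negative values indicate reversal.
#'
#' @inheritParams compute_rges
#' @param method One of `"spearman"`, `"pearson"`, `"cosine"`.
#' @return A single numeric in \[-1, 1\].
#' @export
similarity_score <- function(values, signature,
                             method = c("spearman", "pearson", "cosine")) {
  method <- match.arg(method)
  stopifnot(inherits(signature, "disease_signature"))
  genes <- intersect(signature$stats$gene, names(values))
  if (length(genes) < 3) {
    stop("fewer than 3 signature genes present in the profile", call. = FALSE)
  }
  x <- unname(values[genes])
  y <- signature$stats$log2fc[match(genes, signature$stats$gene)]
  if (any(!is.finite(x))) stop("non-finite profile values", call. = FALSE)
  if (method == "cosine") {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) {
      stop("zero-norm vector: cosine similarity undefined", call. = FALSE)
    }
    return(sum(x * y) / (nx * ny))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance vector: ", method, " correlation undefined",
         call. = FALSE)
  }
  stats::cor(x, y, method = method)
}

#' Permutation P value for an observed RGES
#'
#' Gene-set permutation null: random up/down sets of the observed sizes are
#' drawn from the universe and rescored against the same ranking; the
#' two-sided P value is the fraction of permuted |RGES| at least as extreme
#' as the observed |RGES| (with the add-one correction so P is never zero).
#'
#' @inheritParams compute_rges
#' @param n_perm Number of permutations (at least 100; default 10000).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return A list with `rges`, `p`, `n_perm`.
#' @export
rges_pvalue <- function(values, signature, n_perm = 10000, seed = NULL,
                        min_overlap = 3) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  obs <- compute_rges(values, signature, min_overlap)
  ranked <- rank_profile(values)
  pos <- unname(unclass(ranked))
  n <- attr(ranked, "n")
  m_up <- obs$m_up; m_down <- obs$m_down
  if (m_up + m_down > n) {
    stop("signature larger than the universe", call. = FALSE)
  }
  target <- abs(obs$rges)
  n_extreme <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pick <- sample.int(n, m_up + m_down)
      es_u <- ks_es(sort(pos[pick[seq_len(m_up)]]), n)
      es_d <- ks_es(sort(pos[pick[(m_up + 1):(m_up + m_down)]]), n)
      if (abs(es_u - es_d) >= target) hits <- hits + 1L
    }
    hits
  })
  list(rges = obs$rges, p = (1 + n_extreme) / (n_perm + 1), n_perm = n_perm)
}

#' Write an RGES score table
#'
#' Tab-separated `profile_id  compound_id  cell_line  dose_um  time_h
#' es_up  es_down  rges` (plus overlap counts).
#'
#' @param scores A [batch_score()] result.
#' @param path Output path.
#' @export
write_rges_table <- function(scores, path) {
  require_columns(scores, c("profile_id", "compound_id", "cell_line",
                            "dose_um", "time_h", "rges"), "RGES table")
  write_tsv_atomic(scores, path)
}

#' @rdname write_rges_table
#' @export
read_rges_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("profile_id", "compound_id", "cell_line",
                         "dose_um", "time_h", "rges"), "RGES table")
  tab
}
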
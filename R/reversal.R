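# One-sided Mann-Whitney-Wilcoxon p for x (effective group) vs y.
# Exact via the null Wilcoxon distribution when the total sample is small
# (<= exact_max_n) and tie-free; otherwise normal approximation with the
# mid-rank tie correction and no continuity correction.
#' @keywords internal
mww_onesided <- function(x, y, alternative = c("greater", "less"),
                         exact_max_n = 20) {
  alternative <- match.arg(alternative)
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (N <= exact_max_n && !ties) {
    p <- if (alternative == "greater") {
      stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    } else {
      stats::pwilcox(U, m, n)
    }
  } else {
    tt <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1  # every observation identical: no evidence either way
    } else {
      z <- (U - m * n / 2) / sqrt(sigma2)
      p <- if (alternative == "greater") {
        stats::pnorm(z, lower.tail = FALSE)
      } else {
        stats::pnorm(z)
      }
    }
  }
  list(u = U, p = p)
}

#' Group compounds into effective / ineffective by median IC50
#'
#' Each compound's IC50 measurements are summarized by the lower-middle
#' median (for even counts, the lower of the two central values) and the
#' compound is labelled `effective` when that median is strictly below the
#' activity threshold, `ineffective` otherwise. The default threshold of
#' 10 micromolar is the usual primary-screening activity cutoff.
#'
#' @param efficacy Data frame with columns `compound_id`, `ic50_um`
#'   (optionally `cell_line`); all IC50 values must be positive.
#' @param threshold_um Activity threshold in micromolar (default 10).
#' @return An `efficacy_groups` object: list with named `median_ic50` and
#'   `labels` (`"effective"` / `"ineffective"`).
#' @examples
#' eff <- data.frame(compound_id = c("a", "a", "b"), ic50_um = c(3, 30, 10))
#' summarize_efficacy(eff)$labels  # a: effective, b: ineffective
#' @export
summarize_efficacy <- function(efficacy, threshold_um = 10) {
  require_columns(efficacy, c("compound_id", "ic50_um"), "efficacy table")
  if (nrow(efficacy) == 0) stop("efficacy table is empty", call. = FALSE)
  if (any(!is.finite(efficacy$ic50_um)) || any(efficacy$ic50_um <= 0)) {
    stop("ic50_um must be positive and finite", call. = FALSE)
  }
  med <- vapply(split(efficacy$ic50_um, efficacy$compound_id),
                median_low, numeric(1))
  labels <- ifelse(med < threshold_um, "effective", "ineffective")
  structure(list(median_ic50 = med,
                 labels = stats::setNames(labels, names(med)),
                 threshold_um = threshold_um),
            class = "efficacy_groups")
}

#' @export
print.efficacy_groups <- function(x, ...) {
  cat(sprintf("<efficacy_groups> %d effective / %d ineffective (threshold %g uM)\n",
              sum(x$labels == "effective"), sum(x$labels == "ineffective"),
              x$threshold_um))
  invisible(x)
}

#' Pick one representative profile per compound by median RGES
#'
#' For compounds profiled several times, the representative is the profile
#' whose RGES equals the lower-middle median of the compound's RGES values;
#' among equal scores the lexicographically smallest `profile_id` wins, so
#' the choice is deterministic.
#'
#' @param rges_table A [batch_score()] result.
#' @return Data frame `compound_id, profile_id, rges` (one row per compound).
#' @export
select_representative_profiles <- function(rges_table) {
  require_columns(rges_table, c("profile_id", "compound_id", "rges"),
                  "RGES table")
  if (nrow(rges_table) == 0) stop("RGES table is empty", call. = FALSE)
  idx <- split(seq_len(nrow(rges_table)), rges_table$compound_id)
  rows <- lapply(names(idx), function(cmpd) {
    i <- idx[[cmpd]]
    med <- median_low(rges_table$rges[i])
    cand <- i[rges_table$rges[i] == med]
    pick <- cand[order(rges_table$profile_id[cand], method = "radix")[1]]
    data.frame(compound_id = cmpd, profile_id = rges_table$profile_id[pick],
               rges = rges_table$rges[pick], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalized post-treatment positions of signature genes
#'
#' For each selected profile, each signature gene's rank (1 = most
#' upregulated) divided by the universe size, giving a value in (0, 1]:
#' small means the gene sits near the top (upregulated end) after
#' treatment, large means near the bottom.
#'
#' @param pm A [profile_matrix()].
#' @param signature A [build_signature()] result.
#' @param representatives A [select_representative_profiles()] result (or
#'   any data frame with `compound_id`, `profile_id`); `NULL` scores every
#'   profile, with profile ids as column names.
#' @return Numeric matrix signature-genes x compounds of normalized
#'   positions; genes absent from the profile universe are dropped with a
#'   warning.
#' @export
normalized_positions <- function(pm, signature, representatives = NULL) {
  stopifnot(inherits(pm, "profile_matrix"),
            inherits(signature, "disease_signature"))
  genes <- signature$stats$gene
  present <- genes %in% rownames(pm$values)
  if (!all(present)) {
    warning("dropping ", sum(!present),
            " signature gene(s) absent from the profile universe",
            call. = FALSE)
    genes <- genes[present]
  }
  if (length(genes) == 0) {
    stop("no signature genes present in the profile universe", call. = FALSE)
  }
  if (is.null(representatives)) {
    ids <- pm$meta$profile_id
    cols <- ids
  } else {
    require_columns(representatives, c("compound_id", "profile_id"),
                    "representatives table")
    ids <- representatives$profile_id
    missing <- setdiff(ids, pm$meta$profile_id)
    if (length(missing) > 0) {
      stop("representative profile(s) not in the matrix: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    cols <- representatives$compound_id
  }
  n <- nrow(pm$values)
  mat <- vapply(ids, function(id) {
    unclass(rank_profile(pm$values[, id]))[genes] / n
  }, numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, cols))
  mat
}

#' Test signature genes for differential rank between compound groups
#'
#' A disease-upregulated gene is reversed when effective compounds push it
#' toward the bottom of the ranking, i.e. its normalized positions are
#' stochastically greater in the effective group; a downregulated gene is
#' reversed when effective compounds pull it toward the top (positions
#' stochastically smaller). Each signature gene gets the corresponding
#' one-sided Mann-Whitney-Wilcoxon test and P values are
#' Benjamini-Hochberg-adjusted across all tested genes; genes with adjusted
#' P below `alpha` are flagged.
#'
#' Note the direction convention: because rank 1 is the most upregulated
#' gene, "pushed down by treatment" means a *larger* normalized position.
#'
#' @param positions Matrix from [normalized_positions()] (genes x compounds).
#' @param labels An [summarize_efficacy()] result, or a named character
#'   vector of `"effective"`/`"ineffective"` per compound.
#' @param signature A [build_signature()] result (provides gene directions).
#' @param alpha Adjusted-P cutoff for the reversal flag (default 0.25).
#' @param exact_max_n Largest total group size for the exact test
#'   (default 20).
#' @return Data frame `gene, direction, u_stat, p, padj, reversal`.
#' @export
test_reversal <- function(positions, labels, signature, alpha = 0.25,
                          exact_max_n = 20) {
  stopifnot(inherits(signature, "disease_signature"))
  if (inherits(labels, "efficacy_groups")) labels <- labels$labels
  compounds <- colnames(positions)
  missing <- setdiff(compounds, names(labels))
  if (length(missing) > 0) {
    stop("no efficacy label for compound(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  lab <- labels[compounds]
  eff <- compounds[lab == "effective"]
  ineff <- compounds[lab == "ineffective"]
  if (length(eff) < 2 || length(ineff) < 2) {
    stop("each group needs at least 2 compounds (effective: ", length(eff),
         ", ineffective: ", length(ineff), ")", call. = FALSE)
  }
  genes <- rownames(positions)
  dir <- ifelse(genes %in% signature$up, "up",
                ifelse(genes %in% signature$down, "down", NA_character_))
  if (anyNA(dir)) {
    stop("positions contain genes outside the signature", call. = FALSE)
  }
  res <- lapply(seq_along(genes), function(i) {
    mww_onesided(positions[i, eff], positions[i, ineff],
                 alternative = if (dir[i] == "up") "greater" else "less",
                 exact_max_n = exact_max_n)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = genes, direction = dir,
             u_stat = vapply(res, `[[`, numeric(1), "u"),
             p = p, padj = padj, reversal = padj < alpha,
             stringsAsFactors = FALSE)
}

#' Reversal genes robust to leaving any one compound out
#'
#' Repeats [test_reversal()] once on the full compound set and once with
#' each compound (from either group) left out; a gene is `robust` only when
#' it is flagged as a reversal gene in the full set and in every
#' leave-one-compound-out trial. Full-set statistics are reported.
#'
#' @inheritParams test_reversal
#' @return The full-set [test_reversal()] data frame plus a logical
#'   `robust` column (always a subset of the full-set `reversal` flags).
#' @export
loco_reversal_genes <- function(positions, labels, signature, alpha = 0.25,
                                exact_max_n = 20) {
  if (inherits(labels, "efficacy_groups")) labels <- labels$labels
  compounds <- colnames(positions)
  lab <- labels[compounds]
  if (sum(lab == "effective", na.rm = TRUE) < 3 ||
      sum(lab == "ineffective", na.rm = TRUE) < 3) {
    stop("leave-one-compound-out needs at least 3 compounds per group",
         call. = FALSE)
  }
  full <- test_reversal(positions, labels, signature, alpha, exact_max_n)
  robust <- full$reversal
  for (cmpd in compounds) {
    trial <- test_reversal(positions[, setdiff(compounds, cmpd), drop = FALSE],
                           labels, signature, alpha, exact_max_n)
    robust <- robust & trial$reversal
  }
  full$robust <- robust
  full
}

#' Read an efficacy table / write reversal-gene results
#'
#' Efficacy input is tab-separated `compound_id  cell_line  ic50_um`
#' (`cell_line` optional); results are written as
#' `gene  direction  u_stat  p  padj  reversal [robust]`.
#'
#' @param path File path.
#' @export
read_efficacy <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("compound_id", "ic50_um"), "efficacy table")
  tab
}

#' @rdname read_efficacy
#' @param results A [test_reversal()] or [loco_reversal_genes()] result.
#' @export
write_reversal_results <- function(results, path) {
  require_columns(results, c("gene", "direction", "u_stat", "p", "padj"),
                  "reversal results")
  write_tsv_atomic(results, path)
}
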
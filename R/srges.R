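# Condition bins: dose is classed at the reference dose (default 10 uM) and
# treatment duration at the reference time (default 24 h); boundary values
# fall on the reference side, so the reference condition maps to "high_long".

#' All condition bins / the reference bin
#' @param ref_dose,ref_time Reference dose (micromolar) and duration (hours).
#' @return Character vector of bin labels / the reference bin label.
#' @export
condition_bins <- function() c("high_long", "high_short", "low_long", "low_short")

#' @rdname condition_bins
#' @export
reference_bin <- function() "high_long"

#' Assign assay conditions to dose/time bins
#'
#' Profiles are grouped by whether their dose and treatment duration reach
#' the reference assay condition (10 micromolar, 24 hours — the most common
#' condition in LINCS-style screens). Both thresholds are inclusive on the
#' reference side: (10, 24) is `high_long`, the reference bin.
#'
#' @param dose_um Numeric vector of doses (micromolar), `>= 0`.
#' @param time_h Numeric vector of treatment durations (hours), `> 0`.
#' @inheritParams condition_bins
#' @return Character vector of bin labels (`"high_long"`, `"high_short"`,
#'   `"low_long"`, `"low_short"`).
#' @examples
#' assign_bin(c(10, 5, 20), c(24, 6, 6))
#' @export
assign_bin <- function(dose_um, time_h, ref_dose = 10, ref_time = 24) {
  if (any(dose_um < 0)) stop("dose_um must be >= 0", call. = FALSE)
  if (any(time_h <= 0)) stop("time_h must be > 0", call. = FALSE)
  paste(ifelse(dose_um >= ref_dose, "high", "low"),
        ifelse(time_h >= ref_time, "long", "short"), sep = "_")
}

#' Estimate additive condition offsets toward the reference condition
#'
#' Reversal strength depends on dose and treatment duration, so scores from
#' different assay conditions are not directly comparable. For each
#' non-reference bin the offset is estimated from compounds profiled in the
#' same cell line under both the reference condition and that bin: the mean,
#' over such (compound, cell line) pairs, of (mean reference-bin RGES minus
#' mean target-bin RGES). Adding the offset to a target-bin RGES moves it
#' onto the reference-condition scale.
#'
#' @param rges_table A data frame as returned by [batch_score()] (columns
#'   `compound_id`, `cell_line`, `dose_um`, `time_h`, `rges`).
#' @param min_pairs Minimum number of paired (compound, cell line)
#'   observations required per bin; below it the offset is set to 0 with a
#'   warning (default 10).
#' @inheritParams condition_bins
#' @return A `condition_offsets` object: list with named numeric `offset`
#'   (all bins, reference fixed at 0) and integer `support`.
#' @export
estimate_offsets <- function(rges_table, min_pairs = 10,
                             ref_dose = 10, ref_time = 24) {
  require_columns(rges_table, c("compound_id", "cell_line", "dose_um",
                                "time_h", "rges"), "RGES table")
  bin <- assign_bin(rges_table$dose_um, rges_table$time_h, ref_dose, ref_time)
  key <- paste(rges_table$compound_id, rges_table$cell_line, sep = "\r")
  cell_means <- tapply(rges_table$rges, list(key = key, bin = bin), mean)
  ref <- reference_bin()
  have_ref <- !is.na(cell_means[, ref, drop = TRUE])

  offset <- stats::setNames(numeric(4), condition_bins())
  support <- stats::setNames(integer(4), condition_bins())
  any_pairs <- FALSE
  for (b in setdiff(condition_bins(), ref)) {
    if (!b %in% colnames(cell_means)) next
    paired <- have_ref & !is.na(cell_means[, b])
    support[b] <- sum(paired)
    if (support[b] > 0) {
      any_pairs <- TRUE
      offset[b] <- mean(cell_means[paired, ref] - cell_means[paired, b])
    }
  }
  if (!any_pairs) {
    stop(paste0("no (compound, cell line) pair spans the reference and a ",
                "target condition; use zero offsets"), call. = FALSE)
  }
  seen <- intersect(setdiff(condition_bins(), ref), unique(bin))
  weakly_supported <- seen[support[seen] < min_pairs]
  if (length(weakly_supported) > 0) {
    offset[weakly_supported] <- 0
    warning("offset support below ", min_pairs, " pair(s) for bin(s) ",
            paste(weakly_supported, collapse = ", "),
            "; offset forced to 0", call. = FALSE)
  }
  unseen <- setdiff(setdiff(condition_bins(), ref), seen)
  if (length(unseen) > 0) {
    rges_log("no profiles observed in bin(s) %s; offset fixed at 0",
             paste(unseen, collapse = ", "))
  }
  structure(list(offset = offset, support = support,
                 ref_dose = ref_dose, ref_time = ref_time),
            class = "condition_offsets")
}

#' @export
print.condition_offsets <- function(x, ...) {
  cat("<condition_offsets> (reference:", reference_bin(), ")\n")
  print(data.frame(bin = names(x$offset), offset = unname(x$offset),
                   support = unname(x$support)), row.names = FALSE)
  invisible(x)
}

#' Cell-line weights from transcriptional similarity to tumours
#'
#' Each cell line's raw score is the average rank correlation between its
#' expression profile and each individual tumour sample over the shared
#' genes. Negative averages are clamped to zero and the scores are divided
#' by their maximum, so weights lie in \[0, 1\] with the best-matched cell
#' line at exactly 1.
#'
#' @param cell_expr Numeric matrix genes x cell lines.
#' @param tumour_expr Numeric matrix genes x tumour samples.
#' @param method Correlation method (rank correlation; `"spearman"`).
#' @return A `cell_weight_table`: list with named `weight` and `raw_cor`.
#' @export
compute_cell_weights <- function(cell_expr, tumour_expr,
                                 method = c("spearman")) {
  method <- match.arg(method)
  shared <- intersect(rownames(cell_expr), rownames(tumour_expr))
  if (length(shared) < 3) {
    stop("fewer than 3 shared genes between cell lines and tumours",
         call. = FALSE)
  }
  if (is.null(ncol(tumour_expr)) || ncol(tumour_expr) < 1) {
    stop("at least one tumour sample required", call. = FALSE)
  }
  cmat <- stats::cor(cell_expr[shared, , drop = FALSE],
                     tumour_expr[shared, , drop = FALSE], method = method)
  raw <- rowMeans(cmat)
  clamped <- pmax(raw, 0)
  mx <- max(clamped)
  if (mx <= 0) {
    stop("all cell line-tumour correlations are non-positive; ",
         "weights are undefined", call. = FALSE)
  }
  structure(list(weight = clamped / mx, raw_cor = raw, method = method),
            class = "cell_weight_table")
}

#' @export
print.cell_weight_table <- function(x, ...) {
  cat("<cell_weight_table>\n")
  print(data.frame(cell_line = names(x$weight), raw_cor = unname(x$raw_cor),
                   weight = unname(x$weight)), row.names = FALSE)
  invisible(x)
}

#' Summarize per-profile RGES into one sRGES per compound
#'
#' The default (`"weighted"`) strategy condition-normalizes each profile's
#' RGES by adding its bin offset and takes the cell-line-weighted mean:
#' `sRGES = sum_i w(cell_i) (RGES_i + offset(bin_i)) / sum_i w(cell_i)`.
#' Alternative per-compound summaries of the raw RGES are provided for
#' benchmarking: `"best"` (minimum, i.e. most reversing), `"median"`
#' (lower-middle), `"mean"`.
#'
#' @param rges_table A [batch_score()] result.
#' @param offsets Optional [estimate_offsets()] result; `NULL` means zero
#'   offsets (profiles treated as already comparable).
#' @param weights Optional [compute_cell_weights()] result; `NULL` means
#'   unit weights. Profiles in cell lines missing from the table receive the
#'   mean available weight, with a warning.
#' @param strategy One of `"weighted"`, `"best"`, `"median"`, `"mean"`.
#' @return A data frame `compound_id, srges, n_profiles, n_cell_lines`
#'   sorted ascending by `srges` (most reversing first).
#' @export
summarize_srges <- function(rges_table, offsets = NULL, weights = NULL,
                            strategy = c("weighted", "best", "median", "mean")) {
  strategy <- match.arg(strategy)
  require_columns(rges_table, c("compound_id", "cell_line", "dose_um",
                                "time_h", "rges"), "RGES table")
  if (nrow(rges_table) == 0) stop("RGES table is empty", call. = FALSE)

  if (strategy == "weighted") {
    if (is.null(offsets)) {
      off <- stats::setNames(numeric(4), condition_bins())
      ref_dose <- 10; ref_time <- 24
    } else {
      stopifnot(inherits(offsets, "condition_offsets"))
      off <- offsets$offset
      ref_dose <- offsets$ref_dose; ref_time <- offsets$ref_time
    }
    bin <- assign_bin(rges_table$dose_um, rges_table$time_h,
                      ref_dose, ref_time)
    adj <- rges_table$rges + off[bin]
    if (is.null(weights)) {
      w <- rep(1, nrow(rges_table))
    } else {
      stopifnot(inherits(weights, "cell_weight_table"))
      w <- unname(weights$weight[rges_table$cell_line])
      if (anyNA(w)) {
        missing_cells <- unique(rges_table$cell_line[is.na(w)])
        warning("cell line(s) missing from the weight table (",
                paste(missing_cells, collapse = ", "),
                "); using the mean available weight", call. = FALSE)
        w[is.na(w)] <- mean(weights$weight)
      }
    }
  } else {
    adj <- rges_table$rges
    w <- rep(1, nrow(rges_table))
  }

  idx <- split(seq_len(nrow(rges_table)), rges_table$compound_id)
  rows <- lapply(names(idx), function(cmpd) {
    i <- idx[[cmpd]]
    s <- switch(strategy,
      weighted = {
        sw <- sum(w[i])
        if (sw == 0) {
          warning("all weights zero for compound ", cmpd,
                  "; falling back to the unweighted mean", call. = FALSE)
          mean(adj[i])
        } else sum(w[i] * adj[i]) / sw
      },
      best = min(adj[i]),
      median = median_low(adj[i]),
      mean = mean(adj[i])
    )
    data.frame(compound_id = cmpd, srges = s, n_profiles = length(i),
               n_cell_lines = length(unique(rges_table$cell_line[i])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$srges, out$compound_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize condition offsets and cell weights
#'
#' Tab-separated key/value tables: offsets as `bin  offset  support`,
#' weights as `cell_line  raw_cor  weight`.
#'
#' @param offsets,weights Objects from [estimate_offsets()] /
#'   [compute_cell_weights()].
#' @param path File path.
#' @export
write_offsets <- function(offsets, path) {
  stopifnot(inherits(offsets, "condition_offsets"))
  write_tsv_atomic(data.frame(bin = names(offsets$offset),
                              offset = fmt_double(unname(offsets$offset)),
                              support = unname(offsets$support)), path)
}

#' @rdname write_offsets
#' @inheritParams condition_bins
#' @export
read_offsets <- function(path, ref_dose = 10, ref_time = 24) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("bin", "offset", "support"), "offsets table")
  structure(list(
    offset = stats::setNames(as.numeric(tab$offset), tab$bin),
    support = stats::setNames(as.integer(tab$support), tab$bin),
    ref_dose = ref_dose, ref_time = ref_time
  ), class = "condition_offsets")
}

#' @rdname write_offsets
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "cell_weight_table"))
  write_tsv_atomic(data.frame(cell_line = names(weights$weight),
                              raw_cor = fmt_double(unname(weights$raw_cor)),
                              weight = fmt_double(unname(weights$weight))),
                   path)
}

#' @rdname write_offsets
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("cell_line", "raw_cor", "weight"), "weights table")
  structure(list(
    weight = stats::setNames(as.numeric(tab$weight), tab$cell_line),
    raw_cor = stats::setNames(as.numeric(tab$raw_cor), tab$cell_line),
    method = "spearman"
  ), class = "cell_weight_table")
}
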
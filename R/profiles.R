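#' Drug perturbation profile matrix
#'
#' Container for a collection of perturbation expression profiles over a
#' common gene universe: a genes-by-profiles matrix of differential-expression
#' values plus one row of assay metadata per profile (compound, cell line,
#' dose in micromolar, treatment duration in hours, and a quality flag in the
#' spirit of the L1000 "gold" annotation).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   profiles in columns (colnames = profile ids). Every profile must cover
#'   the full universe: missing values are an error.
#' @param meta Data frame with columns `profile_id`, `compound_id`,
#'   `cell_line`, `dose_um`, `time_h`, `quality_flag`; one row per column of
#'   `values`, matched by `profile_id`.
#' @param universe Optional [gene_universe()]; defaults to the row order of
#'   `values`.
#' @return A `profile_matrix` object: list with `values`, `meta`, `universe`.
#' @export
profile_matrix <- function(values, meta, universe = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (genes x profiles)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and profile colnames", call. = FALSE)
  }
  if (ncol(values) < 1) stop("profile matrix has no profiles", call. = FALSE)
  if (anyNA(values)) {
    stop("profiles must cover the full universe: missing values found",
         call. = FALSE)
  }
  if (is.null(universe)) universe <- gene_universe(rownames(values))
  if (!identical(as.character(universe), rownames(values))) {
    if (!setequal(as.character(universe), rownames(values))) {
      stop("values rownames do not match the universe", call. = FALSE)
    }
    values <- values[as.character(universe), , drop = FALSE]
  }
  require_columns(meta, c("profile_id", "compound_id", "cell_line",
                          "dose_um", "time_h", "quality_flag"),
                  "profile metadata")
  meta$profile_id <- as.character(meta$profile_id)
  if (anyDuplicated(meta$profile_id)) {
    stop("profile_id must be unique", call. = FALSE)
  }
  if (!setequal(meta$profile_id, colnames(values))) {
    stop("metadata profile_id does not match the value matrix columns",
         call. = FALSE)
  }
  meta <- meta[match(colnames(values), meta$profile_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(meta$dose_um < 0)) stop("dose_um must be >= 0", call. = FALSE)
  if (any(meta$time_h <= 0)) stop("time_h must be > 0", call. = FALSE)
  meta$quality_flag <- as.logical(meta$quality_flag)
  if (anyNA(meta$quality_flag)) {
    stop("quality_flag must be interpretable as logical", call. = FALSE)
  }
  structure(list(values = values, meta = meta, universe = universe),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "<profile_matrix> %d genes x %d profiles (%d compounds, %d cell lines, %d high-quality)\n",
    nrow(x$values), ncol(x$values), length(unique(x$meta$compound_id)),
    length(unique(x$meta$cell_line)), sum(x$meta$quality_flag)))
  invisible(x)
}

#' Read / write a profile matrix as delimited text
#'
#' The value matrix is tab-separated with a `gene` first column and one
#' column per profile; the metadata sidecar is tab-separated with columns
#' `profile_id  compound_id  cell_line  dose_um  time_h  quality_flag`.
#'
#' @param values_path,meta_path Paths to the value matrix and metadata table.
#' @param universe Optional [gene_universe()] to validate against.
#' @return A [profile_matrix()].
#' @export
read_profile_matrix <- function(values_path, meta_path, universe = NULL) {
  for (p in c(values_path, meta_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  tab <- utils::read.delim(values_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene") {
    stop("profile value matrix must have a 'gene' first column", call. = FALSE)
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$gene
  storage.mode(values) <- "double"
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  profile_matrix(values, meta, universe)
}

#' @rdname read_profile_matrix
#' @param pm A [profile_matrix()].
#' @export
write_profile_matrix <- function(pm, values_path, meta_path) {
  stopifnot(inherits(pm, "profile_matrix"))
  tab <- data.frame(gene = rownames(pm$values), pm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_atomic(tab, values_path)
  write_tsv_atomic(pm$meta, meta_path)
  invisible(c(values_path, meta_path))
}

#' Read a GCT v1.3 text matrix as a profile matrix
#'
#' Parses the `#1.3` text flavour of the GCT format (value matrix plus row
#' and column annotations) and maps column annotations onto the assay
#' metadata fields used throughout the package. The default mapping follows
#' LINCS-style annotation keys (`pert_iname`, `cell_id`, `pert_dose`,
#' `pert_time`, `is_gold`).
#'
#' @param path Path to a GCT v1.3 text file.
#' @param meta_fields Named character vector mapping the metadata fields
#'   `compound_id`, `cell_line`, `dose_um`, `time_h`, `quality_flag` to
#'   column-annotation names in the file.
#' @return A [profile_matrix()].
#' @export
read_gct <- function(path,
                     meta_fields = c(compound_id = "pert_iname",
                                     cell_line = "cell_id",
                                     dose_um = "pert_dose",
                                     time_h = "pert_time",
                                     quality_flag = "is_gold")) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 2)
  if (length(header) < 2 || !startsWith(trimws(header[1]), "#1.3")) {
    stop("not a GCT v1.3 file (missing '#1.3' header): ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(trimws(header[2]), "\t")[[1]])
  if (length(dims) != 4 || anyNA(dims)) {
    stop("malformed GCT dimension line", call. = FALSE)
  }
  n_rows <- dims[1]; n_cols <- dims[2]; n_rhd <- dims[3]; n_chd <- dims[4]

  body <- utils::read.delim(path, skip = 2, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (ncol(body) != 1 + n_rhd + n_cols || nrow(body) != n_chd + n_rows) {
    stop("GCT body does not match the declared dimensions", call. = FALSE)
  }
  profile_ids <- names(body)[(1 + n_rhd + 1):ncol(body)]

  col_ann <- body[seq_len(n_chd), , drop = FALSE]
  ann <- as.data.frame(t(as.matrix(col_ann[, profile_ids, drop = FALSE])),
                       stringsAsFactors = FALSE)
  names(ann) <- col_ann[[1]]

  data_rows <- body[(n_chd + 1):nrow(body), , drop = FALSE]
  values <- as.matrix(data_rows[, profile_ids, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- data_rows[[1]]
  colnames(values) <- profile_ids

  missing_ann <- setdiff(unname(meta_fields), names(ann))
  if (length(missing_ann) > 0) {
    stop("GCT column annotations lack field(s): ",
         paste(missing_ann, collapse = ", "),
         "; provide a sidecar metadata table instead", call. = FALSE)
  }
  meta <- data.frame(
    profile_id = profile_ids,
    compound_id = ann[[meta_fields[["compound_id"]]]],
    cell_line = ann[[meta_fields[["cell_line"]]]],
    dose_um = as.numeric(ann[[meta_fields[["dose_um"]]]]),
    time_h = as.numeric(ann[[meta_fields[["time_h"]]]]),
    quality_flag = ann[[meta_fields[["quality_flag"]]]] %in%
      c("1", "TRUE", "true", "T"),
    stringsAsFactors = FALSE
  )
  if (anyNA(meta$dose_um) || anyNA(meta$time_h)) {
    stop("GCT dose/time annotations are not numeric", call. = FALSE)
  }
  profile_matrix(values, meta)
}
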
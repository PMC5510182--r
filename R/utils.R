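# Internal helpers shared across modules.

#' @keywords internal
rges_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

# Lower-middle median: for even counts, the lower of the two central values.
# Fixed (rather than interpolating) so profile/compound selections are
# bit-reproducible and always correspond to an observed value.
#' @keywords internal
median_low <- function(x) {
  stopifnot(length(x) >= 1)
  sort(x)[floor((length(x) + 1) / 2)]
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed uses the current stream.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Write a table atomically: a partially written file never replaces `path`.
#' @keywords internal
write_tsv_atomic <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  tmp <- tempfile(pattern = ".rges_tmp_", tmpdir = dir, fileext = ".tsv")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

# Format doubles so read.delim() recovers them bit-exactly.
#' @keywords internal
fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' @keywords internal
require_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
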
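# Shared fixtures and independent brute-force oracles.

quietly <- function(expr) suppressWarnings(suppressMessages(expr))

toy_universe <- function(n) gene_universe(sprintf("g%02d", seq_len(n)))

# A four-gene profile ranked g1 > g2 > g3 > g4.
toy_ranked4 <- function() rank_profile(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))

toy_signature <- function(up, down, universe) {
  genes <- c(up, down)
  de <- data.frame(gene = genes,
                   log2fc = c(rep(2, length(up)), rep(-2, length(down))),
                   padj = rep(1e-6, length(genes)))
  quietly(build_signature(de, universe))
}

# Brute-force KS-type enrichment maxima: explicit loops over j, independent
# of the implementation's vectorized form.
bf_enrichment <- function(positions, geneset, n) {
  V <- sort(positions[geneset])
  m <- length(V)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(m)) {
    a <- max(a, j / m - V[j] / n)
    b <- max(b, V[j] / n - (j - 1) / m)
  }
  if (a > b) a else -b
}

bf_rges <- function(values, up, down) {
  ord <- order(-values, names(values))
  pos <- integer(length(values))
  pos[ord] <- seq_along(values)
  names(pos) <- names(values)
  bf_enrichment(pos, up, length(values)) -
    bf_enrichment(pos, down, length(values))
}

# Exhaustive one-sided Mann-Whitney p by enumerating every assignment of the
# pooled observations to the first group.
bf_mww_p <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  m <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(length(vals), m)
  us <- apply(splits, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  if (alternative == "greater") mean(us >= u_obs) else mean(us <= u_obs)
}

# Small profile matrix: values is a genes x profiles matrix; metadata filled
# with reference-condition defaults unless overridden.
make_pm <- function(values, compound_id = NULL, cell_line = "CL1",
                    dose_um = 10, time_h = 24, quality_flag = TRUE) {
  ids <- colnames(values)
  if (is.null(compound_id)) compound_id <- ids
  meta <- data.frame(profile_id = ids, compound_id = compound_id,
                     cell_line = cell_line, dose_um = dose_um,
                     time_h = time_h, quality_flag = quality_flag,
                     stringsAsFactors = FALSE)
  profile_matrix(values, meta)
}

# Hand-built normalization state for summarization tests.
make_offsets <- function(high_short = 0, low_long = 0, low_short = 0) {
  off <- c(high_long = 0, high_short = high_short, low_long = low_long,
           low_short = low_short)
  structure(list(offset = off,
                 support = stats::setNames(rep(100L, 4), names(off)),
                 ref_dose = 10, ref_time = 24),
            class = "condition_offsets")
}

make_weights <- function(...) {
  w <- c(...)
  structure(list(weight = w, raw_cor = w, method = "spearman"),
            class = "cell_weight_table")
}
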
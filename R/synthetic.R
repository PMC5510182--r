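#' Configuration for a synthetic signature-reversal study
#'
#' Defines the generating conditions for a complete in-silico study: a
#' landmark-sized gene universe, a disease signature of planted up/down
#' genes, perturbation profiles for effective and ineffective compounds in
#' several cell lines under a 2x2 grid of dose/time conditions, matching
#' IC50 tables, and cell-line/tumour expression matrices. All planted
#' structure is recorded as ground truth.
#'
#' Reversal is parameterized directly in normalized rank units: in an
#' effective compound's profile, each planted up-gene is shifted
#' `reversal_strength` toward the bottom of the ranking (and each planted
#' down-gene toward the top) relative to a standard-normal background.
#' Rank shifts (rather than expression effect sizes) are the natural scale
#' here because every downstream statistic is rank-based.
#'
#' @param n_genes Universe size (default 978, the landmark panel size).
#' @param n_up,n_down Signature genes per direction (default 50 each).
#' @param n_reversal_up,n_reversal_down How many signature genes effective
#'   compounds actually reverse (default: all of them). Setting these below
#'   `n_up`/`n_down` plants a subset of true reversal genes among otherwise
#'   inert signature genes.
#' @param n_effective,n_ineffective Compounds per efficacy group
#'   (default 30 each).
#' @param reversal_strength Mean normalized rank shift of planted genes in
#'   effective compounds' reference-condition profiles (default 0.3).
#' @param noise_sd Per-profile jitter of the realized rank shift
#'   (default 0.05).
#' @param condition_attenuation Named reduction of the planted shift in
#'   each non-reference condition bin, in rank units (default
#'   `c(high_short = 0.15, low_long = 0.10, low_short = 0.20)`): lower
#'   doses and shorter treatments weaken reversal.
#' @param cell_tumour_rho Named per-cell-line correlation to the shared
#'   tumour expression factor (default `c(CL1 = .9, CL2 = .7, CL3 = .5)`).
#' @param n_tumours Tumour samples to simulate (default 30).
#' @param tumour_noise_sd Independent noise added to each tumour sample on
#'   top of the shared factor (default 0.3).
#' @param ic50_a,ic50_b,ic50_sd Log-linear efficacy link: each compound's
#'   IC50 (micromolar) is `exp(ic50_a - ic50_b * strength + eps)` with
#'   lognormal noise `sd(eps) = ic50_sd` (defaults 3, 8, 0.5, placing the
#'   10 uM activity threshold between the two groups non-trivially).
#' @param frac_low_quality Fraction of profiles flagged low-quality
#'   (default 0.05).
#' @param seed Integer RNG seed (default 1).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 978, n_up = 50, n_down = 50,
                       n_reversal_up = NULL, n_reversal_down = NULL,
                       n_effective = 30, n_ineffective = 30,
                       reversal_strength = 0.3, noise_sd = 0.05,
                       condition_attenuation = c(high_short = 0.15,
                                                 low_long = 0.10,
                                                 low_short = 0.20),
                       cell_tumour_rho = c(CL1 = 0.9, CL2 = 0.7, CL3 = 0.5),
                       n_tumours = 30, tumour_noise_sd = 0.3,
                       ic50_a = 3, ic50_b = 8, ic50_sd = 0.5,
                       frac_low_quality = 0.05, seed = 1) {
  if (is.null(n_reversal_up)) n_reversal_up <- n_up
  if (is.null(n_reversal_down)) n_reversal_down <- n_down
  cfg <- list(n_genes = n_genes, n_up = n_up, n_down = n_down,
              n_reversal_up = n_reversal_up,
              n_reversal_down = n_reversal_down,
              n_effective = n_effective, n_ineffective = n_ineffective,
              reversal_strength = reversal_strength, noise_sd = noise_sd,
              condition_attenuation = condition_attenuation,
              cell_tumour_rho = cell_tumour_rho, n_tumours = n_tumours,
              tumour_noise_sd = tumour_noise_sd,
              ic50_a = ic50_a, ic50_b = ic50_b, ic50_sd = ic50_sd,
              frac_low_quality = frac_low_quality, seed = seed)
  counts <- c(n_genes, n_up, n_down, n_effective, n_ineffective, n_tumours)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (n_up + n_down >= n_genes) {
    stop("signature must be smaller than the universe", call. = FALSE)
  }
  if (n_reversal_up > n_up || n_reversal_down > n_down ||
      n_reversal_up < 0 || n_reversal_down < 0) {
    stop("planted reversal genes must be a subset of the signature",
         call. = FALSE)
  }
  if (reversal_strength < 0) {
    stop("reversal_strength must be >= 0", call. = FALSE)
  }
  if (1.3 * reversal_strength >= 0.95) {
    stop("infeasible config: reversal_strength pushes positions outside (0, 1]",
         call. = FALSE)
  }
  if (any(cell_tumour_rho < 0 | cell_tumour_rho > 1)) {
    stop("cell_tumour_rho must be in [0, 1]", call. = FALSE)
  }
  if (!all(sort(names(condition_attenuation)) %in%
           setdiff(condition_bins(), reference_bin()))) {
    stop("condition_attenuation must be named by non-reference bins",
         call. = FALSE)
  }
  if (frac_low_quality < 0 || frac_low_quality >= 1) {
    stop("frac_low_quality must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Representative (dose, time) for each condition bin.
#' @keywords internal
bin_conditions <- function() {
  data.frame(bin = c("high_long", "high_short", "low_long", "low_short"),
             dose_um = c(10, 10, 1, 1), time_h = c(24, 6, 24, 6),
             stringsAsFactors = FALSE)
}

#' Simulate cell-line and tumour expression with known similarity
#'
#' Tumour samples share a latent expression factor; each cell line is a
#' correlation-parameterized mixture `rho * factor +
#' sqrt(1 - rho^2) * noise`, so its expected (Pearson) correlation to the
#' factor is exactly `rho` and rank correlations increase monotonically
#' with `rho`.
#'
#' @param n_genes Number of genes.
#' @param rho_per_cell Named vector of mixture correlations in \[0, 1\].
#' @param n_tumours Number of tumour samples.
#' @param tumour_noise_sd Noise sd added to each tumour sample on top of
#'   the shared factor (0 makes tumours identical to the factor).
#' @param seed Optional seed (the caller's RNG stream is preserved).
#' @return List with `cell_expr` and `tumour_expr` (genes x samples).
#' @export
simulate_cell_expression <- function(n_genes, rho_per_cell, n_tumours,
                                     tumour_noise_sd = 0.3, seed = NULL) {
  if (any(rho_per_cell < 0 | rho_per_cell > 1)) {
    stop("rho must be in [0, 1]", call. = FALSE)
  }
  if (is.null(names(rho_per_cell))) {
    names(rho_per_cell) <- sprintf("CL%d", seq_along(rho_per_cell))
  }
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    f <- stats::rnorm(n_genes)
    tumour <- vapply(seq_len(n_tumours), function(i) {
      f + tumour_noise_sd * stats::rnorm(n_genes)
    }, numeric(n_genes))
    cells <- vapply(rho_per_cell, function(r) {
      r * f + sqrt(1 - r^2) * stats::rnorm(n_genes)
    }, numeric(n_genes))
    dimnames(tumour) <- list(genes, sprintf("T%03d", seq_len(n_tumours)))
    dimnames(cells) <- list(genes, names(rho_per_cell))
    list(cell_expr = cells, tumour_expr = tumour)
  })
}

#' Simulate a complete synthetic reversal study
#'
#' Generates, under one seed: the gene universe; a differential-expression
#' table whose planted up/down genes pass the signature filter; one profile
#' per compound x cell line x condition bin, with planted rank shifts for
#' the reversal genes of effective compounds (attenuated in non-reference
#' bins); per-compound, per-cell-line IC50 values tied to true reversal
#' strength by a lognormal link; and cell/tumour expression matrices with
#' known similarity. Ground truth (planted genes, strengths, attenuations,
#' expected weights) is returned alongside.
#'
#' @param cfg A [sim_config()].
#' @return An `rges_study` list: `profiles` ([profile_matrix()]),
#'   `signature`, `de_table`, `efficacy`, `cell_expr`, `tumour_expr`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    universe <- gene_universe(genes)

    up_genes <- genes[seq_len(cfg$n_up)]
    down_genes <- genes[cfg$n_up + seq_len(cfg$n_down)]
    null_genes <- setdiff(genes, c(up_genes, down_genes))
    de <- data.frame(
      gene = c(up_genes, down_genes, null_genes),
      log2fc = c(stats::runif(cfg$n_up, 1.8, 4),
                 -stats::runif(cfg$n_down, 1.8, 4),
                 stats::runif(length(null_genes), -1, 1)),
      padj = c(10^stats::runif(cfg$n_up + cfg$n_down, -12, -4),
               stats::runif(length(null_genes), 0.05, 1)),
      stringsAsFactors = FALSE
    )
    signature <- build_signature(de, universe)

    rev_up <- up_genes[seq_len(cfg$n_reversal_up)]
    rev_down <- down_genes[seq_len(cfg$n_reversal_down)]

    compounds <- c(sprintf("eff%03d", seq_len(cfg$n_effective)),
                   sprintf("ineff%03d", seq_len(cfg$n_ineffective)))
    group <- rep(c("effective", "ineffective"),
                 c(cfg$n_effective, cfg$n_ineffective))
    strength <- stats::setNames(c(
      cfg$reversal_strength * stats::runif(cfg$n_effective, 0.7, 1.3),
      cfg$reversal_strength * stats::runif(cfg$n_ineffective, 0, 0.1)
    ), compounds)

    cells <- names(cfg$cell_tumour_rho)
    conds <- bin_conditions()
    atten <- c(stats::setNames(0, reference_bin()), cfg$condition_attenuation)

    grid <- expand.grid(ci = seq_along(compounds), cl = cells,
                        bi = seq_len(nrow(conds)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n_prof <- nrow(grid)
    meta <- data.frame(
      profile_id = sprintf("p%05d", seq_len(n_prof)),
      compound_id = compounds[grid$ci],
      cell_line = grid$cl,
      dose_um = conds$dose_um[grid$bi],
      time_h = conds$time_h[grid$bi],
      quality_flag = stats::runif(n_prof) >= cfg$frac_low_quality,
      stringsAsFactors = FALSE
    )
    bins <- conds$bin[grid$bi]

    values <- matrix(stats::rnorm(cfg$n_genes * n_prof),
                     nrow = cfg$n_genes,
                     dimnames = list(genes, meta$profile_id))
    up_idx <- match(rev_up, genes)
    down_idx <- match(rev_down, genes)
    for (k in seq_len(n_prof)) {
      s0 <- strength[meta$compound_id[k]] - atten[bins[k]]
      shift <- max(0, s0) + stats::rnorm(1, 0, cfg$noise_sd)
      shift <- min(max(shift, 0), 0.95)
      if (shift > 0) {
        # planted genes: background uniform position, displaced by `shift`
        # (up-genes toward the bottom, down-genes toward the top), mapped
        # back to the value scale through the normal quantile function
        if (length(up_idx) > 0) {
          p1 <- pmin(stats::runif(length(up_idx)) + shift, 0.999)
          values[up_idx, k] <- stats::qnorm(1 - p1)
        }
        if (length(down_idx) > 0) {
          p1 <- pmax(stats::runif(length(down_idx)) - shift, 0.001)
          values[down_idx, k] <- stats::qnorm(1 - p1)
        }
      }
    }
    pm <- profile_matrix(values, meta, universe)

    efficacy <- data.frame(
      compound_id = rep(compounds, each = length(cells)),
      cell_line = rep(cells, times = length(compounds)),
      ic50_um = exp(cfg$ic50_a -
                      cfg$ic50_b * rep(unname(strength), each = length(cells)) +
                      stats::rnorm(length(compounds) * length(cells),
                                   0, cfg$ic50_sd)),
      stringsAsFactors = FALSE
    )

    expr <- simulate_cell_expression(cfg$n_genes, cfg$cell_tumour_rho,
                                     cfg$n_tumours, cfg$tumour_noise_sd)

    truth <- list(
      reversal_up = rev_up, reversal_down = rev_down,
      strength = strength, group = stats::setNames(group, compounds),
      condition_attenuation = cfg$condition_attenuation,
      cell_tumour_rho = cfg$cell_tumour_rho,
      expected_weights = cfg$cell_tumour_rho / max(cfg$cell_tumour_rho)
    )
    structure(list(profiles = pm, signature = signature, de_table = de,
                   efficacy = efficacy, cell_expr = expr$cell_expr,
                   tumour_expr = expr$tumour_expr, truth = truth,
                   config = cfg),
              class = "rges_study")
  })
}

#' @export
print.rges_study <- function(x, ...) {
  cat(sprintf(paste0("<rges_study> %d genes, %d profiles, %d+%d compounds, ",
                     "%d cell lines, seed %d\n"),
              nrow(x$profiles$values), ncol(x$profiles$values),
              x$config$n_effective, x$config$n_ineffective,
              length(x$config$cell_tumour_rho), x$config$seed))
  invisible(x)
}

#' Simulate an RGES table with exactly additive condition effects
#'
#' Generates paired reference/target-bin scores for (compound, cell line)
#' pairs where each non-reference bin elevates RGES by a fixed amount
#' (`bin_effects`, positive = weaker reversal than at the reference
#' condition) plus Gaussian noise. Because the planted structure is exactly
#' additive on the RGES scale, this is the generator for validating
#' [estimate_offsets()]: the adjustment it should recover is
#' `-bin_effects`, recorded as `true_offsets`.
#'
#' @param bin_effects Named elevation of mean RGES per non-reference bin
#'   (default `c(high_short = 0.15, low_long = 0.10, low_short = 0.20)`).
#' @param noise_sd Per-profile noise sd (default 0.05).
#' @param n_pairs Number of (compound, cell line) pairs, each with one
#'   reference profile and one profile per target bin (default 300).
#' @param base_mean,base_sd Distribution of the pair-level baseline RGES
#'   (defaults -0.3, 0.15).
#' @param seed Optional seed.
#' @return List with `rges` (a table accepted by [estimate_offsets()]) and
#'   `true_offsets`.
#' @export
simulate_offset_training <- function(bin_effects = c(high_short = 0.15,
                                                     low_long = 0.10,
                                                     low_short = 0.20),
                                     noise_sd = 0.05, n_pairs = 300,
                                     base_mean = -0.3, base_sd = 0.15,
                                     seed = NULL) {
  target_bins <- setdiff(condition_bins(), reference_bin())
  if (!all(names(bin_effects) %in% target_bins)) {
    stop("bin_effects must be named by non-reference bins", call. = FALSE)
  }
  conds <- bin_conditions()
  with_seed(seed, {
    rows <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      base <- stats::rnorm(1, base_mean, base_sd)
      bin_i <- c(reference_bin(), names(bin_effects))
      eff <- c(0, unname(bin_effects))
      ci <- match(bin_i, conds$bin)
      rows[[i]] <- data.frame(
        profile_id = sprintf("pair%04d_%s", i, bin_i),
        compound_id = sprintf("cmpd%04d", i),
        cell_line = "CL1",
        dose_um = conds$dose_um[ci],
        time_h = conds$time_h[ci],
        rges = base + eff + stats::rnorm(length(bin_i), 0, noise_sd),
        stringsAsFactors = FALSE
      )
    }
    list(rges = do.call(rbind, rows),
         true_offsets = c(stats::setNames(0, reference_bin()), -bin_effects))
  })
}

#' Write a simulated study to a directory of standard input files
#'
#' Emits every file the pipeline consumes — `universe.txt`,
#' `de_table.tsv`, `signature.tsv`, `profiles.tsv` + `profile_meta.tsv`,
#' `efficacy.tsv`, `cell_expr.tsv`, `tumour_expr.tsv` — plus `truth.json`
#' (ground truth) and `sim_config.yaml`.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "rges_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_universe(study$profiles$universe, file.path(dir, "universe.txt"))
  write_de_table(study$de_table, file.path(dir, "de_table.tsv"))
  write_signature(study$signature, file.path(dir, "signature.tsv"))
  write_profile_matrix(study$profiles, file.path(dir, "profiles.tsv"),
                       file.path(dir, "profile_meta.tsv"))
  write_tsv_atomic(study$efficacy, file.path(dir, "efficacy.tsv"))
  expr_df <- function(m) data.frame(gene = rownames(m), m,
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE)
  write_tsv_atomic(expr_df(study$cell_expr), file.path(dir, "cell_expr.tsv"))
  write_tsv_atomic(expr_df(study$tumour_expr),
                   file.path(dir, "tumour_expr.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(study$config)
  cfg$condition_attenuation <- as.list(cfg$condition_attenuation)
  cfg$cell_tumour_rho <- as.list(cfg$cell_tumour_rho)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
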
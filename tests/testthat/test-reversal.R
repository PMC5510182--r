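test_that("median IC50 grouping uses the lower-middle median and a strict threshold", {
  eff <- data.frame(compound_id = c("a", "a", "b", "c"),
                    ic50_um = c(3, 30, 10, 9.99))
  g <- summarize_efficacy(eff)
  expect_identical(unname(g$labels["a"]), "effective")    # median_low(3, 30) = 3
  expect_identical(unname(g$labels["b"]), "ineffective")  # 10 is not < 10
  expect_identical(unname(g$labels["c"]), "effective")
  expect_equal(unname(g$median_ic50["a"]), 3)
  expect_error(summarize_efficacy(data.frame(compound_id = "x", ic50_um = 0)),
               "positive")
})

test_that("the representative profile carries the (lower-middle) median RGES", {
  tab <- data.frame(profile_id = c("p3", "p1", "p2", "q2", "q1", "r1"),
                    compound_id = c("a", "a", "a", "b", "b", "c"),
                    rges = c(0.3, -0.5, -0.1, -0.2, -0.4, 0.7))
  reps <- select_representative_profiles(tab)
  picked <- stats::setNames(reps$profile_id, reps$compound_id)
  expect_identical(unname(picked["a"]), "p2")  # odd count: the middle value
  expect_identical(unname(picked["b"]), "q1")  # even count: lower-middle
  expect_identical(unname(picked["c"]), "r1")  # single profile: itself
  # equal scores: lexicographically smallest profile id wins
  tie <- data.frame(profile_id = c("z9", "a1"), compound_id = "t",
                    rges = c(0.5, 0.5))
  expect_identical(select_representative_profiles(tie)$profile_id, "a1")
})

test_that("normalized positions are rank/n and rank-transform invariant", {
  genes <- sprintf("n%02d", 1:4)
  vals <- matrix(c(4, 3, 2, 1), ncol = 1, dimnames = list(genes, "p1"))
  pm <- make_pm(vals)
  sig <- toy_signature("n01", "n04", gene_universe(genes))
  pos <- normalized_positions(pm, sig)
  expect_equal(pos["n01", "p1"], 0.25)
  expect_equal(pos["n04", "p1"], 1.0)
  pm2 <- make_pm(matrix(exp(vals), ncol = 1,
                        dimnames = dimnames(vals)))
  expect_equal(normalized_positions(pm2, sig), pos)
})

test_that("the 3v3 toy gives the exact one-sided p of 1/20", {
  genes <- "t01"
  u <- gene_universe(c("t01", "t02"))
  sig <- toy_signature("t01", "t02", u)
  pos <- matrix(c(0.8, 0.9, 0.95, 0.2, 0.3, 0.4), nrow = 1,
                dimnames = list("t01", sprintf("c%d", 1:6)))
  labels <- stats::setNames(rep(c("effective", "ineffective"), each = 3),
                            colnames(pos))
  res <- test_reversal(pos, labels, sig)
  expect_equal(res$u_stat, 9)
  expect_equal(res$p, 1 / 20)
  expect_gte(res$padj, res$p)
  expect_true(res$reversal)  # 0.05 < 0.25
})

test_that("small-sample p-values match exhaustive enumeration to 1e-12", {
  set.seed(404)
  for (i in 1:60) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- runif(m); y <- runif(n)
    for (alt in c("greater", "less")) {
      got <- rgescore:::mww_onesided(x, y, alternative = alt)
      expect_equal(got$p, bf_mww_p(x, y, alt), tolerance = 1e-13)
    }
  }
})

test_that("swapping group labels converts a greater test into its less complement", {
  set.seed(405)
  x <- runif(5); y <- runif(4)
  g <- rgescore:::mww_onesided(x, y, "greater")
  l <- rgescore:::mww_onesided(y, x, "less")
  expect_equal(g$p, l$p, tolerance = 1e-13)
  # and in the large-sample branch as well
  x2 <- rnorm(30); y2 <- rnorm(25)
  expect_equal(rgescore:::mww_onesided(x2, y2, "greater")$p,
               rgescore:::mww_onesided(y2, x2, "less")$p, tolerance = 1e-12)
})

test_that("ties route to the corrected normal approximation", {
  x <- c(0.1, 0.2, 0.2, 0.5); y <- c(0.2, 0.3, 0.6, 0.7)
  got <- rgescore:::mww_onesided(x, y, "greater")
  expect_true(got$p > 0 && got$p < 1)
  # all-identical observations carry no evidence
  expect_equal(rgescore:::mww_onesided(rep(1, 4), rep(1, 4), "less")$p, 1)
})

test_that("identical position distributions are never flagged", {
  genes <- sprintf("u%02d", 1:5)
  sig <- toy_signature(genes[1:3], genes[4:5],
                       gene_universe(c(genes, "zz")))
  base <- c(0.1, 0.4, 0.6, 0.9)
  pos <- matrix(rep(c(base, base), each = 5), nrow = 5,
                dimnames = list(genes, sprintf("c%d", 1:8)))
  labels <- stats::setNames(rep(c("effective", "ineffective"), each = 4),
                            colnames(pos))
  res <- test_reversal(pos, labels, sig)
  expect_true(all(!res$reversal))
  expect_true(all(res$p >= 0.4))
})

test_that("group-size preconditions are enforced", {
  genes <- "v01"
  sig <- toy_signature("v01", "v02", gene_universe(c("v01", "v02")))
  pos <- matrix(runif(3), nrow = 1,
                dimnames = list("v01", c("c1", "c2", "c3")))
  labels <- stats::setNames(c("effective", "effective", "ineffective"),
                            colnames(pos))
  expect_error(test_reversal(pos, labels, sig), "at least 2")
  expect_error(loco_reversal_genes(pos, labels, sig), "at least 3")
})

test_that("LOCO-robust genes are a subset of full-set reversal genes", {
  set.seed(500)
  st <- quietly(simulate_study(sim_config(
    n_genes = 300, n_up = 15, n_down = 15, n_reversal_up = 4,
    n_reversal_down = 4, n_effective = 8, n_ineffective = 8,
    cell_tumour_rho = c(CL1 = 0.9), n_tumours = 5, seed = 61)))
  sc <- quietly(batch_score(st$profiles, st$signature))
  eff <- summarize_efficacy(st$efficacy)
  reps <- select_representative_profiles(sc)
  pos <- normalized_positions(st$profiles, st$signature, reps)
  res <- loco_reversal_genes(pos, eff, st$signature)
  expect_true(all(res$gene[res$robust] %in% res$gene[res$reversal]))
  expect_true(all(res$padj >= res$p))
})

test_that("raw p-values are calibrated under label permutation", {
  set.seed(600)
  st <- quietly(simulate_study(sim_config(
    n_genes = 300, n_up = 15, n_down = 15, reversal_strength = 0,
    n_effective = 10, n_ineffective = 10,
    cell_tumour_rho = c(CL1 = 0.9), n_tumours = 5, seed = 62)))
  sc <- quietly(batch_score(st$profiles, st$signature))
  reps <- select_representative_profiles(sc)
  pos <- normalized_positions(st$profiles, st$signature, reps)
  cmpds <- colnames(pos)
  hits <- 0; total <- 0
  for (b in 1:50) {
    lab <- stats::setNames(sample(rep(c("effective", "ineffective"), each = 10)),
                           cmpds)
    res <- test_reversal(pos, lab, st$signature)
    hits <- hits + sum(res$p < 0.05); total <- total + nrow(res)
  }
  frac <- hits / total
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / total) + 0.01)
})
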
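test_that("ranking puts the most upregulated gene first, ties by identifier", {
  r <- rank_profile(c(gA = 2.1, gB = -0.5, gC = 0.0, gD = 0.9))
  expect_identical(unclass(r)[c("gA", "gD", "gC", "gB")],
                   c(gA = 1L, gD = 2L, gC = 3L, gB = 4L))
  r2 <- rank_profile(c(gB = 1.0, gA = 1.0))
  expect_lt(r2[["gA"]], r2[["gB"]])
  r3 <- rank_profile(stats::setNames(rep(0, 5), c("e", "c", "a", "d", "b")))
  expect_identical(names(sort(unclass(r3))), letters[1:5])
  expect_error(rank_profile(c(gA = 1, gB = NA)), "gB")
  expect_error(rank_profile(c(gA = Inf, gB = 1)), "gA")
})

test_that("enrichment scores match the worked micro-examples", {
  r <- toy_ranked4()
  expect_equal(enrichment_score(r, "g1"), 0.75)
  expect_equal(enrichment_score(r, "g4"), -1.0)
  for (n in c(4, 7, 11)) {
    u <- sprintf("x%02d", seq_len(n))
    rr <- rank_profile(stats::setNames(rnorm(n), u))
    expect_equal(enrichment_score(rr, u), -1 / n)
  }
  expect_error(enrichment_score(r, character(0)), "empty")
  expect_error(enrichment_score(r, c("g1", "zz")), "zz")
})

test_that("RGES reproduces the +-1.75 micro-examples and their swap", {
  u <- gene_universe(c("g1", "g2", "g3", "g4"))
  vals <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  mim <- toy_signature("g1", "g4", u)
  rec <- quietly(compute_rges(vals, mim, min_overlap = 1))
  expect_equal(rec$es_up, 0.75)
  expect_equal(rec$es_down, -1.0)
  expect_equal(rec$rges, 1.75)
  rev <- quietly(compute_rges(vals, swap_direction(mim), min_overlap = 1))
  expect_equal(rev$rges, -1.75)
})

test_that("RGES agrees with a brute-force oracle on random small cases", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(3:12, 1)
    genes <- sprintf("r%02d", seq_len(n))
    m_up <- sample(seq_len(min(3, n - 1)), 1)
    m_down <- sample(seq_len(min(3, n - m_up)), 1)
    pick <- sample(genes, m_up + m_down)
    vals <- stats::setNames(runif(n), genes)
    sig <- toy_signature(pick[seq_len(m_up)],
                         pick[(m_up + 1):(m_up + m_down)],
                         gene_universe(genes))
    rec <- quietly(compute_rges(vals, sig, min_overlap = 1))
    expect_equal(rec$rges, bf_rges(vals, sig$up, sig$down),
                 tolerance = 1e-14)
  }
})

test_that("RGES is invariant under monotone transforms and antisymmetric", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    genes <- sprintf("m%02d", seq_len(n))
    vals <- stats::setNames(rnorm(n), genes)
    pick <- sample(genes, 6)
    sig <- toy_signature(pick[1:3], pick[4:6], gene_universe(genes))
    rec <- compute_rges(vals, sig)
    mono <- compute_rges(exp(2 * vals) + 5, sig)
    expect_identical(mono$rges, rec$rges)
    swap <- compute_rges(vals, swap_direction(sig))
    expect_equal(swap$rges, -rec$rges, tolerance = 1e-15)
  }
})

test_that("empirical mean RGES under random rankings matches a brute-force simulation", {
  set.seed(303)
  n <- 20
  genes <- sprintf("s%02d", seq_len(n))
  sig <- toy_signature(genes[1:3], genes[4:6], gene_universe(genes))
  impl <- replicate(4000, {
    compute_rges(stats::setNames(runif(n), genes), sig)$rges
  })
  bf <- replicate(4000, {
    pos <- stats::setNames(sample.int(n), genes)
    bf_enrichment(pos, sig$up, n) - bf_enrichment(pos, sig$down, n)
  })
  expect_lt(abs(mean(impl) - mean(bf)), 0.05)
})

test_that("batch scoring honours the quality filter and input order", {
  set.seed(9)
  genes <- sprintf("b%02d", 1:20)
  vals <- matrix(rnorm(20 * 3), nrow = 20,
                 dimnames = list(genes, c("p1", "p2", "p3")))
  vals[, 3] <- vals[, 1]  # identical to profile 1
  pm <- make_pm(vals, quality_flag = c(TRUE, FALSE, TRUE))
  sig <- toy_signature(genes[1:3], genes[4:6], gene_universe(genes))
  hq <- quietly(batch_score(pm, sig))
  expect_identical(hq$profile_id, c("p1", "p3"))
  expect_identical(hq$rges[1], hq$rges[2])
  all3 <- quietly(batch_score(pm, sig, quality_only = FALSE))
  expect_identical(all3$profile_id, c("p1", "p2", "p3"))
  pm_bad <- make_pm(vals, quality_flag = FALSE)
  expect_error(quietly(batch_score(pm_bad, sig)), "quality")
})

test_that("insufficient signature overlap is an error listing missing genes", {
  genes <- sprintf("b%02d", 1:10)
  vals <- stats::setNames(rnorm(10), genes)
  sig <- toy_signature(c("b01", "zz1", "zz2"), c("b02", "b03", "b04"),
                       gene_universe(c(genes, "zz1", "zz2")))
  err <- tryCatch(quietly(compute_rges(vals, sig, min_overlap = 3)),
                  error = conditionMessage)
  expect_match(err, "up signature")
  expect_match(err, "zz1")
})

test_that("similarity scores behave as correlations of reversal", {
  u <- gene_universe(c("gA", "gB", "gC"))
  sig <- quietly(build_signature(
    data.frame(gene = c("gA", "gB", "gC"), log2fc = c(2, -2, 1.6),
               padj = rep(1e-6, 3)), u))
  self <- c(gA = 2, gB = -2, gC = 1.6)
  expect_equal(similarity_score(self, sig, "pearson"), 1.0)
  expect_equal(similarity_score(-self, sig, "cosine"), -1.0)
  anti <- c(gA = -1, gB = 3, gC = -0.5)  # ranks exactly reversed
  expect_equal(similarity_score(anti, sig, "spearman"), -1.0)
  expect_error(similarity_score(c(gA = 1, gB = 1, gC = 1), sig, "pearson"),
               "zero-variance")
  expect_error(similarity_score(c(gA = 0, gB = 0, gC = 0), sig, "cosine"),
               "zero-norm")
  expect_error(similarity_score(c(gA = 1), sig, "pearson"), "fewer than 3")
})

test_that("permutation P values are reproducible and calibrated at the null", {
  set.seed(11)
  genes <- sprintf("q%02d", 1:6)
  u <- gene_universe(genes)
  vals <- stats::setNames(c(6, 5, 4, 3, 2, 1), genes)
  sig <- toy_signature("q02", "q05", u)

  p1 <- quietly(rges_pvalue(vals, sig, n_perm = 500, seed = 99,
                            min_overlap = 1))
  p2 <- quietly(rges_pvalue(vals, sig, n_perm = 500, seed = 99,
                            min_overlap = 1))
  expect_identical(p1$p, p2$p)
  expect_error(rges_pvalue(vals, sig, n_perm = 50, seed = 1), "n_perm")

  # n = 6, m_up = m_down = 1: enumerate all 30 ordered (up, down) pairs
  pos <- seq_len(6)
  pairs <- expand.grid(up = pos, down = pos)
  pairs <- pairs[pairs$up != pairs$down, ]
  all_rges <- apply(pairs, 1, function(pr) {
    bf_enrichment(pr[["up"]], 1, 6) - bf_enrichment(pr[["down"]], 1, 6)
  })
  obs <- quietly(compute_rges(vals, sig, min_overlap = 1))$rges
  exact_tail <- mean(abs(all_rges) >= abs(obs))
  est <- quietly(rges_pvalue(vals, sig, n_perm = 4000, seed = 3,
                             min_overlap = 1))
  expect_lt(abs(est$p - exact_tail), 0.03)

  # the least extreme attainable RGES has a permutation P near 1
  best <- which.min(abs(all_rges))
  flat_sig <- toy_signature(genes[pairs$up[best]], genes[pairs$down[best]], u)
  flat <- quietly(rges_pvalue(vals, flat_sig, n_perm = 400, seed = 5,
                              min_overlap = 1))
  expect_gt(flat$p, 0.9)
})
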
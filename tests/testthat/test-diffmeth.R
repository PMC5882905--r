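test_that("methylation score is the methylated fraction of coverage", {
  expect_equal(methylation_score(3, 1), 0.75)
  expect_equal(methylation_score(0, 25), 0)
  expect_equal(methylation_score(7, 3), 0.7)
  expect_error(methylation_score(0, 0), "zero coverage")
})

test_that("coverage filter drops loci any contrast sample covers too thinly", {
  cov <- rbind(c(12, 9, 15, 20, 11, 30),   # one sample below 10 -> dropped
               c(15, 12, 15, 20, 11, 30),  # retained
               c(10, 10, 10, 10, 10, 10))  # boundary retained (>= semantics)
  meth <- matrix(5L, 3, 6, dimnames = list(NULL, paste0("s", 1:6)))
  mat <- toy_matrix(meth, cov - 5L, rep(c("case", "control"), each = 3))
  filt <- filter_loci(mat, min_coverage = 10, max_cov_percentile = 100)
  expect_equal(nrow(filt$loci), 2)
  expect_equal(filt$loci$pos, c(200L, 300L))

  ident <- filter_loci(mat, min_coverage = 1, max_cov_percentile = 100)
  expect_equal(nrow(ident$loci), 3)

  # idempotence: re-applying the recorded filter is a no-op
  expect_identical(filter_loci(filt, 10, 100), filt)
  expect_error(filter_loci(mat, min_coverage = 1000), "removed all")
})

test_that("retained fraction under NB coverage matches the analytic tail", {
  set.seed(42)
  n <- 20000; k <- 6
  cov <- matrix(rnbinom(n * k, size = 5, mu = 30), n, k,
                dimnames = list(NULL, paste0("s", 1:k)))
  cov[cov < 1] <- 1L
  mat <- toy_matrix(matrix(1L, n, k, dimnames = dimnames(cov)), cov - 1L,
                    rep(c("case", "control"), each = 3))
  filt <- suppressWarnings(filter_loci(mat, 10, 100))
  observed <- nrow(filt$loci) / n
  p_below <- (pnbinom(9, size = 5, mu = 30) - dnbinom(0, size = 5, mu = 30))
  p_keep_one <- 1 - p_below / (1 - dnbinom(0, size = 5, mu = 30))
  expected <- p_keep_one^k
  expect_lt(abs(observed - expected), 0.01)
})

test_that("pooled exact test agrees with fisher.test and behaves symmetrically", {
  # worked example: strongly discordant table
  p1 <- methylstage:::fisher_pooled_p(9, 1, 1, 9)
  expect_equal(p1, fisher.test(matrix(c(9, 1, 1, 9), 2))$p.value, tolerance = 1e-12)

  # random tables: oracle agreement and case/control label symmetry
  set.seed(7)
  for (i in 1:60) {
    m1 <- rpois(1, 8); u1 <- rpois(1, 8) + 1L
    m2 <- rpois(1, 8) + 1L; u2 <- rpois(1, 8)
    mine <- methylstage:::fisher_pooled_p(m1, u1, m2, u2)
    oracle <- fisher.test(matrix(c(m1, u1, m2, u2), 2, byrow = TRUE))$p.value
    expect_equal(mine, oracle, tolerance = 1e-12)
    expect_equal(mine, methylstage:::fisher_pooled_p(m2, u2, m1, u1),
                 tolerance = 1e-12)
  }
})

test_that("identical pooled counts give zero difference and p = 1", {
  meth <- matrix(c(5L, 5L), 1, 2, dimnames = list(NULL, c("a", "b")))
  unmeth <- matrix(c(15L, 15L), 1, 2, dimnames = list(NULL, c("a", "b")))
  mat <- toy_matrix(meth, unmeth, c("case", "control"))
  rec <- test_dmc(mat, "w6")
  expect_equal(rec$diff, 0)
  expect_equal(rec$p, 1)
})

test_that("difference is computed from pooled group scores", {
  meth <- matrix(c(90L, 50L), 1, 2, dimnames = list(NULL, c("a", "b")))
  unmeth <- matrix(c(10L, 50L), 1, 2, dimnames = list(NULL, c("a", "b")))
  mat <- toy_matrix(meth, unmeth, c("case", "control"))
  rec <- test_dmc(mat, "w6")
  expect_equal(rec$diff, 40)
  expect_equal(rec$m_case, 0.9)
  expect_equal(rec$m_ctrl, 0.5)
})

test_that("logistic contrast ranks a real difference above a null locus", {
  meth <- rbind(c(25L, 27L, 26L, 5L, 6L, 4L),   # shifted locus
                c(15L, 14L, 16L, 15L, 16L, 14L)) # null locus
  unmeth <- 30L - meth
  colnames(meth) <- colnames(unmeth) <- paste0("s", 1:6)
  mat <- toy_matrix(meth, unmeth, rep(c("case", "control"), each = 3))
  rec <- test_dmc(mat, "w6", method = "logistic")
  expect_lt(rec$p[1], 0.001)
  expect_gt(rec$p[2], 0.5)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(adjust_q(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_q(0.2), 0.2)
  expect_equal(adjust_q(rep(1, 5)), rep(1, 5))
  set.seed(1)
  p <- runif(50)
  q <- adjust_q(p)
  expect_true(all(q >= p))
  expect_true(!is.unsorted(q[order(p)]))
  expect_error(adjust_q(c(0.1, NA)), "NA")
})

test_that("DMC classification applies both thresholds with >= semantics", {
  rec <- data.frame(diff = c(12, 12, -9.9, 10, -10),
                    p = 0.001, q = c(0.005, 0.02, 1e-4, 0.005, 0.005))
  out <- classify_dmcs(rec)
  expect_equal(out$status, c("hyper", "ns", "ns", "hyper", "hypo"))
})

test_that("stage dynamics reproduces count arithmetic and set intersections", {
  counts <- summarize_stage_counts(
    data.frame(stage = "hyperplasia", n_hypo = 70323, n_hyper = 30187))
  expect_equal(counts$n_total, 100510)
  expect_equal(round(counts$hyper_pct, 1), 30)

  a <- make_records(c(100, 200), c(30, 30), 1e-5, "hyper")
  b <- make_records(c(300, 400), c(-30, -30), 1e-5, "hypo")
  dyn <- stage_dynamics(list(s1 = a, s2 = b))
  expect_equal(dyn$pairwise_intersections["s1", "s2"], 0)
  expect_equal(length(dyn$all_stage_intersection), 0)
  dyn2 <- stage_dynamics(list(s1 = a, s2 = a))
  expect_equal(dyn2$pairwise_intersections["s1", "s2"], 2)
})

test_that("DMC counts grow with the stage multipliers", {
  # the effect multipliers (0.6, 0.7, 0.9, 1.0) make detection easier at
  # later stages; the trend check is first-vs-last plus a positive rank
  # trend, since detection saturates between the two late stages and
  # strict stage-by-stage monotonicity is not identifiable at this scale
  trend <- vapply(1:10, function(s) {
    ds <- simulate_methylation_dataset(small_config(seed = 100 + s))
    mat <- build_meth_matrix(ds$calls, ds$samples)
    n <- vapply(levels(ds$samples$stage), function(st) {
      ids <- ds$samples$sample_id[ds$samples$stage == st]
      smat <- filter_loci(subset_samples(mat, ids), 10, 99.9)
      rec <- call_dmcs(smat, st)
      sum(rec$status != "ns")
    }, numeric(1))
    n[4] > n[1] && cor(n, seq_along(n), method = "spearman") > 0
  }, logical(1))
  expect_gte(mean(trend), 0.95)
})

test_that("transition contrast subtracts the developmental background", {
  ds <- simulate_methylation_dataset(small_config(seed = 21))
  mat <- filter_loci(build_meth_matrix(ds$calls, ds$samples))
  ann <- build_annotation(ds$genome$genes, ds$genome$enhancers)
  tr <- suppressMessages(
    pooled_transition_contrast(mat, c("w6", "w8"), c("w10", "w12"), ann))
  # subtraction rule: no reported gene may appear in the control contrast
  expect_length(intersect(tr$hyper_genes,
                          c(tr$control_hyper_genes, tr$control_hypo_genes)), 0)
  expect_length(intersect(tr$hypo_genes,
                          c(tr$control_hyper_genes, tr$control_hypo_genes)), 0)
  expect_error(pooled_transition_contrast(mat, "w6", c("w6", "w8"), ann),
               "overlap")
})

test_that("transition contrast recovers genes under a steep progression", {
  cfg <- small_config(seed = 22, multipliers = c(0.15, 0.25, 0.9, 1.0))
  ds <- simulate_methylation_dataset(cfg)
  mat <- filter_loci(build_meth_matrix(ds$calls, ds$samples))
  ann <- build_annotation(ds$genome$genes, ds$genome$enhancers)
  tr <- suppressMessages(
    pooled_transition_contrast(mat, c("w6", "w8"), c("w10", "w12"), ann))
  planted <- unique(na.omit(ds$truth$dmrs$gene_id[ds$truth$dmrs$direction == "hyper"]))
  expect_gte(mean(planted %in% tr$hyper_genes), 0.8)
})
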
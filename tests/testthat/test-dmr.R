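test_that("gap threshold lands between the two spacing modes", {
  set.seed(1)
  gaps <- 10^c(rnorm(300, 1.3, 0.1), rnorm(300, 3.5, 0.1))
  pos <- cumsum(round(gaps))
  d1 <- estimate_gap_threshold(pos)
  expect_gt(d1, 100)
  expect_lt(d1, 1000)
  expect_equal(attr(d1, "method"), "mixture")
  expect_identical(as.numeric(d1), as.numeric(estimate_gap_threshold(pos)))
})

test_that("EM mixture fit agrees with mclust on well-separated components", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(2)
  x <- c(rnorm(400, 1.3, 0.1), rnorm(400, 3.5, 0.1))
  fit <- methylstage:::em_normal_mixture_2(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(sort(fit$weight), sort(as.numeric(mc$parameters$pro)),
               tolerance = 0.05)
})

test_that("degenerate spacing falls back to the default distance", {
  set.seed(3)
  pos <- cumsum(round(10^rnorm(300, 2, 0.05)))  # unimodal gaps
  d <- estimate_gap_threshold(pos, fallback = 100)
  expect_equal(as.numeric(d), 100)
  expect_warning(estimate_gap_threshold(cumsum(rep(50, 20))), "fallback")
})

test_that("seed-and-extend merging matches the hand-worked example", {
  rec <- make_records(pos = c(100, 150, 200, 5000),
                      diff = c(30, 30, 30, 30), p = 1e-6,
                      status = "hyper")
  dmrs <- call_dmrs(rec, gap = 500, min_cpgs = 3, q_threshold = NULL)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 100)
  expect_equal(dmrs$end, 200)
  expect_equal(dmrs$n_dmcs, 3)
})

test_that("opposite directions never share a region", {
  rec <- make_records(pos = c(100, 150, 200, 250),
                      diff = c(30, -30, 30, 30), p = 1e-6,
                      status = c("hyper", "hypo", "hyper", "hyper"))
  dmrs <- call_dmrs(rec, gap = 500, min_cpgs = 1, q_threshold = NULL)
  expect_equal(nrow(dmrs), 3)
  expect_equal(dmrs$status, c("hyper", "hypo", "hyper"))
})

test_that("regions below the 20-point mean difference are filtered", {
  rec <- make_records(pos = c(100, 150, 200), diff = 15, p = 1e-6, status = "hyper")
  expect_equal(nrow(call_dmrs(rec, gap = 500, q_threshold = NULL)), 0)
})

test_that("non-DMC CpGs inside the span dilute the mean difference", {
  rec <- rbind(make_records(c(100, 300), c(40, 40), 1e-8, "hyper"),
               make_records(200, 0, 1, "ns"))
  rec <- rec[order(rec$pos), ]
  dmrs <- call_dmrs(rec, gap = 500, min_cpgs = 3, q_threshold = NULL)
  expect_equal(dmrs$n_cpgs, 3)
  expect_equal(dmrs$n_dmcs, 2)
  expect_equal(dmrs$mean_diff, mean(c(40, 0, 40)))
})

test_that("merging equals the brute-force oracle on random inputs", {
  set.seed(9)
  for (i in 1:12) {
    n <- sample(10:50, 1)
    pos <- sort(sample(1:20000, n))
    status <- sample(c("hyper", "hypo", "ns"), n, replace = TRUE,
                     prob = c(0.3, 0.3, 0.4))
    diff <- ifelse(status == "hyper", runif(n, 20, 50),
                   ifelse(status == "hypo", -runif(n, 20, 50), runif(n, -5, 5)))
    rec <- make_records(pos, diff, runif(n, 1e-9, 1e-3), status)
    gap <- sample(c(100, 300, 1000), 1)
    mine <- call_dmrs(rec, gap = gap, min_cpgs = 2, q_threshold = NULL)
    oracle <- brute_force_dmrs(rec, gap = gap, min_cpgs = 2)
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0)
    } else {
      expect_equal(nrow(mine), nrow(oracle))
      expect_equal(mine$start, oracle$start)
      expect_equal(mine$end, oracle$end)
      expect_equal(mine$n_cpgs, oracle$n_cpgs)
      expect_equal(mine$mean_diff, oracle$mean_diff)
    }
  }
})

test_that("every emitted region satisfies the filter invariants", {
  ds <- simulate_methylation_dataset(small_config(seed = 30))
  mat <- filter_loci(build_meth_matrix(ds$calls, ds$samples))
  rec <- call_dmcs(mat, "w12")
  dmrs <- call_dmrs(rec, gap = estimate_gap_threshold(mat$loci))
  expect_gt(nrow(dmrs), 0)
  expect_true(all(dmrs$n_cpgs >= 3))
  expect_true(all(dmrs$n_dmcs >= 1))
  expect_true(all(abs(dmrs$mean_diff) >= 20))
  expect_true(all(dmrs$q_region < 0.05))
  for (ch in unique(dmrs$chrom)) {
    d <- dmrs[dmrs$chrom == ch, ]
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("region evidence strengthens with each concordant CpG", {
  p_prev <- 1
  for (n in 2:8) {
    rec <- make_records(pos = 100 * seq_len(n), diff = 30, p = 0.3, status = "hyper")
    dmrs <- call_dmrs(rec, gap = 500, min_cpgs = 2,
                      mean_diff_threshold = 0, q_threshold = NULL)
    expect_lt(dmrs$p_region, p_prev)
    p_prev <- dmrs$p_region
  }
})

test_that("cross-stage union merges overlaps and records provenance", {
  w6 <- structure(data.frame(chrom = "chr1", start = 100L, end = 200L,
                             status = "hyper"), class = c("dmr_set", "data.frame"))
  w10 <- structure(data.frame(chrom = "chr1", start = 150L, end = 260L,
                              status = "hyper"), class = c("dmr_set", "data.frame"))
  u <- union_dmrs(list(w6 = w6, w10 = w10))
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 100L)
  expect_equal(u$end, 260L)
  expect_equal(u$stages, "w6,w10")

  far <- structure(data.frame(chrom = "chr1", start = 1000L, end = 1100L,
                              status = "hypo"), class = c("dmr_set", "data.frame"))
  u2 <- union_dmrs(list(w6 = w6, w10 = far))
  expect_equal(nrow(u2), 2)
  expect_identical(union_dmrs(list(a = w6, b = w6))$start, 100L)
})

test_that("trajectory clustering recovers planted progression groups", {
  set.seed(4)
  mk <- function(center, n) {
    t(replicate(n, center + rnorm(4, 0, 2)))
  }
  traj <- rbind(mk(c(40, 40, 40, 40), 10),
                mk(c(-40, -40, -40, -40), 10),
                mk(c(0, 0, -25, -25), 10))
  rownames(traj) <- paste0("r", 1:30)
  colnames(traj) <- paste0("w", c(6, 8, 10, 12))
  cl <- trajectory_cluster(traj, k = 3)
  expect_equal(cl$labels, rep(c(1, 3, 2), each = 10))  # sorted by mean, descending
  expect_equal(cl$sizes, rep(10L, 3))
  expect_lt(max(abs(cl$centers["group1", ] - 40)), 3)

  expect_equal(unique(trajectory_cluster(traj, k = 1)$labels), 1)
  perm <- sample(30)
  cl2 <- trajectory_cluster(traj[perm, ], k = 3)
  expect_equal(cl2$labels, cl$labels[perm])
  expect_error(trajectory_cluster(traj[1:2, ], k = 3), "exceeds")
})

test_that("trajectory matrix averages covered CpG differences per interval", {
  uni <- data.frame(chrom = "chr1", start = 100L, end = 300L, stages = "w6")
  recs <- list(w6 = make_records(c(100, 200, 300, 900), c(30, 20, 10, 99), 1e-5,
                                 c("hyper", "hyper", "hyper", "hyper")),
               w8 = make_records(c(100, 200, 300), c(-10, -20, -30), 1e-5, "hypo"))
  m <- dmr_trajectory_matrix(uni, recs)
  expect_equal(unname(m[1, ]), c(20, -20))
})
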
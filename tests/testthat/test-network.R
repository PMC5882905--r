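toy_modules <- function(adjacency, scores, members = NULL) {
  # hand-built cometh_modules for operations that only need structure
  net <- structure(list(adjacency = adjacency, scores = scores, beta = 1),
                   class = "cometh_network")
  membership <- if (is.null(members)) rep(1L, nrow(scores)) else members
  mods <- lapply(sort(unique(membership[membership > 0])), function(m) {
    rownames(scores)[membership == m]
  })
  names(mods) <- paste0("M", seq_along(mods))
  structure(list(membership = membership, modules = mods, network = net),
            class = "cometh_modules")
}

test_that("upstream promoter selection is strand-aware and q-filtered", {
  genes <- data.frame(gene_id = c("P", "M"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10000L, 30000L))
  rec <- make_records(pos = c(9500L, 10500L, 30500L, 29500L, 9000L),
                      diff = 30, p = 1e-5,
                      status = "hyper")
  rec$q <- ifelse(rec$pos == 9000L, 0.02, 1e-4)  # 9000 fails the q filter
  sel <- select_network_loci(list(w6 = rec), genes)
  # plus strand: upstream = [tss-2000, tss-1]; minus strand: [tss+1, tss+2000]
  expect_setequal(sel$pos, c(9500L, 30500L))
  expect_equal(sel$gene_id[sel$pos == 9500L], "P")
  expect_equal(sel$gene_id[sel$pos == 30500L], "M")
})

test_that("signed adjacency maps correlation endpoints correctly", {
  x <- as.numeric(1:10)
  scores <- rbind(a = x, b = x, c = -x, d = c(x[1:5], -x[1:5] + 12))
  a2 <- build_adjacency(scores, beta = 2)$adjacency
  expect_equal(a2["a", "b"], 1)        # r = 1
  expect_equal(a2["a", "c"], 0)        # r = -1
  expect_equal(unname(diag(a2)), rep(1, 4))
  expect_equal(a2, t(a2))
  r0 <- cor(x, scores["d", ])
  expect_equal(a2["a", "d"], ((1 + r0) / 2)^2)
  expect_error(build_adjacency(scores[, 1:2]), ">= 3 samples")
})

test_that("zero-correlation pair with beta 2 gives adjacency 0.25", {
  scores <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  a <- build_adjacency(scores, beta = 2)$adjacency
  expect_equal(a["a", "b"], 0.25)
})

test_that("adjacency bounds and TOM identities hold on random data", {
  set.seed(12)
  scores <- matrix(rnorm(40 * 12), 40, 12,
                   dimnames = list(paste0("l", 1:40), NULL))
  net <- build_adjacency(scores, beta = 6)
  a <- net$adjacency
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(a, t(a))
  tom <- tom_similarity(a)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 40))
  expect_equal(tom, t(tom))
})

test_that("two planted correlation blocks are recovered as two modules", {
  sim <- simulate_comethylation_scores(n_samples = 24, block_sizes = c(50, 50),
                                       n_background = 0, rho = 0.9, seed = 5)
  net <- build_adjacency(sim$scores, beta = 6)
  mods <- detect_modules(net, min_module_size = 30)
  expect_equal(length(mods$modules), 2)
  # membership accuracy up to label permutation
  acc <- max(sapply(list(c(1, 2), c(2, 1)), function(pm) {
    mean(mods$membership[sim$membership > 0] == pm[sim$membership[sim$membership > 0]])
  }))
  expect_gte(acc, 0.95)
})

test_that("module detection is invariant to locus order and respects size", {
  sim <- simulate_comethylation_scores(n_samples = 24, block_sizes = c(40, 40),
                                       n_background = 0, rho = 0.9, seed = 6)
  net <- build_adjacency(sim$scores, beta = 6)
  mods <- detect_modules(net, min_module_size = 30)
  perm <- sample(nrow(sim$scores))
  mods_p <- detect_modules(build_adjacency(sim$scores[perm, ], beta = 6),
                           min_module_size = 30)
  expect_equal(length(mods_p$modules), length(mods$modules))
  expect_setequal(unname(unlist(mods_p$modules)), unname(unlist(mods$modules)))

  expect_warning(
    small <- detect_modules(net, min_module_size = nrow(sim$scores) + 1),
    "unassigned")
  expect_length(small$modules, 0)
})

test_that("module eigengene is the dominant shared profile", {
  samp <- paste0("s", 1:8)
  prof <- rnorm(8)
  scores <- matrix(rep(prof, each = 5), 5, 8,
                   dimnames = list(paste0("l", 1:5), samp))
  scores <- scores + matrix(rnorm(40, 0, 1e-8), 5, 8)
  eg <- module_eigengene(scores)
  expect_gt(eg$var_explained, 0.999)
  expect_gt(abs(cor(eg$eigengene, prof)), 0.999)
  expect_equal(sum(eg$eigengene^2), 1)
  # sign convention survives negating all members
  eg2 <- module_eigengene(-scores)
  expect_gte(mean(cor(eg2$eigengene, t(-scores))), 0)

  # two orthogonal half-blocks split the variance evenly (profiles centred
  # and orthogonalised so row standardisation preserves orthogonality)
  a <- rnorm(8); a <- a - mean(a)
  b <- rnorm(8); b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a^2)
  half <- rbind(matrix(rep(a, each = 4), 4, 8), matrix(rep(b, each = 4), 4, 8))
  rownames(half) <- paste0("h", 1:8); colnames(half) <- samp
  eg3 <- module_eigengene(half + rnorm(64, 0, 1e-9))
  expect_lt(abs(eg3$var_explained - 0.5), 0.01)
  expect_error(module_eigengene(scores[1, , drop = FALSE]), ">= 2")
})

test_that("eigengene explained variance matches an eigendecomposition oracle", {
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(rnorm(15 * 9), 15, 9, dimnames = list(paste0("l", 1:15), NULL))
    eg <- module_eigengene(m)
    z <- t(scale(t(m)))
    ev <- eigen(crossprod(z), symmetric = TRUE)$values
    expect_equal(eg$var_explained, ev[1] / sum(ev), tolerance = 1e-10)
    # first-PC optimality: no single member explains more
    proj <- apply(z, 1, function(row) {
      (sum(row * eg$eigengene))^2 / sum(row^2)
    })
    expect_gte(eg$var_explained + 1e-12, max(proj) / nrow(m))
  }
})

test_that("preservation z-summary separates planted from random modules", {
  sim <- simulate_comethylation_scores(n_samples = 48, block_sizes = 50,
                                       n_background = 150, rho = 0.85, seed = 7)
  scores <- sim$scores
  net <- build_adjacency(scores, beta = 6)
  planted <- toy_modules(net$adjacency, scores, members = sim$membership)
  # test data identical to reference: strong preservation
  pres <- suppressWarnings(
    module_preservation(planted, scores, scores, beta = 6, n_perm = 200, seed = 1))
  expect_gte(pres$Z_summary[1], 10)

  # random locus sets in unstructured data are not preserved
  noise_ref <- simulate_comethylation_scores(n_samples = 48, block_sizes = integer(),
                                             n_background = 200, seed = 8)$scores
  noise_test <- simulate_comethylation_scores(n_samples = 48, block_sizes = integer(),
                                              n_background = 200, seed = 9)$scores
  z_null <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    fake <- toy_modules(NULL, noise_ref,
                        members = as.integer(seq_len(nrow(noise_ref)) %in%
                                               sample(nrow(noise_ref), 30)))
    suppressWarnings(
      module_preservation(fake, noise_ref, noise_test, beta = 6,
                          n_perm = 100, seed = i)$Z_summary)
  }, numeric(1))
  expect_gte(mean(abs(z_null) < 2), 0.95)
})

test_that("preservation drops when the test data loses the structure", {
  # graded loadings give the module an intrinsic hub ordering that an
  # independent replicate reproduces but sample shuffling destroys
  z <- vapply(1:10, function(s) {
    ref <- simulate_comethylation_scores(n_samples = 24, block_sizes = 40,
                                         n_background = 60, rho = c(0.5, 0.95),
                                         seed = s)
    rep2 <- simulate_comethylation_scores(n_samples = 24, block_sizes = 40,
                                          n_background = 60, rho = c(0.5, 0.95),
                                          seed = s + 500)
    net <- build_adjacency(ref$scores, beta = 6)
    mods <- toy_modules(net$adjacency, ref$scores, members = ref$membership)
    # independent replicate preserves; per-locus sample shuffling destroys
    shuffled <- t(apply(rep2$scores, 1, sample))
    dimnames(shuffled) <- dimnames(rep2$scores)
    c(module_preservation(mods, ref$scores, rep2$scores, beta = 6,
                          n_perm = 100, seed = 1)$Z_summary[1],
      module_preservation(mods, ref$scores, shuffled, beta = 6,
                          n_perm = 100, seed = 1)$Z_summary[1])
  }, numeric(2))
  expect_true(all(z[1, ] > z[2, ]))
})

test_that("degenerate permutation null yields infinite Z, never NaN", {
  scores <- matrix(rep(c(1, 2, 3, 4), 6), 6, 4, byrow = TRUE,
                   dimnames = list(paste0("l", 1:6), paste0("s", 1:4)))
  scores <- scores + matrix(rnorm(24, 0, 1e-10), 6, 4)
  mods <- toy_modules(((1 + cor(t(scores))) / 2), scores,
                      members = c(1L, 1L, 1L, 0L, 0L, 0L))
  w <- capture_warnings(
    pres <- module_preservation(mods, scores, scores, beta = 1, n_perm = 20,
                                seed = 2))
  expect_match(w, "degenerate", all = FALSE)
  expect_false(any(is.nan(pres$Z_summary)))
})

test_that("eigengene group test flags planted case shifts after BH", {
  set.seed(14)
  samples <- data.frame(sample_id = paste0("s", 1:24),
                        group = rep(c("case", "control"), each = 12),
                        stage = "w6", replicate = 1:12)
  shifted <- c(rnorm(12, 1), rnorm(12, 0))
  flat <- rnorm(24)
  eg <- cbind(M1 = shifted / sqrt(sum(shifted^2)), M2 = flat / sqrt(sum(flat^2)))
  rownames(eg) <- samples$sample_id
  res <- eigengene_group_test(eg, samples)
  expect_lt(res$p_adj[res$module == "M1"], 0.05)
  expect_gt(res$p[res$module == "M2"], 0.05)
  # single module: BH with m = 1 leaves p unchanged
  res1 <- eigengene_group_test(eg[, 1, drop = FALSE], samples)
  expect_equal(res1$p, res1$p_adj)
  expect_error(eigengene_group_test(eg, transform(samples, group = "case")),
               "both")
})

test_that("hub ranking follows intramodular connectivity with stable ties", {
  keys <- paste("chr1", c(100, 200, 300, 400), "+", sep = ":")
  a <- matrix(0.1, 4, 4, dimnames = list(keys, keys))
  a[1, ] <- a[, 1] <- 0.9  # star centre
  diag(a) <- 1
  scores <- matrix(rnorm(16), 4, 4, dimnames = list(keys, NULL))
  mods <- toy_modules(a, scores)
  hubs <- hub_report(mods, "M1", top_k = 2)
  expect_equal(hubs$locus[1], keys[1])
  all_h <- hub_report(mods, "M1", top_k = 99)
  expect_equal(nrow(all_h), 4)
  # loci 2..4 tie; order falls back to locus key order
  expect_equal(all_h$locus[2:4], sort(keys[2:4]))
  expect_error(hub_report(mods, "M9"), "no module")
})

test_that("edge export is thresholded and symmetric-free", {
  sim <- simulate_comethylation_scores(n_samples = 12, block_sizes = 10,
                                       n_background = 5, rho = 0.9, seed = 9)
  net <- build_adjacency(sim$scores, beta = 2)
  edges <- network_edges(net, threshold = 0.5)
  expect_true(all(edges$adjacency >= 0.5))
  expect_true(all(edges$locus_i != edges$locus_j))
  key <- paste(pmin(edges$locus_i, edges$locus_j),
               pmax(edges$locus_i, edges$locus_j))
  expect_false(any(duplicated(key)))
})
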
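#' Select promoter-upstream DMC loci for network construction
#'
#' Keeps loci reaching `q < q_threshold` in at least one stage whose
#' position lies in the 2 kb window strictly upstream of a TSS, oriented
#' by the gene's strand (`[TSS - w, TSS - 1]` on plus-strand genes,
#' `[TSS + 1, TSS + w]` on minus-strand genes).
#'
#' @param stage_records Named list of per-stage DMC records with `q`.
#' @param genes Gene model data frame.
#' @param upstream_window Window width in bp (default 2000).
#' @param q_threshold Significance cutoff (default 0.01).
#' @return Data frame of selected loci (`chrom`, `pos`, `strand`,
#'   `gene_id`, `min_q`), one row per locus (first matching gene listed).
#' @export
select_network_loci <- function(stage_records, genes, upstream_window = 2000,
                                q_threshold = 0.01) {
  keys_q <- list()
  for (rec in stage_records) {
    k <- locus_key(rec$chrom, rec$pos, rec$strand)
    keys_q[[length(keys_q) + 1]] <- stats::setNames(rec$q, k)
  }
  all_keys <- unique(unlist(lapply(keys_q, names)))
  min_q <- rep(Inf, length(all_keys)); names(min_q) <- all_keys
  for (qs in keys_q) {
    idx <- match(names(qs), all_keys)
    min_q[idx] <- pmin(min_q[idx], qs)
  }
  sig_keys <- all_keys[min_q < q_threshold]
  if (!length(sig_keys)) {
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      gene_id = character(), min_q = numeric()))
  }
  parts <- strsplit(sig_keys, ":", fixed = TRUE)
  loci <- data.frame(chrom = vapply(parts, `[`, "", 1),
                     pos = as.integer(vapply(parts, `[`, "", 2)),
                     strand = vapply(parts, `[`, "", 3),
                     stringsAsFactors = FALSE)
  upstream <- data.frame(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$tss - as.integer(upstream_window),
                   genes$tss + 1L),
    end = ifelse(genes$strand == "+", genes$tss - 1L,
                 genes$tss + as.integer(upstream_window)),
    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  upstream$start <- pmax(1L, as.integer(upstream$start))
  hits <- GenomicRanges::findOverlaps(loci_granges(loci), interval_granges(upstream))
  qh <- S4Vectors::queryHits(hits)
  first <- !duplicated(qh)
  sel <- qh[first]
  out <- loci[sel, , drop = FALSE]
  out$gene_id <- upstream$gene_id[S4Vectors::subjectHits(hits)[first]]
  out$min_q <- unname(min_q[sig_keys][sel])
  out <- order_loci(out)
  rownames(out) <- NULL
  out
}

#' Build a signed co-methylation adjacency
#'
#' Pairwise Pearson correlation of locus methylation profiles across
#' samples, mapped to \[0, 1\] by the signed soft-threshold
#' `a = ((1 + r) / 2)^beta`. Zero-variance loci are dropped (reported via
#' message). With `choose_beta`, the smallest even power in 2..20 whose
#' binned log-log degree distribution fits a scale-free line with
#' R-squared at least 0.8 is used, falling back to the default 12.
#'
#' @param scores Numeric matrix, loci x samples (rownames = locus keys).
#' @param beta Soft-threshold power (default 12).
#' @param choose_beta Select beta by scale-free fit (default FALSE).
#' @return A `cometh_network`: list with `adjacency`, `scores`, `beta`,
#'   and `scale_free_r2` when selected.
#' @export
build_adjacency <- function(scores, beta = 12, choose_beta = FALSE) {
  if (ncol(scores) < 3) .stopf("need >= 3 samples to correlate profiles")
  if (beta < 1) .stopf("beta must be >= 1")
  v <- apply(scores, 1, stats::var)
  if (any(v == 0)) {
    message(sprintf("dropping %d zero-variance locus/loci", sum(v == 0)))
    scores <- scores[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(scores))
  r2 <- NA_real_
  if (choose_beta) {
    pick <- NA_integer_
    for (b in seq(2, 20, by = 2)) {
      a <- ((1 + r) / 2)^b
      fit <- scale_free_fit(rowSums(a) - 1)
      if (!is.na(fit) && fit >= 0.8) { pick <- b; r2 <- fit; break }
    }
    beta <- if (is.na(pick)) 12 else pick
  }
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  structure(list(adjacency = a, scores = scores, beta = beta,
                 scale_free_r2 = r2),
            class = "cometh_network")
}

# R-squared of the log-log regression of binned connectivity frequency.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  cuts <- cut(k, n_bins)
  freq <- tapply(k, cuts, length)
  mid <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mid[ok]))
  summary(fit)$r.squared
}

#' @export
print.cometh_network <- function(x, ...) {
  cat(sprintf("cometh_network: %d loci x %d samples, signed adjacency beta = %g\n",
              nrow(x$scores), ncol(x$scores), x$beta))
  invisible(x)
}

#' Topological overlap of an adjacency matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` over `u != i, j` and connectivity
#' `k_i = sum_u a_iu` (u != i); `TOM_ii = 1`.
#'
#' @param adjacency Symmetric matrix in \[0, 1\] with unit diagonal.
#' @return The topological overlap matrix.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-methylation modules by hierarchical clustering with a
#' simplified dynamic tree cut
#'
#' Average-linkage clustering of `1 - TOM` (or `1 - adjacency`), followed
#' by a static cut at absolute dissimilarity `cut_height` (loci whose
#' branches only join above it stay apart), then recursive branch
#' decomposition: each branch large enough to split is re-cut just below
#' its own top merge height, up to `deep_split` levels; branches of at
#' least `min_module_size` loci become modules. Loci in small leftover
#' branches are unassigned (module 0). Module labels are ordered by size,
#' largest first.
#'
#' @param network A `cometh_network`.
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Absolute static cut height on the dissimilarity
#'   scale (default 0.99).
#' @param deep_split Recursion depth of branch decomposition (default 2).
#' @param use_tom Cluster on topological overlap dissimilarity (default
#'   TRUE) or raw `1 - adjacency`.
#' @return A `cometh_modules` object: list with `membership` (integer per
#'   locus; 0 = unassigned), `modules` (list of locus-key vectors, sorted
#'   by size), and the `network`.
#' @export
detect_modules <- function(network, min_module_size = 30, cut_height = 0.99,
                           deep_split = 2, use_tom = TRUE) {
  stopifnot(inherits(network, "cometh_network"))
  d <- if (use_tom) 1 - tom_similarity(network$adjacency) else 1 - network$adjacency
  n <- nrow(d)
  keys <- rownames(network$scores)
  split_branch <- function(idx, depth) {
    if (length(idx) < 2 * min_module_size || depth >= deep_split) return(list(idx))
    hc <- stats::hclust(stats::as.dist(d[idx, idx, drop = FALSE]), method = "average")
    hs <- sort(hc$height, decreasing = TRUE)
    # split only below a clear gap: the top join must sit well above the
    # next merge, otherwise the branch is one cohesive module
    if (length(hs) < 2 || hs[1] - hs[2] < 0.05) return(list(idx))
    parts <- unname(split(idx, stats::cutree(hc, h = hs[1] * (1 - 1e-6))))
    big <- Filter(function(p) length(p) >= min_module_size, parts)
    if (length(big) < 2) return(list(idx))
    unlist(lapply(big, split_branch, depth = depth + 1), recursive = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  top <- unname(split(seq_len(n), stats::cutree(hc, h = cut_height)))
  branches <- list()
  for (p in top) {
    if (length(p) >= min_module_size) {
      branches <- c(branches, split_branch(p, 0L))
    }
  }
  branches <- Filter(function(p) length(p) >= min_module_size, branches)
  membership <- integer(n)
  if (length(branches)) {
    branches <- branches[order(-lengths(branches))]
    for (m in seq_along(branches)) membership[branches[[m]]] <- m
  } else {
    .warnf("no module reached min_module_size = %d; all loci unassigned",
           min_module_size)
  }
  modules <- lapply(seq_along(branches), function(m) keys[membership == m])
  names(modules) <- if (length(branches)) paste0("M", seq_along(branches)) else NULL
  structure(list(membership = membership, modules = modules,
                 network = network, use_tom = use_tom,
                 min_module_size = min_module_size, cut_height = cut_height),
            class = "cometh_modules")
}

#' @export
print.cometh_modules <- function(x, ...) {
  cat(sprintf("cometh_modules: %d module(s) over %d loci (%d unassigned)\n",
              length(x$modules), length(x$membership), sum(x$membership == 0)))
  if (length(x$modules)) {
    cat("  sizes:", paste(lengths(x$modules), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Module eigengene (first principal component of a module)
#'
#' First right-singular vector of the row-standardised member-by-sample
#' matrix: a unit-norm per-sample summary profile, sign-aligned so that
#' its mean correlation with member profiles is non-negative.
#'
#' @param member_scores Matrix, members x samples (>= 2 members).
#' @return List with `eigengene` (length = samples, unit norm) and
#'   `var_explained` (fraction in \[0, 1\]).
#' @export
module_eigengene <- function(member_scores) {
  if (nrow(member_scores) < 2) .stopf("module eigengene needs >= 2 members")
  v <- apply(member_scores, 1, stats::var)
  if (any(v == 0)) .stopf("zero-variance member profile in module")
  z <- t(scale(t(member_scores)))
  sv <- svd(z)
  e <- sv$v[, 1]
  if (mean(stats::cor(e, t(member_scores))) < 0) e <- -e
  names(e) <- colnames(member_scores)
  list(eigengene = e, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes for all modules
#' @param modules A `cometh_modules`.
#' @return Matrix samples x modules of eigengene scores.
#' @export
module_eigengenes <- function(modules) {
  scores <- modules$network$scores
  do.call(cbind, lapply(stats::setNames(names(modules$modules), names(modules$modules)),
                        function(m) {
    module_eigengene(scores[modules$modules[[m]], , drop = FALSE])$eigengene
  }))
}

#' Module preservation z-summary between a reference and a test dataset
#'
#' For each module, two observed statistics in the test network: density
#' (mean off-diagonal within-module adjacency) and connectivity
#' preservation (Pearson correlation between members' intramodular
#' connectivity in the reference vs the test network). Each statistic is
#' standardised to a Z-score against its own permutation null: density
#' against `n_perm` random same-size locus sets from the network (is the
#' module denser than chance?), connectivity against `n_perm` random
#' reorderings of the test-side connectivity vector within the module (is
#' the hub ordering reproduced beyond chance?). `Z_summary` is the mean
#' of the two. Z above ~10 indicates strong preservation, 2-10 moderate
#' (reported, not enforced).
#'
#' @param modules A `cometh_modules` (reference module definitions).
#' @param scores_ref,scores_test Score matrices (same loci, reference =
#'   e.g. case samples, test = control samples).
#' @param beta Soft power for both networks (default: the module
#'   network's beta).
#' @param n_perm Permutations (default 200).
#' @param seed Integer seed.
#' @return Data frame per module: `module`, `size`, `density`,
#'   `connectivity_cor`, `Z_density`, `Z_connectivity`, `Z_summary`.
#'   Modules smaller than 3 are skipped (message); degenerate null sd
#'   yields +/-Inf with a warning, never NaN.
#' @export
module_preservation <- function(modules, scores_ref, scores_test,
                                beta = NULL, n_perm = 200, seed = 1L) {
  stopifnot(inherits(modules, "cometh_modules"))
  beta <- beta %||% modules$network$beta
  keys <- rownames(scores_ref)
  if (!identical(keys, rownames(scores_test))) {
    .stopf("reference and test score matrices must share the same loci")
  }
  a_ref <- ((1 + stats::cor(t(scores_ref))) / 2)^beta
  a_test <- ((1 + stats::cor(t(scores_test))) / 2)^beta
  density_of <- function(idx) {
    sub <- a_test[idx, idx]
    mean(sub[lower.tri(sub)])
  }
  safe_cor <- function(x, y) {
    r <- suppressWarnings(stats::cor(x, y))
    if (is.na(r)) 0 else r
  }
  zscore <- function(obs, null, m) {
    mu <- mean(null); sdv <- stats::sd(null)
    if (sdv == 0) {
      .warnf("degenerate null (sd = 0) for module %s; Z reported as +/-Inf", m)
      if (abs(obs - mu) < 1e-12) 0 else sign(obs - mu) * Inf
    } else {
      (obs - mu) / sdv
    }
  }
  local_seed(derive_seed(seed, "preservation"))
  rows <- list()
  for (m in names(modules$modules)) {
    idx <- match(modules$modules[[m]], keys)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 3) {
      message(sprintf("module %s has < 3 loci in the test data; skipped", m))
      next
    }
    dens_obs <- density_of(idx)
    k_ref <- rowSums(a_ref[idx, idx]) - 1
    k_test <- rowSums(a_test[idx, idx]) - 1
    conn_obs <- safe_cor(k_ref, k_test)
    dens_null <- vapply(seq_len(n_perm), function(b) {
      density_of(sample.int(length(keys), length(idx)))
    }, numeric(1))
    conn_null <- vapply(seq_len(n_perm), function(b) {
      safe_cor(k_ref, k_test[sample.int(length(idx))])
    }, numeric(1))
    z <- c(zscore(dens_obs, dens_null, m), zscore(conn_obs, conn_null, m))
    rows[[m]] <- data.frame(module = m, size = length(idx),
                            density = dens_obs, connectivity_cor = conn_obs,
                            Z_density = z[1], Z_connectivity = z[2],
                            Z_summary = mean(z), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon test of module eigengenes between case and control samples
#'
#' Two-sided rank-sum test per module eigengene, BH-adjusted across
#' modules.
#'
#' @param eigengenes Matrix samples x modules (see
#'   [module_eigengenes()]).
#' @param samples Sample sheet aligned with the rows of `eigengenes`.
#' @return Data frame `module`, `p`, `p_adj`, `median_case`,
#'   `median_control`.
#' @export
eigengene_group_test <- function(eigengenes, samples) {
  is_case <- samples$group == "case"
  if (!any(is_case) || all(is_case)) .stopf("need both case and control samples")
  rows <- lapply(colnames(eigengenes), function(m) {
    x <- eigengenes[is_case, m]; y <- eigengenes[!is_case, m]
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    data.frame(module = m, p = wt$p.value,
               median_case = stats::median(x), median_control = stats::median(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_q(out$p)
  out[, c("module", "p", "p_adj", "median_case", "median_control")]
}

#' Rank module members by intramodular connectivity (hub report)
#'
#' Members sorted by their within-module adjacency row sum (diagonal
#' excluded), ties broken by locus key order; optionally mapped to
#' promoter genes.
#'
#' @param modules A `cometh_modules`.
#' @param module Module name (e.g. `"M1"`).
#' @param top_k Number of hubs to report (default 10; capped at module
#'   size).
#' @param gene_map Optional data frame with locus `key` and `gene_id`
#'   columns (e.g. from [select_network_loci()]).
#' @return Data frame `locus`, `connectivity`, `rank`, optional
#'   `gene_id`.
#' @export
hub_report <- function(modules, module, top_k = 10, gene_map = NULL) {
  stopifnot(inherits(modules, "cometh_modules"))
  members <- modules$modules[[module]]
  if (is.null(members)) .stopf("no module named '%s'", module)
  keys <- rownames(modules$network$scores)
  idx <- match(members, keys)
  a <- modules$network$adjacency[idx, idx, drop = FALSE]
  conn <- rowSums(a) - 1
  ord <- order(-conn, members)
  k <- min(top_k, length(members))
  out <- data.frame(locus = members[ord][seq_len(k)],
                    connectivity = conn[ord][seq_len(k)],
                    rank = seq_len(k), stringsAsFactors = FALSE)
  if (!is.null(gene_map)) {
    out$gene_id <- gene_map$gene_id[match(out$locus, gene_map$key)]
  }
  out
}

#' Export the network edge list above an adjacency threshold
#'
#' @param network A `cometh_network`.
#' @param threshold Minimum adjacency (default 0.1).
#' @return Data frame `locus_i`, `locus_j`, `adjacency` (i < j).
#' @export
network_edges <- function(network, threshold = 0.1) {
  a <- network$adjacency
  keys <- rownames(network$scores)
  idx <- which(upper.tri(a) & a >= threshold, arr.ind = TRUE)
  out <- data.frame(locus_i = keys[idx[, 1]], locus_j = keys[idx[, 2]],
                    adjacency = a[idx], stringsAsFactors = FALSE)
  out[order(out$locus_i, out$locus_j), , drop = FALSE]
}
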
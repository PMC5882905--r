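# Shared fixtures: small simulated studies and hand-built objects.

# Reduced-scale study configuration used where many seeds are needed.
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 1L, n_islands = 40L,
         cpgs_per_island = 25, n_genes = 25L, n_enhancers = 10L,
         n_hyper_dmrs = 6L, n_hypo_dmrs = 8L, dmr_n_cpgs = 5L,
         planted_set_size = 10L, n_decoy_sets = 10L, decoy_set_size = 10L),
    list(...))
  do.call(sim_config, args)
}

# Tiny deterministic meth_matrix built from explicit counts.
# counts: list of per-sample data.frames (chrom,pos,strand,count_meth,count_unmeth)
toy_matrix <- function(meth, unmeth, groups, stage = "w6") {
  n <- nrow(meth)
  loci <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L, strand = "+")
  samples <- data.frame(
    sample_id = colnames(meth),
    group = groups,
    stage = stage,
    replicate = stats::ave(seq_along(groups), groups, FUN = seq_along))
  calls <- lapply(seq_along(groups), function(j) {
    data.frame(loci, count_meth = meth[, j], count_unmeth = unmeth[, j])
  })
  names(calls) <- colnames(meth)
  build_meth_matrix(calls, samples)
}

# Classified DMC records built directly (for DMR-level tests).
make_records <- function(pos, diff, p, status, chrom = "chr1") {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), strand = "+",
                   m_case = NA_real_, m_ctrl = NA_real_,
                   diff = diff, p = p, q = p, status = status,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$pos), ]
}

# Brute-force O(n^2) DMR merge oracle: same rule as call_dmrs, written
# independently (explicit pairwise pass rather than run-length grouping).
brute_force_dmrs <- function(records, gap, min_cpgs = 3, min_dmcs = 1,
                             mean_diff_threshold = 20) {
  dmc <- records[records$status != "ns", ]
  dmc <- dmc[order(dmc$chrom, dmc$pos), ]
  if (!nrow(dmc)) return(NULL)
  groups <- list(1L)
  for (i in seq_len(nrow(dmc))[-1]) {
    prev <- dmc[i - 1, ]
    joins <- prev$chrom == dmc$chrom[i] && prev$status == dmc$status[i] &&
      dmc$pos[i] - prev$pos <= gap
    if (joins) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], i)
    } else {
      groups[[length(groups) + 1]] <- i
    }
  }
  out <- lapply(groups, function(idx) {
    sub <- dmc[idx, ]
    span <- records$chrom == sub$chrom[1] &
      records$pos >= min(sub$pos) & records$pos <= max(sub$pos)
    covered <- records[span, ]
    data.frame(chrom = sub$chrom[1], start = min(sub$pos), end = max(sub$pos),
               n_cpgs = nrow(covered), n_dmcs = nrow(sub),
               mean_diff = mean(covered$diff), status = sub$status[1])
  })
  out <- do.call(rbind, out)
  out <- out[out$n_cpgs >= min_cpgs & out$n_dmcs >= min_dmcs &
               abs(out$mean_diff) >= mean_diff_threshold, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Choose()-ratio summation oracle for the hypergeometric upper tail.
hyper_tail_oracle <- function(k, n_set, n_universe, n_query) {
  kk <- k:min(n_set, n_query)
  sum(choose(n_set, kk) * choose(n_universe - n_set, n_query - kk)) /
    choose(n_universe, n_query)
}
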
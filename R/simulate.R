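#' Configuration for the synthetic ERRBS-like data generator
#'
#' The generator emulates enhanced reduced-representation bisulfite
#' sequencing of a staged case/control study: CpGs clustered into islands
#' (bimodal inter-CpG distances), negative-binomial coverage,
#' beta-binomial replicate noise around a bimodal baseline methylation
#' landscape, and stage-progressive hyper-/hypomethylated regions spiked
#' into case samples with known ground truth. A configurable fraction of
#' the hypermethylated regions is planted into promoters of a designated
#' "planted" gene set so that downstream set enrichment is testable.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_chroms Number of chromosomes.
#' @param n_islands Islands per chromosome.
#' @param cpgs_per_island Mean CpGs per island (Poisson).
#' @param within_gap_log10,within_gap_sd Log10 mean/sd of within-island
#'   inter-CpG distance (tens of bp).
#' @param between_gap_log10,between_gap_sd Log10 mean/sd of between-island
#'   gaps (kb scale).
#' @param coverage_mean,coverage_size Negative-binomial coverage model
#'   (mean/size), truncated at 1.
#' @param baseline_low,baseline_high Beta shape pairs for the low
#'   (island/promoter) and high (open sea) baseline methylation modes.
#' @param high_mode_prob Probability that a non-promoter island draws from
#'   the high mode.
#' @param precision Beta-binomial precision of replicate noise.
#' @param stages Ordered stage labels.
#' @param multipliers Monotone non-decreasing stage effect multipliers in
#'   (0, 1].
#' @param n_hyper_dmrs,n_hypo_dmrs Numbers of spiked regions (more hypo
#'   than hyper by default, matching the direction bias of tumour
#'   hypomethylation).
#' @param delta Spike effect size in percentage points.
#' @param dmr_n_cpgs CpGs per spiked region (>= 3).
#' @param n_case,n_control Replicates per group per stage.
#' @param n_genes Number of genes (each TSS centred on an island).
#' @param n_enhancers Number of enhancer intervals.
#' @param enhancer_near_gene_frac Fraction of enhancers placed within
#'   10 kb of a gene TSS.
#' @param planted_frac Fraction of hyper spikes placed in promoters of
#'   planted-set genes.
#' @param planted_set_size,n_decoy_sets,decoy_set_size Gene-set collection
#'   geometry (one planted set plus random decoys).
#' @param expression_shift,expression_sd,expression_se Log-fold-change
#'   shift applied to genes with promoter hyper spikes, biological sd of
#'   null logFC, and the standard error used for the DE p-value.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       n_islands = 150L,
                       cpgs_per_island = 67,
                       within_gap_log10 = 1.3, within_gap_sd = 0.15,
                       between_gap_log10 = 3.5, between_gap_sd = 0.15,
                       coverage_mean = 30, coverage_size = 5,
                       baseline_low = c(2, 18), baseline_high = c(12, 3),
                       high_mode_prob = 0.8,
                       precision = 50,
                       stages = c("w6", "w8", "w10", "w12"),
                       multipliers = c(0.6, 0.7, 0.9, 1.0),
                       n_hyper_dmrs = 20L, n_hypo_dmrs = 30L,
                       delta = 40,
                       dmr_n_cpgs = 8L,
                       n_case = 3L, n_control = 3L,
                       n_genes = 200L,
                       n_enhancers = 50L,
                       enhancer_near_gene_frac = 0.7,
                       planted_frac = 0.6,
                       planted_set_size = 20L,
                       n_decoy_sets = 50L,
                       decoy_set_size = 20L,
                       expression_shift = -1.0,
                       expression_sd = 0.5,
                       expression_se = 0.3) {
  cfg <- as.list(environment())
  if (length(cfg$multipliers) != length(cfg$stages)) {
    .stopf("need one stage multiplier per stage")
  }
  if (any(cfg$multipliers <= 0) || any(cfg$multipliers > 1)) {
    .stopf("stage multipliers must lie in (0, 1]")
  }
  if (is.unsorted(cfg$multipliers)) {
    .stopf("stage multipliers must be non-decreasing")
  }
  if (cfg$dmr_n_cpgs < 3) .stopf("spiked regions must cover >= 3 CpGs")
  if (cfg$n_genes > cfg$n_chroms * cfg$n_islands) {
    .stopf("more genes than islands: infeasible geometry")
  }
  if (cfg$n_hyper_dmrs > cfg$n_genes) {
    .stopf("more hyper spikes than gene promoters available")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ERRBS study configuration\n")
  cat(sprintf("  %d chrom(s) x %d islands, ~%d CpGs/island\n",
              x$n_chroms, x$n_islands, round(x$cpgs_per_island)))
  cat(sprintf("  stages: %s (multipliers %s)\n",
              paste(x$stages, collapse = " < "),
              paste(x$multipliers, collapse = ", ")))
  cat(sprintf("  spikes: %d hyper + %d hypo, delta = %g pp, %d CpGs each\n",
              x$n_hyper_dmrs, x$n_hypo_dmrs, x$delta, x$dmr_n_cpgs))
  cat(sprintf("  %d case vs %d control per stage, coverage NB(mean %g, size %g)\n",
              x$n_case, x$n_control, x$coverage_mean, x$coverage_size))
  invisible(x)
}

#' Simulate the genome layout: CpG islands, genes, enhancers
#'
#' CpG positions are laid down island by island so that inter-CpG
#' distances are bimodal (tens of bp within islands, kb between). Gene
#' TSSs are centred on islands, so every promoter (TSS +/- 2 kb) covers at
#' least one island; promoter islands draw baseline methylation from the
#' low beta mode, other islands mostly from the high mode.
#'
#' @param config A [sim_config()].
#' @return A list with `cpgs` (chrom, pos, strand, island, baseline),
#'   `genes` (gene_id, chrom, strand, tss, tes), `enhancers` (1-based
#'   inclusive intervals), and `islands`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(derive_seed(config$seed, "genome"))
  cpg_list <- list(); island_list <- list()
  island_id <- 0L
  for (ch in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ch)
    cursor <- 1000
    for (isl in seq_len(config$n_islands)) {
      island_id <- island_id + 1L
      cursor <- cursor + round(10^stats::rnorm(1, config$between_gap_log10,
                                               config$between_gap_sd))
      n_cpg <- max(3L, stats::rpois(1, config$cpgs_per_island))
      gaps <- pmax(2, round(10^stats::rnorm(n_cpg - 1, config$within_gap_log10,
                                            config$within_gap_sd)))
      pos <- cursor + c(0, cumsum(gaps))
      strand <- sample(c("+", "-"), n_cpg, replace = TRUE)
      cpg_list[[island_id]] <- data.frame(
        chrom = chrom, pos = as.integer(pos), strand = strand,
        island = island_id, stringsAsFactors = FALSE)
      island_list[[island_id]] <- data.frame(
        island = island_id, chrom = chrom,
        start = as.integer(min(pos)), end = as.integer(max(pos)),
        n_cpgs = n_cpg, stringsAsFactors = FALSE)
      cursor <- max(pos)
    }
  }
  cpgs <- do.call(rbind, cpg_list)
  islands <- do.call(rbind, island_list)

  # genes: TSS at island centres, spread over islands
  gene_islands <- sort(sample(islands$island, config$n_genes))
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(config$n_genes)),
    chrom = islands$chrom[match(gene_islands, islands$island)],
    strand = rep_len(c("+", "-"), config$n_genes),
    tss = as.integer(round((islands$start + islands$end)[match(gene_islands, islands$island)] / 2)),
    island = gene_islands,
    stringsAsFactors = FALSE
  )
  genes$tes <- as.integer(ifelse(genes$strand == "+", genes$tss + 5000L,
                                 pmax(1L, genes$tss - 5000L)))

  # baseline methylation: promoter islands low, others mostly high
  is_promoter_island <- islands$island %in% gene_islands
  island_mode <- ifelse(is_promoter_island, "low",
                        ifelse(stats::runif(nrow(islands)) < config$high_mode_prob,
                               "high", "low"))
  mode_per_cpg <- island_mode[match(cpgs$island, islands$island)]
  n <- nrow(cpgs)
  baseline <- numeric(n)
  lo <- mode_per_cpg == "low"
  baseline[lo] <- stats::rbeta(sum(lo), config$baseline_low[1], config$baseline_low[2])
  baseline[!lo] <- stats::rbeta(sum(!lo), config$baseline_high[1], config$baseline_high[2])
  cpgs$baseline <- pmin(0.99, pmax(0.01, baseline))
  islands$mode <- island_mode

  # enhancers: a fraction near gene TSSs, the rest over non-promoter islands
  n_near <- round(config$enhancer_near_gene_frac * config$n_enhancers)
  near_genes <- sample(seq_len(nrow(genes)), n_near, replace = n_near > nrow(genes))
  near_start <- genes$tss[near_genes] + sample(4000:6000, n_near, replace = TRUE)
  enh_near <- data.frame(chrom = genes$chrom[near_genes],
                         start = as.integer(near_start),
                         end = as.integer(near_start + 1000L))
  far_pool <- islands[!is_promoter_island, , drop = FALSE]
  n_far <- config$n_enhancers - n_near
  far_rows <- sample(seq_len(nrow(far_pool)), n_far)
  enh_far <- data.frame(chrom = far_pool$chrom[far_rows],
                        start = far_pool$start[far_rows],
                        end = far_pool$end[far_rows])
  enhancers <- rbind(enh_near, enh_far)
  enhancers <- enhancers[order(enhancers$chrom, enhancers$start), , drop = FALSE]
  enhancers$name <- sprintf("ENH%03d", seq_len(nrow(enhancers)))
  enhancers$score <- 0
  enhancers$strand <- "+"
  rownames(enhancers) <- NULL
  list(cpgs = cpgs, genes = genes, enhancers = enhancers, islands = islands)
}

#' Plant ground-truth differentially methylated regions
#'
#' Hypermethylated spikes go into promoter islands (low baseline, room to
#' rise); a `planted_frac` fraction of them into promoters of the planted
#' gene set. Hypomethylated spikes go into high-baseline non-promoter
#' islands. Each spike is a run of consecutive CpGs.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return A list with `dmrs` (chrom, start, end, direction, gene_id,
#'   n_cpgs, per-stage expected delta), `cpg_keys` per direction,
#'   `planted_genes`, and `planted_set_name`.
#' @export
plant_truth <- function(config, genome) {
  local_seed(derive_seed(config$seed, "truth"))
  cpgs <- genome$cpgs; islands <- genome$islands; genes <- genome$genes

  pick_run <- function(island_id) {
    idx <- which(cpgs$island == island_id)
    n <- min(config$dmr_n_cpgs, length(idx))
    start <- if (length(idx) > n) idx[sample.int(length(idx) - n + 1, 1)] else idx[1]
    start:(start + n - 1)
  }

  # hyper spikes in gene promoter islands
  n_planted <- round(config$planted_frac * config$n_hyper_dmrs)
  hyper_gene_rows <- sample(seq_len(nrow(genes)), config$n_hyper_dmrs)
  planted_rows <- hyper_gene_rows[seq_len(n_planted)]
  planted_genes <- genes$gene_id[planted_rows]

  # hypo spikes in high-mode non-promoter islands
  hypo_pool <- islands$island[islands$mode == "high" &
                                !(islands$island %in% genes$island)]
  if (length(hypo_pool) < config$n_hypo_dmrs) {
    .stopf("not enough high-baseline islands for %d hypo spikes", config$n_hypo_dmrs)
  }
  hypo_islands <- sample(hypo_pool, config$n_hypo_dmrs)

  rows <- list(); keys_hyper <- character(); keys_hypo <- character()
  spiked <- integer(0)
  add_spike <- function(island_id, direction, gene_id) {
    run <- pick_run(island_id)
    spiked <<- c(spiked, run)
    sub <- cpgs[run, ]
    if (direction == "hyper") {
      keys_hyper <<- c(keys_hyper, locus_key(sub$chrom, sub$pos, sub$strand))
    } else {
      keys_hypo <<- c(keys_hypo, locus_key(sub$chrom, sub$pos, sub$strand))
    }
    data.frame(chrom = sub$chrom[1], start = min(sub$pos), end = max(sub$pos),
               direction = direction, gene_id = gene_id, n_cpgs = length(run),
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(hyper_gene_rows)) {
    g <- hyper_gene_rows[i]
    rows[[length(rows) + 1]] <- add_spike(genes$island[g], "hyper", genes$gene_id[g])
  }
  for (isl in hypo_islands) {
    rows[[length(rows) + 1]] <- add_spike(isl, "hypo", NA_character_)
  }
  dmrs <- do.call(rbind, rows)
  for (s in seq_along(config$stages)) {
    dmrs[[paste0("delta_", config$stages[s])]] <-
      ifelse(dmrs$direction == "hyper", 1, -1) * config$delta * config$multipliers[s]
  }
  list(dmrs = dmrs,
       cpg_keys = list(hyper = keys_hyper, hypo = keys_hypo),
       spiked_idx = spiked,
       planted_genes = planted_genes,
       planted_set_name = "PLANTED_PRC2_TARGETS")
}

#' Simulate per-sample methylation call tables
#'
#' Coverage is negative binomial truncated at 1; per-CpG per-sample
#' methylation proportions are beta-distributed around the group mean
#' (precision `config$precision`) and methylated counts are binomial.
#' Case group means are shifted by `direction * delta * multiplier(stage)`
#' inside spiked regions and clipped to \[0.01, 0.99\]; controls are never
#' shifted.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param truth Output of [plant_truth()].
#' @return A list with `calls` (named list of call data frames) and
#'   `samples` (sample sheet data frame).
#' @export
simulate_counts <- function(config, genome, truth) {
  local_seed(derive_seed(config$seed, "counts"))
  cpgs <- genome$cpgs
  n <- nrow(cpgs)
  keys <- locus_key(cpgs$chrom, cpgs$pos, cpgs$strand)
  dir_vec <- numeric(n)
  dir_vec[keys %in% truth$cpg_keys$hyper] <- 1
  dir_vec[keys %in% truth$cpg_keys$hypo] <- -1

  samples <- expand.grid(replicate = seq_len(max(config$n_case, config$n_control)),
                         group = c("case", "control"),
                         stage = config$stages,
                         stringsAsFactors = FALSE)
  samples <- samples[(samples$group == "case" & samples$replicate <= config$n_case) |
                       (samples$group == "control" & samples$replicate <= config$n_control), ]
  samples <- samples[order(match(samples$stage, config$stages),
                           samples$group, samples$replicate), ]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$group, samples$stage,
                               samples$replicate)
  samples <- samples[, c("sample_id", "group", "stage", "replicate")]
  rownames(samples) <- NULL

  base <- pmin(0.99, pmax(0.01, cpgs$baseline))
  calls <- vector("list", nrow(samples))
  names(calls) <- samples$sample_id
  for (i in seq_len(nrow(samples))) {
    st <- samples$stage[i]
    mult <- config$multipliers[match(st, config$stages)]
    mu <- base
    if (samples$group[i] == "case") {
      mu <- pmin(0.99, pmax(0.01, base + dir_vec * (config$delta / 100) * mult))
    }
    coverage <- stats::rnbinom(n, size = config$coverage_size, mu = config$coverage_mean)
    coverage[coverage < 1] <- 1L
    p <- stats::rbeta(n, mu * config$precision, (1 - mu) * config$precision)
    count_meth <- stats::rbinom(n, coverage, p)
    calls[[i]] <- data.frame(
      chrom = cpgs$chrom, pos = cpgs$pos, strand = cpgs$strand,
      count_meth = as.integer(count_meth),
      count_unmeth = as.integer(coverage - count_meth),
      stringsAsFactors = FALSE)
  }
  list(calls = calls, samples = validate_sample_sheet(samples, config$stages))
}

#' Simulate a differential-expression table coupled to the methylation truth
#'
#' Genes whose promoters carry hypermethylation spikes receive a negative
#' log-fold-change shift; all genes get Gaussian biological noise, a
#' Wald-type p-value and BH FDR.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param truth Output of [plant_truth()].
#' @return Data frame `gene_id`, `logFC`, `fdr`.
#' @export
simulate_expression <- function(config, genome, truth) {
  local_seed(derive_seed(config$seed, "expression"))
  genes <- genome$genes
  shift <- ifelse(genes$gene_id %in% truth$dmrs$gene_id[truth$dmrs$direction == "hyper"],
                  config$expression_shift, 0)
  logFC <- shift + stats::rnorm(nrow(genes), 0, config$expression_sd)
  p <- 2 * stats::pnorm(-abs(logFC / config$expression_se))
  data.frame(gene_id = genes$gene_id, logFC = logFC,
             fdr = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
}

#' Build the gene-set collection with one planted set plus random decoys
#'
#' The planted set contains the planted (hyper-spiked) genes padded with
#' random unspiked genes up to `planted_set_size`; decoy sets are random
#' draws from all genes.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param truth Output of [plant_truth()].
#' @return Named list of gene-id vectors (GMT-compatible).
#' @export
simulate_gene_sets <- function(config, genome, truth) {
  local_seed(derive_seed(config$seed, "genesets"))
  all_genes <- genome$genes$gene_id
  pad <- setdiff(all_genes, truth$planted_genes)
  planted <- c(truth$planted_genes,
               sample(pad, max(0, config$planted_set_size - length(truth$planted_genes))))
  sets <- list()
  sets[[truth$planted_set_name]] <- planted
  for (i in seq_len(config$n_decoy_sets)) {
    sets[[sprintf("DECOY_%03d", i)]] <- sample(all_genes, config$decoy_set_size)
  }
  sets
}

#' Simulate a complete staged methylation study
#'
#' Convenience wrapper running [simulate_genome()], [plant_truth()],
#' [simulate_counts()], [simulate_expression()] and
#' [simulate_gene_sets()].
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list with elements `config`, `genome`, `truth`,
#'   `calls`, `samples`, `expression`, `gene_sets`.
#' @export
simulate_methylation_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  truth <- plant_truth(config, genome)
  counts <- simulate_counts(config, genome, truth)
  out <- list(config = config, genome = genome, truth = truth,
              calls = counts$calls, samples = counts$samples,
              expression = simulate_expression(config, genome, truth),
              gene_sets = simulate_gene_sets(config, genome, truth))
  class(out) <- "sim_dataset"
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic ERRBS dataset: %d CpGs, %d samples, %d stages\n",
              nrow(x$genome$cpgs), length(x$calls), length(x$config$stages)))
  cat(sprintf("  planted: %d hyper + %d hypo regions; planted set '%s' (%d genes)\n",
              sum(x$truth$dmrs$direction == "hyper"),
              sum(x$truth$dmrs$direction == "hypo"),
              x$truth$planted_set_name, length(x$truth$planted_genes)))
  invisible(x)
}

#' Write a simulated dataset to a directory in pipeline input layout
#'
#' Emits methylKit-dialect call tables under `calls/`, `sample_sheet.tsv`,
#' `genes.tsv`, `enhancers.bed`, `gene_sets.gmt`, `expression.tsv`, the
#' ground truth (`truth_dmrs.tsv`, `truth.json`) and the configuration as
#' YAML.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  for (sid in names(dataset$calls)) {
    write_methylation_calls(dataset$calls[[sid]],
                            file.path(dir, "calls", paste0(sid, ".txt")))
  }
  ss <- dataset$samples
  ss$stage <- as.character(ss$stage)
  write_tsv(ss, file.path(dir, "sample_sheet.tsv"))
  write_tsv(dataset$genome$genes[, c("gene_id", "chrom", "strand", "tss", "tes")],
            file.path(dir, "genes.tsv"))
  write_bed(dataset$genome$enhancers, file.path(dir, "enhancers.bed"))
  write_gmt(dataset$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_tsv(dataset$expression, file.path(dir, "expression.tsv"))
  write_tsv(dataset$truth$dmrs, file.path(dir, "truth_dmrs.tsv"))
  write_json(list(planted_set_name = dataset$truth$planted_set_name,
                  planted_genes = dataset$truth$planted_genes,
                  hyper_cpgs = dataset$truth$cpg_keys$hyper,
                  hypo_cpgs = dataset$truth$cpg_keys$hypo),
             file.path(dir, "truth.json"))
  cfg <- unclass(dataset$config)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Simulate a locus-by-sample score matrix with block correlation structure
#'
#' Generates methylation-score-like profiles with planted co-methylation
#' modules: loci within a block share a latent per-sample factor with
#' correlation about `rho`; background loci are independent noise. Used to
#' exercise network module detection and preservation directly, where
#' correlation structure (not mean shifts) is the quantity of interest.
#'
#' @param n_samples Number of samples (columns).
#' @param block_sizes Integer vector of planted block sizes.
#' @param n_background Number of unstructured background loci.
#' @param rho Within-block correlation of planted loci: a single value for
#'   uniform blocks, or a length-2 range giving graded per-member factor
#'   loadings (hub structure, so intramodular connectivity has an
#'   intrinsic, reproducible ordering).
#' @param seed Integer seed.
#' @return A list with `scores` (matrix loci x samples, rownames are locus
#'   keys) and `membership` (integer vector, 0 = background).
#' @export
simulate_comethylation_scores <- function(n_samples = 24, block_sizes = c(50, 50),
                                          n_background = 100, rho = 0.8,
                                          seed = 1L) {
  local_seed(derive_seed(seed, "cometh"))
  n <- sum(block_sizes) + n_background
  membership <- c(rep(seq_along(block_sizes), block_sizes), rep(0L, n_background))
  scores <- matrix(stats::rnorm(n * n_samples), n, n_samples)
  for (b in seq_along(block_sizes)) {
    f <- stats::rnorm(n_samples)
    idx <- which(membership == b)
    ld <- if (length(rho) == 2) {
      seq(rho[1], rho[2], length.out = length(idx))
    } else {
      rep(rho, length(idx))
    }
    scores[idx, ] <- sqrt(ld) * matrix(f, length(idx), n_samples, byrow = TRUE) +
      sqrt(1 - ld) * scores[idx, ]
  }
  rownames(scores) <- locus_key("chrS", seq_len(n) * 100L, "+")
  colnames(scores) <- sprintf("s%02d", seq_len(n_samples))
  list(scores = scores, membership = membership)
}
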
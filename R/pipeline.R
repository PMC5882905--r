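#' Pipeline configuration
#'
#' Collects every threshold and seed the pipeline consumes. Each random
#' stage derives its own seed deterministically from the global seed and
#' the stage name, and the configuration is serialised into every output
#' directory so a run can be reproduced from its artifacts alone.
#'
#' @param seed Global integer seed.
#' @param min_coverage,max_cov_percentile Coverage filter (defaults 10 and
#'   99.9).
#' @param dmc_diff,dmc_q DMC thresholds (percentage points, q; defaults 10
#'   and 0.01).
#' @param display_diff Stricter difference threshold used only for
#'   display-style summaries (default 25).
#' @param dmr_mean_diff,dmr_min_cpgs,dmr_min_dmcs,dmr_q DMR filters
#'   (defaults 20, 3, 1, 0.05).
#' @param promoter_window,upstream_window,enhancer_target_window
#'   Annotation windows in bp (defaults 2000, 2000, 10000).
#' @param perm_B Compartment permutation replicates (default 1000).
#' @param n_perm_preservation Preservation permutations (default 200).
#' @param trajectory_k Trajectory cluster count (default 3).
#' @param beta,min_module_size Network soft power and minimum module size
#'   (defaults 12 and 30).
#' @param de_fdr Differential-expression FDR cutoff (default 0.05).
#' @param early_stages,late_stages Stage partition for the transition
#'   contrast (defaults: first two vs last two stages of the sheet).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            min_coverage = 10, max_cov_percentile = 99.9,
                            dmc_diff = 10, dmc_q = 0.01,
                            display_diff = 25,
                            dmr_mean_diff = 20, dmr_min_cpgs = 3,
                            dmr_min_dmcs = 1, dmr_q = 0.05,
                            promoter_window = 2000, upstream_window = 2000,
                            enhancer_target_window = 10000,
                            perm_B = 1000, n_perm_preservation = 200,
                            trajectory_k = 3,
                            beta = 12, min_module_size = 30,
                            de_fdr = 0.05,
                            early_stages = NULL, late_stages = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with `pipeline_config` fields.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' Principal-component QC of methylation profiles
#'
#' PCA of the sample-by-locus methylation score matrix (loci standardised;
#' zero-variance loci dropped). Samples further than `k_mad` MADs from the
#' median on PC1 or PC2 are flagged as outliers -- a QC suggestion only,
#' never removed automatically.
#'
#' @param scores Locus x sample score matrix (see [meth_scores()]).
#' @param samples Sample sheet aligned with the columns.
#' @param k_mad Outlier flag threshold in MADs (default 5).
#' @return List with `coordinates` (samples x PCs), `var_explained`
#'   (fractions summing to 1), `outliers` (logical per sample).
#' @export
qc_pca <- function(scores, samples, k_mad = 5) {
  if (ncol(scores) < 3) .stopf("PCA needs >= 3 samples")
  v <- apply(scores, 1, stats::var)
  x <- t(scores[v > 0, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  flag <- function(z) {
    m <- stats::mad(z)
    if (m == 0) rep(FALSE, length(z)) else abs(z - stats::median(z)) > k_mad * m
  }
  outliers <- flag(pc$x[, 1]) | flag(pc$x[, 2])
  names(outliers) <- samples$sample_id
  list(coordinates = pc$x, var_explained = ve, outliers = outliers)
}

#' Score pipeline output against the generator's ground truth
#'
#' Computes, for simulated runs: per-CpG DMC sensitivity and observed
#' false-discovery rate at the final stage (direction-aware), base-pair
#' Jaccard overlap between called and planted regions, and the planted
#' gene set's enrichment FDR and rank among decoys.
#'
#' @param stage_records Named list of classified DMC records.
#' @param stage_dmrs Named list of `dmr_set` data frames.
#' @param enrichment Enrichment table from [overlap_enrichment()] (or
#'   NULL).
#' @param truth Generator ground truth (see [plant_truth()]).
#' @param stage Stage to score (default: last of `stage_records`).
#' @return List of metrics (`dmc_sensitivity`, `dmc_fdr`, `dmr_jaccard`,
#'   `planted_set_fdr`, `planted_set_rank`).
#' @export
evaluate_against_truth <- function(stage_records, stage_dmrs, enrichment = NULL,
                                   truth, stage = NULL) {
  stage <- stage %||% names(stage_records)[length(stage_records)]
  rec <- stage_records[[stage]]
  keys <- locus_key(rec$chrom, rec$pos, rec$strand)
  true_hyper <- intersect(truth$cpg_keys$hyper, keys)
  true_hypo <- intersect(truth$cpg_keys$hypo, keys)
  called_hyper <- keys[rec$status == "hyper"]
  called_hypo <- keys[rec$status == "hypo"]
  tp <- length(intersect(called_hyper, true_hyper)) +
    length(intersect(called_hypo, true_hypo))
  n_called <- length(called_hyper) + length(called_hypo)
  n_true <- length(true_hyper) + length(true_hypo)
  sens <- if (n_true) tp / n_true else NA_real_
  fdr <- if (n_called) {
    fp <- length(setdiff(called_hyper, true_hyper)) +
      length(setdiff(called_hypo, true_hypo))
    fp / n_called
  } else NA_real_
  jac <- NA_real_
  dmrs <- stage_dmrs[[stage]]
  if (!is.null(dmrs) && nrow(dmrs)) {
    called_gr <- GenomicRanges::reduce(interval_granges(dmrs))
    truth_gr <- GenomicRanges::reduce(interval_granges(truth$dmrs))
    inter <- sum(IRanges::width(GenomicRanges::intersect(called_gr, truth_gr)))
    uni <- sum(IRanges::width(GenomicRanges::union(called_gr, truth_gr)))
    jac <- inter / uni
  }
  planted_fdr <- NA_real_; planted_rank <- NA_real_
  if (!is.null(enrichment)) {
    i <- match(truth$planted_set_name, enrichment$set_name)
    if (!is.na(i)) {
      planted_fdr <- enrichment$fdr[i]
      planted_rank <- i
    }
  }
  list(stage = stage, dmc_sensitivity = sens, dmc_fdr = fdr,
       dmc_called = n_called, dmc_true = n_true,
       dmr_jaccard = jac,
       planted_set_fdr = planted_fdr, planted_set_rank = planted_rank)
}

# ---- pipeline orchestration -------------------------------------------------

stage_done <- function(outdir, files) all(file.exists(file.path(outdir, files)))

#' Run the full methylation progression pipeline
#'
#' Orchestrates qc -> dmc -> dmr -> trajectory -> annotate -> enrich ->
#' network over a pipeline input directory (the layout written by
#' [write_simulation()]): per-stage DMC tables, DMR calls and their
#' cross-stage union, trajectory clustering, compartment annotation with
#' permutation enrichment, gene-set enrichment with expression
#' integration, the premalignant/malignant transition contrast, and the
#' co-methylation network with preservation statistics. Each stage is
#' skipped when its artifacts already exist and nothing upstream was
#' recomputed, so deleting one stage directory re-runs only that stage
#' and its dependents. All outputs are plain TSV/JSON with deterministic
#' content for a fixed configuration.
#'
#' @param input_dir Directory with `calls/`, `sample_sheet.tsv`,
#'   `genes.tsv`, `enhancers.bed`, `gene_sets.gmt`, optional
#'   `expression.tsv`.
#' @param output_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory results per stage.
#' @export
run_pipeline <- function(input_dir, output_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("sample_sheet.tsv", "genes.tsv", "calls")
  missing <- need[!file.exists(file.path(input_dir, need))]
  if (length(missing)) {
    .stopf("missing pipeline input(s) in %s: %s", input_dir,
           paste(missing, collapse = ", "))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_json(unclass(config), file.path(output_dir, "config.json"))

  samples <- read_sample_sheet(file.path(input_dir, "sample_sheet.tsv"))
  genes <- read_gene_model(file.path(input_dir, "genes.tsv"))
  enh_path <- file.path(input_dir, "enhancers.bed")
  enhancers <- if (file.exists(enh_path)) read_bed(enh_path) else NULL
  gmt_path <- file.path(input_dir, "gene_sets.gmt")
  gene_sets <- if (file.exists(gmt_path)) read_gmt(gmt_path) else NULL
  expr_path <- file.path(input_dir, "expression.tsv")
  expression <- if (file.exists(expr_path)) read_expression(expr_path) else NULL

  calls <- lapply(stats::setNames(samples$sample_id, samples$sample_id), function(sid) {
    read_methylation_calls(file.path(input_dir, "calls", paste0(sid, ".txt")),
                           "methylkit")
  })
  mat_raw <- build_meth_matrix(calls, samples)
  # coverage filter over all samples: used for QC, the pooled transition
  # contrast and the network; per-stage contrasts re-filter on their own
  # six samples only (the coverage requirement applies to the samples in
  # the contrast, not the whole study)
  mat <- filter_loci(mat_raw, config$min_coverage, config$max_cov_percentile)
  scores <- meth_scores(mat)
  annotation <- build_annotation(genes, enhancers, config$promoter_window,
                                 config$enhancer_target_window)
  stages <- levels(samples$stage)
  results <- list(matrix = mat, annotation = annotation)
  ran <- character()

  run_stage <- function(name, files, fn) {
    sdir <- file.path(output_dir, name)
    if (stage_done(sdir, files) && !length(ran)) {
      message(sprintf("[%s] up to date; skipping", name))
      return(invisible(NULL))
    }
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    fn(sdir)
    ran <<- c(ran, name)
    invisible(NULL)
  }

  # qc ------------------------------------------------------------------
  run_stage("qc", "pca.tsv", function(sdir) {
    pca <- qc_pca(scores, samples)
    df <- data.frame(sample_id = samples$sample_id,
                     round(pca$coordinates[, seq_len(min(4, ncol(pca$coordinates)))], 6),
                     outlier = pca$outliers, row.names = NULL)
    write_tsv(df, file.path(sdir, "pca.tsv"))
    write_json(list(var_explained = round(pca$var_explained, 6)),
               file.path(sdir, "variance.json"))
    results$qc <<- pca
  })

  # dmc -----------------------------------------------------------------
  dmc_files <- c(paste0("dmc_", stages, ".tsv"), "stage_summary.json")
  run_stage("dmc", dmc_files, function(sdir) {
    recs <- lapply(stats::setNames(stages, stages), function(st) {
      ids <- samples$sample_id[samples$stage == st]
      smat <- filter_loci(subset_samples(mat_raw, ids),
                          config$min_coverage, config$max_cov_percentile)
      call_dmcs(smat, st, diff_threshold = config$dmc_diff,
                q_threshold = config$dmc_q)
    })
    for (st in stages) {
      out <- recs[[st]]
      out$m_case <- round(out$m_case, 6); out$m_ctrl <- round(out$m_ctrl, 6)
      out$diff <- round(out$diff, 4)
      write_tsv(out, file.path(sdir, paste0("dmc_", st, ".tsv")))
    }
    dyn <- stage_dynamics(recs, annotation)
    write_json(list(counts = dyn$counts,
                    pairwise_intersections = as.data.frame(dyn$pairwise_intersections),
                    n_all_stage = length(dyn$all_stage_intersection)),
               file.path(sdir, "stage_summary.json"))
    results$dmc <<- recs
    results$dynamics <<- dyn
  })
  if (is.null(results$dmc)) {
    results$dmc <- lapply(stats::setNames(stages, stages), function(st) {
      df <- read_tsv(file.path(output_dir, "dmc", paste0("dmc_", st, ".tsv")))
      attr(df, "stage") <- st
      df
    })
  }

  # dmr + trajectory ------------------------------------------------------
  dmr_files <- c(paste0("dmr_", stages, ".tsv"), "union.tsv", "counts.json")
  run_stage("dmr", dmr_files, function(sdir) {
    gap <- estimate_gap_threshold(mat$loci)
    dmrs <- lapply(stats::setNames(stages, stages), function(st) {
      call_dmrs(results$dmc[[st]], gap = gap,
                min_cpgs = config$dmr_min_cpgs, min_dmcs = config$dmr_min_dmcs,
                mean_diff_threshold = config$dmr_mean_diff,
                q_threshold = config$dmr_q)
    })
    for (st in stages) {
      d <- as.data.frame(dmrs[[st]])
      d$mean_diff <- round(d$mean_diff, 4)
      write_tsv(d, file.path(sdir, paste0("dmr_", st, ".tsv")))
      if (nrow(d)) {
        write_bed(data.frame(chrom = d$chrom, start = d$start, end = d$end,
                             name = d$status, score = round(d$mean_diff, 2),
                             strand = "+"),
                  file.path(sdir, paste0("dmr_", st, ".bed")))
      }
    }
    uni <- union_dmrs(dmrs)
    write_tsv(uni, file.path(sdir, "union.tsv"))
    counts <- lapply(stats::setNames(stages, stages), function(st) {
      d <- dmrs[[st]]
      list(hypo = sum(d$status == "hypo"), hyper = sum(d$status == "hyper"),
           total = nrow(d))
    })
    write_json(list(gap_bp = as.numeric(gap), counts = counts),
               file.path(sdir, "counts.json"))
    results$dmr <<- dmrs
    results$dmr_union <<- uni
  })
  if (is.null(results$dmr)) {
    results$dmr <- lapply(stats::setNames(stages, stages), function(st) {
      structure(read_tsv(file.path(output_dir, "dmr", paste0("dmr_", st, ".tsv"))),
                class = c("dmr_set", "data.frame"))
    })
    results$dmr_union <- read_tsv(file.path(output_dir, "dmr", "union.tsv"))
  }

  run_stage("trajectory", c("matrix.tsv", "centers.tsv"), function(sdir) {
    uni <- results$dmr_union
    if (nrow(uni) >= config$trajectory_k) {
      traj <- dmr_trajectory_matrix(uni, results$dmc)
      cl <- trajectory_cluster(traj, k = config$trajectory_k)
      df <- data.frame(region = rownames(traj), round(traj, 4),
                       group = cl$labels, row.names = NULL, check.names = FALSE)
      write_tsv(df, file.path(sdir, "matrix.tsv"))
      write_tsv(data.frame(group = rownames(cl$centers), round(cl$centers, 4),
                           size = cl$sizes, row.names = NULL, check.names = FALSE),
                file.path(sdir, "centers.tsv"))
      results$trajectory <<- list(matrix = traj, clusters = cl)
    } else {
      write_tsv(data.frame(region = character()), file.path(sdir, "matrix.tsv"))
      write_tsv(data.frame(group = character()), file.path(sdir, "centers.tsv"))
    }
  })

  # annotate --------------------------------------------------------------
  run_stage("annotate", c("locus_annotation.tsv", "compartment_summary.json"),
            function(sdir) {
    final <- results$dmc[[stages[length(stages)]]]
    ann <- map_loci(final, annotation)
    write_tsv(cbind(final[, c("chrom", "pos", "strand", "status")], ann),
              file.path(sdir, "locus_annotation.tsv"))
    cs <- compartment_summary(final, annotation, B = config$perm_B,
                              seed = derive_seed(config$seed, "annotate"))
    cs$fractions[, -(1:2)] <- round(cs$fractions[, -(1:2)], 6)
    write_json(cs, file.path(sdir, "compartment_summary.json"))
    et <- enhancer_targets(annotation)
    write_tsv(et, file.path(sdir, "enhancer_targets.tsv"))
    results$compartments <<- cs
  })

  # enrich ----------------------------------------------------------------
  run_stage("enrich", c("transition_genes.tsv"), function(sdir) {
    covered <- map_loci(mat$loci, annotation)
    universe <- sort(unique(unlist(strsplit(
      covered$promoter_genes[covered$promoter], ","))))
    results$universe <<- universe
    if (!is.null(gene_sets)) {
      for (st in stages) {
        rec <- results$dmc[[st]]
        ann <- map_loci(rec, annotation)
        hyper_genes <- intersect(unique(unlist(strsplit(
          ann$promoter_genes[ann$promoter & rec$status == "hyper"], ","))), universe)
        if (length(hyper_genes)) {
          enr <- overlap_enrichment(hyper_genes, gene_sets, universe)
          enr$p <- signif(enr$p, 6); enr$fdr <- signif(enr$fdr, 6)
          write_tsv(enr, file.path(sdir, paste0("enrichment_", st, ".tsv")))
          results$enrichment[[st]] <<- enr
        }
        if (!is.null(expression)) {
          hypo_genes <- intersect(unique(unlist(strsplit(
            ann$promoter_genes[ann$promoter & rec$status == "hypo"], ","))), universe)
          integ <- integrate_expression(hyper_genes, hypo_genes, expression,
                                        config$de_fdr)
          write_tsv(integ$counts, file.path(sdir, paste0("integration_", st, ".tsv")))
          results$integration[[st]] <<- integ
        }
      }
    }
    early <- config$early_stages %||% stages[seq_len(floor(length(stages) / 2))]
    late <- config$late_stages %||% setdiff(stages, early)
    trans <- pooled_transition_contrast(mat, early, late, annotation,
                                        config$dmc_diff, config$dmc_q)
    write_tsv(data.frame(
      gene_id = c(trans$hyper_genes, trans$hypo_genes),
      direction = c(rep("hyper", length(trans$hyper_genes)),
                    rep("hypo", length(trans$hypo_genes)))),
      file.path(sdir, "transition_genes.tsv"))
    results$transition <<- trans
  })

  # network ---------------------------------------------------------------
  run_stage("network", c("membership.tsv", "preservation.json"), function(sdir) {
    loci <- select_network_loci(results$dmc, genes,
                                config$upstream_window, config$dmc_q)
    # restrict to loci covered in every sample (network profiles span the
    # whole study, unlike per-stage contrasts)
    loci <- loci[locus_key(loci$chrom, loci$pos, loci$strand) %in%
                   rownames(scores), , drop = FALSE]
    if (nrow(loci) < max(10, config$min_module_size)) {
      message("too few promoter-upstream DMC loci for network analysis")
      write_tsv(data.frame(locus = character(), module = character()),
                file.path(sdir, "membership.tsv"))
      write_json(list(), file.path(sdir, "preservation.json"))
      return(invisible(NULL))
    }
    key <- locus_key(loci$chrom, loci$pos, loci$strand)
    sc <- scores[key, , drop = FALSE]
    net <- build_adjacency(sc, beta = config$beta)
    mods <- detect_modules(net, min_module_size = config$min_module_size)
    memb <- data.frame(locus = rownames(net$scores),
                       module = ifelse(mods$membership == 0, "M0",
                                       paste0("M", mods$membership)),
                       gene_id = loci$gene_id[match(rownames(net$scores), key)])
    write_tsv(memb, file.path(sdir, "membership.tsv"))
    pres <- NULL
    if (length(mods$modules)) {
      case_ids <- samples$sample_id[samples$group == "case"]
      ctrl_ids <- samples$sample_id[samples$group == "control"]
      sc_net <- net$scores
      pres <- module_preservation(mods, sc_net[, case_ids, drop = FALSE],
                                  sc_net[, ctrl_ids, drop = FALSE],
                                  n_perm = config$n_perm_preservation,
                                  seed = derive_seed(config$seed, "network"))
      eg <- module_eigengenes(mods)
      write_tsv(data.frame(sample_id = rownames(eg) %||% samples$sample_id,
                           round(eg, 6), check.names = FALSE),
                file.path(sdir, "eigengenes.tsv"))
      egt <- eigengene_group_test(eg, samples)
      write_tsv(cbind(egt[1], signif(egt[-1], 6)), file.path(sdir, "eigengene_test.tsv"))
      gene_map <- data.frame(key = key, gene_id = loci$gene_id)
      hubs <- do.call(rbind, lapply(names(mods$modules), function(m) {
        cbind(module = m, hub_report(mods, m, top_k = 10, gene_map = gene_map))
      }))
      hubs$connectivity <- round(hubs$connectivity, 6)
      write_tsv(hubs, file.path(sdir, "hubs.tsv"))
    }
    write_json(list(n_loci = nrow(net$scores), beta = net$beta,
                    n_perm = config$n_perm_preservation,
                    seed = derive_seed(config$seed, "network"),
                    modules = pres),
               file.path(sdir, "preservation.json"))
    results$network <<- list(loci = loci, network = net, modules = mods,
                             preservation = pres)
  })

  invisible(results)
}
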
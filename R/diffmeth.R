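#' Per-CpG methylation score
#'
#' The methylation score of a CpG is the methylated read count divided by
#' total coverage, `M / (M + U)`.
#'
#' @param count_meth,count_unmeth Non-negative integer vectors.
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' methylation_score(3, 1)   # 0.75
#' @export
methylation_score <- function(count_meth, count_unmeth) {
  cov <- count_meth + count_unmeth
  if (any(cov < 1)) .stopf("methylation score undefined at zero coverage")
  count_meth / cov
}

#' Assemble a locus-by-sample methylation count matrix
#'
#' Joins per-sample call tables on exact (chrom, pos, strand) identity.
#' Loci absent from a sample carry NA counts until coverage filtering.
#'
#' @param calls Named list of call data frames (see
#'   [read_methylation_calls()]); names must match `samples$sample_id`.
#' @param samples Sample sheet data frame.
#' @return A `meth_matrix` object: list with `meth` and `unmeth` count
#'   matrices (loci x samples), `loci` data frame, and `samples`.
#' @export
build_meth_matrix <- function(calls, samples) {
  samples <- validate_sample_sheet(samples)
  if (!all(samples$sample_id %in% names(calls))) {
    .stopf("missing call tables for: %s",
           paste(setdiff(samples$sample_id, names(calls)), collapse = ", "))
  }
  calls <- calls[samples$sample_id]
  keys_per_sample <- lapply(calls, function(d) locus_key(d$chrom, d$pos, d$strand))
  all_keys <- unique(unlist(keys_per_sample))
  first <- do.call(rbind, lapply(calls, function(d) d[c("chrom", "pos", "strand")]))
  loci <- first[!duplicated(locus_key(first$chrom, first$pos, first$strand)), ]
  loci <- order_loci(loci)
  rownames(loci) <- NULL
  keys <- locus_key(loci$chrom, loci$pos, loci$strand)
  n <- length(keys); m <- nrow(samples)
  meth <- matrix(NA_integer_, n, m, dimnames = list(keys, samples$sample_id))
  unmeth <- meth
  for (j in seq_len(m)) {
    d <- calls[[j]]
    idx <- match(keys_per_sample[[j]], keys)
    meth[idx, j] <- d$count_meth
    unmeth[idx, j] <- d$count_unmeth
  }
  structure(list(meth = meth, unmeth = unmeth, loci = loci, samples = samples),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  filt <- attr(x, "filter")
  cat(sprintf("meth_matrix: %d loci x %d samples (%d stages)\n",
              nrow(x$loci), nrow(x$samples), nlevels(x$samples$stage)))
  if (!is.null(filt)) {
    cat(sprintf("  coverage-filtered: min %g, cap percentile %g\n",
                filt$min_coverage, filt$max_cov_percentile))
  }
  invisible(x)
}

#' Coverage-filter a methylation matrix
#'
#' Retains a locus iff every sample covers it with at least `min_coverage`
#' reads and at most its sample's `max_cov_percentile` coverage quantile
#' (a guard against PCR duplicates). The applied filter is recorded on the
#' object; re-applying the same filter is a no-op, so filtering is
#' idempotent.
#'
#' @param mat A `meth_matrix`.
#' @param min_coverage Minimum per-sample coverage (default 10).
#' @param max_cov_percentile Upper coverage percentile cap per sample
#'   (default 99.9; 100 disables the cap).
#' @return The filtered `meth_matrix`.
#' @export
filter_loci <- function(mat, min_coverage = 10, max_cov_percentile = 99.9) {
  stopifnot(inherits(mat, "meth_matrix"))
  prev <- attr(mat, "filter")
  if (!is.null(prev) && prev$min_coverage == min_coverage &&
      prev$max_cov_percentile == max_cov_percentile) {
    return(mat)
  }
  cov <- mat$meth + mat$unmeth
  keep <- rep(TRUE, nrow(cov))
  for (j in seq_len(ncol(cov))) {
    cj <- cov[, j]
    ok <- !is.na(cj) & cj >= min_coverage
    if (max_cov_percentile < 100) {
      cap <- stats::quantile(cj[!is.na(cj)], max_cov_percentile / 100,
                             names = FALSE, type = 7)
      ok <- ok & cj <= cap
    }
    keep <- keep & ok
  }
  if (!any(keep)) {
    .stopf("coverage filter removed all %d loci (min %g, cap %g%%)",
           nrow(cov), min_coverage, max_cov_percentile)
  }
  out <- structure(list(meth = mat$meth[keep, , drop = FALSE],
                        unmeth = mat$unmeth[keep, , drop = FALSE],
                        loci = mat$loci[keep, , drop = FALSE],
                        samples = mat$samples),
                   class = "meth_matrix")
  rownames(out$loci) <- NULL
  attr(out, "filter") <- list(min_coverage = min_coverage,
                              max_cov_percentile = max_cov_percentile)
  out
}

#' Subset a methylation matrix to a set of samples
#'
#' Drops unused stage levels; any prior coverage filter is cleared since
#' it applied to a different sample set.
#'
#' @param mat A `meth_matrix`.
#' @param sample_ids Sample ids to keep.
#' @return A `meth_matrix` over the selected samples.
#' @export
subset_samples <- function(mat, sample_ids) {
  stopifnot(inherits(mat, "meth_matrix"))
  if (!all(sample_ids %in% mat$samples$sample_id)) .stopf("unknown sample id")
  ss <- mat$samples[match(sample_ids, mat$samples$sample_id), , drop = FALSE]
  ss$stage <- droplevels(ss$stage)
  rownames(ss) <- NULL
  structure(list(meth = mat$meth[, sample_ids, drop = FALSE],
                 unmeth = mat$unmeth[, sample_ids, drop = FALSE],
                 loci = mat$loci, samples = ss),
            class = "meth_matrix")
}

#' Per-locus methylation score matrix
#' @param mat A `meth_matrix` (coverage-filtered; no NA counts).
#' @return Matrix of scores, loci x samples.
#' @export
meth_scores <- function(mat) {
  stopifnot(inherits(mat, "meth_matrix"))
  mat$meth / (mat$meth + mat$unmeth)
}

# Vectorised two-sided conditional exact test on 2x2 tables
# [m1, u1; m2, u2]: the p-value sums hypergeometric point probabilities
# not exceeding the observed one (with the customary 1e-7 relative
# tolerance), the same definition stats::fisher.test uses.
fisher_pooled_p <- function(m1, u1, m2, u2) {
  n <- length(m1)
  p <- numeric(n)
  for (i in seq_len(n)) {
    mm <- m1[i] + m2[i]; uu <- u1[i] + u2[i]; k <- m1[i] + u1[i]
    lo <- max(0L, k - uu); hi <- min(k, mm)
    d <- stats::dhyper(lo:hi, mm, uu, k)
    p[i] <- min(1, sum(d[d <= d[m1[i] - lo + 1] * (1 + 1e-7)]))
  }
  p
}

# Internal two-group contrast on pooled counts: returns diff (pp) and p.
contrast_loci <- function(mat, case_ids, ctrl_ids,
                          method = c("fisher_pooled", "logistic")) {
  method <- match.arg(method)
  m_case <- rowSums(mat$meth[, case_ids, drop = FALSE])
  u_case <- rowSums(mat$unmeth[, case_ids, drop = FALSE])
  m_ctrl <- rowSums(mat$meth[, ctrl_ids, drop = FALSE])
  u_ctrl <- rowSums(mat$unmeth[, ctrl_ids, drop = FALSE])
  ok <- (m_case + u_case) >= 1 & (m_ctrl + u_ctrl) >= 1
  if (!all(ok)) {
    message(sprintf("skipping %d locus/loci with zero pooled coverage in a group",
                    sum(!ok)))
  }
  loci <- mat$loci[ok, , drop = FALSE]
  m_case <- m_case[ok]; u_case <- u_case[ok]
  m_ctrl <- m_ctrl[ok]; u_ctrl <- u_ctrl[ok]
  s_case <- m_case / (m_case + u_case)
  s_ctrl <- m_ctrl / (m_ctrl + u_ctrl)
  if (method == "fisher_pooled") {
    p <- fisher_pooled_p(m_case, u_case, m_ctrl, u_ctrl)
  } else {
    grp <- factor(mat$samples$group[match(c(case_ids, ctrl_ids),
                                          mat$samples$sample_id)],
                  levels = c("control", "case"))
    cols <- c(case_ids, ctrl_ids)
    p <- vapply(seq_len(nrow(loci)), function(i) {
      ri <- which(ok)[i]
      y <- cbind(mat$meth[ri, cols], mat$unmeth[ri, cols])
      fit1 <- stats::glm(y ~ grp, family = stats::binomial())
      fit0 <- stats::glm(y ~ 1, family = stats::binomial())
      stats::anova(fit0, fit1, test = "LRT")$`Pr(>Chi)`[2]
    }, numeric(1))
    p[is.na(p)] <- 1
  }
  out <- data.frame(loci,
                    m_case = s_case, m_ctrl = s_ctrl,
                    diff = (s_case - s_ctrl) * 100,
                    p = p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Test for differential methylation at one stage
#'
#' Compares case against control samples of a stage. With the default
#' `fisher_pooled` method, methylated/unmethylated counts are summed
#' within each group and a two-sided exact test is applied to the pooled
#' 2x2 table; the methylation difference is always the pooled case score
#' minus the pooled control score, in percentage points. The `logistic`
#' method fits a per-locus binomial regression across replicates
#' (likelihood-ratio p).
#'
#' @param mat A filtered `meth_matrix`.
#' @param stage Stage label present in the sample sheet.
#' @param method `"fisher_pooled"` (default) or `"logistic"`.
#' @return Data frame with `chrom`, `pos`, `strand`, `m_case`, `m_ctrl`,
#'   `diff` (percentage points), `p`; attribute `stage` records the
#'   contrast.
#' @export
test_dmc <- function(mat, stage, method = c("fisher_pooled", "logistic")) {
  stopifnot(inherits(mat, "meth_matrix"))
  ss <- mat$samples
  case_ids <- ss$sample_id[ss$stage == stage & ss$group == "case"]
  ctrl_ids <- ss$sample_id[ss$stage == stage & ss$group == "control"]
  if (!length(case_ids) || !length(ctrl_ids)) {
    .stopf("stage '%s' needs >= 1 case and >= 1 control sample", stage)
  }
  out <- contrast_loci(mat, case_ids, ctrl_ids, method)
  attr(out, "stage") <- stage
  attr(out, "method") <- match.arg(method)
  out
}

#' Benjamini-Hochberg q-values
#'
#' @param p Numeric vector of p-values in \[0, 1\] (no NA).
#' @return q-values (BH step-up adjusted p-values).
#' @export
adjust_q <- function(p) {
  if (any(is.na(p))) .stopf("NA/NaN p-values cannot be adjusted")
  if (any(p < 0 | p > 1)) .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify loci as hyper-/hypomethylated DMCs
#'
#' A locus is a hypermethylated DMC iff `diff >= diff_threshold` and
#' `q < q_threshold`; hypomethylated iff `diff <= -diff_threshold` and
#' `q < q_threshold`; otherwise `ns`. Equality at the magnitude threshold
#' counts as significant.
#'
#' @param records Data frame from [test_dmc()] with `q` already attached
#'   (see [adjust_q()]).
#' @param diff_threshold Minimum absolute difference in percentage points
#'   (default 10).
#' @param q_threshold q-value cutoff (default 0.01).
#' @return The records with a `status` column (`hyper`/`hypo`/`ns`).
#' @export
classify_dmcs <- function(records, diff_threshold = 10, q_threshold = 0.01) {
  if (is.null(records$q)) .stopf("records need a q column; run adjust_q() first")
  status <- rep("ns", nrow(records))
  sig <- records$q < q_threshold
  status[sig & records$diff >= diff_threshold] <- "hyper"
  status[sig & records$diff <= -diff_threshold] <- "hypo"
  records$status <- status
  attr(records, "diff_threshold") <- diff_threshold
  attr(records, "q_threshold") <- q_threshold
  records
}

#' Call DMCs for one stage (test + adjust + classify)
#'
#' @inheritParams test_dmc
#' @inheritParams classify_dmcs
#' @return Classified DMC records (see [classify_dmcs()]).
#' @export
call_dmcs <- function(mat, stage, method = c("fisher_pooled", "logistic"),
                      diff_threshold = 10, q_threshold = 0.01) {
  rec <- test_dmc(mat, stage, method)
  rec$q <- adjust_q(rec$p)
  rec <- classify_dmcs(rec, diff_threshold, q_threshold)
  attr(rec, "stage") <- stage
  rec
}

#' Summarise per-stage DMC counts and hypermethylation fractions
#'
#' Works on a plain counts table (columns `stage`, `n_hypo`, `n_hyper`),
#' e.g. a published summary table, adding `n_total` and
#' `hyper_pct = n_hyper / n_total * 100`.
#'
#' @param counts Data frame with `stage`, `n_hypo`, `n_hyper`.
#' @return The table with `n_total` and `hyper_pct` columns.
#' @export
summarize_stage_counts <- function(counts) {
  stopifnot(all(c("stage", "n_hypo", "n_hyper") %in% names(counts)))
  counts$n_total <- counts$n_hypo + counts$n_hyper
  counts$hyper_pct <- 100 * counts$n_hyper / counts$n_total
  counts
}

#' Cross-stage DMC dynamics
#'
#' Per-stage counts (hyper, hypo, total, hyper percentage) plus pairwise
#' and all-stage intersections of DMC locus sets (exact
#' (chrom, pos, strand) identity). When an annotation is supplied, the
#' same intersections are computed for the sets of genes with promoter
#' DMCs.
#'
#' @param stage_records Named list of classified DMC records, one per
#'   stage, in stage order.
#' @param annotation Optional `annotation_set` (see
#'   [build_annotation()]) for promoter-gene intersections.
#' @return A list with `counts` (data frame), `locus_sets`,
#'   `pairwise_intersections` (matrix), `all_stage_intersection`, and,
#'   with annotation, `gene_sets` plus gene intersection entries.
#' @export
stage_dynamics <- function(stage_records, annotation = NULL) {
  if (length(stage_records) < 2) .stopf("stage_dynamics needs >= 2 stages")
  stages <- names(stage_records)
  counts <- data.frame(
    stage = stages,
    n_hypo = vapply(stage_records, function(r) sum(r$status == "hypo"), numeric(1)),
    n_hyper = vapply(stage_records, function(r) sum(r$status == "hyper"), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  counts <- summarize_stage_counts(counts)
  locus_sets <- lapply(stage_records, function(r) {
    dmc <- r[r$status != "ns", ]
    locus_key(dmc$chrom, dmc$pos, dmc$strand)
  })
  k <- length(stages)
  inter <- matrix(NA_real_, k, k, dimnames = list(stages, stages))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    inter[i, j] <- length(intersect(locus_sets[[i]], locus_sets[[j]]))
  }
  out <- list(counts = counts, locus_sets = locus_sets,
              pairwise_intersections = inter,
              all_stage_intersection = Reduce(intersect, locus_sets))
  if (!is.null(annotation)) {
    gene_sets <- lapply(stage_records, function(r) {
      dmc <- r[r$status != "ns", ]
      ann <- map_loci(dmc, annotation)
      unique(unlist(strsplit(ann$promoter_genes[ann$promoter], ",")))
    })
    ginter <- matrix(NA_real_, k, k, dimnames = list(stages, stages))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      ginter[i, j] <- length(intersect(gene_sets[[i]], gene_sets[[j]]))
    }
    out$gene_sets <- gene_sets
    out$gene_pairwise_intersections <- ginter
    out$gene_all_stage_intersection <- Reduce(intersect, gene_sets)
  }
  out
}

#' Premalignant-to-malignant pooled transition contrast
#'
#' Pools case samples of the early stages against case samples of the late
#' stages, calls DMCs, and maps them to promoter genes; the same contrast
#' on control samples defines a developmental background, and genes found
#' in the control contrast are subtracted from the case gene lists.
#'
#' @param mat A filtered `meth_matrix`.
#' @param early_stages,late_stages Disjoint stage label sets.
#' @param annotation An `annotation_set` for promoter mapping.
#' @param diff_threshold,q_threshold DMC thresholds (defaults 10 and
#'   0.01).
#' @param control_subtraction Subtract control-contrast genes (default
#'   TRUE).
#' @return List with `hyper_genes`, `hypo_genes` (after subtraction),
#'   `control_hyper_genes`, `control_hypo_genes`, and the underlying
#'   classified records (`case_records`, `control_records`).
#' @export
pooled_transition_contrast <- function(mat, early_stages, late_stages, annotation,
                                       diff_threshold = 10, q_threshold = 0.01,
                                       control_subtraction = TRUE) {
  if (length(intersect(early_stages, late_stages))) {
    .stopf("early and late stage sets must not overlap")
  }
  ss <- mat$samples
  promoter_genes <- function(records) {
    dmc <- records[records$status != "ns", ]
    if (!nrow(dmc)) return(list(hyper = character(), hypo = character()))
    ann <- map_loci(dmc, annotation)
    genes_of <- function(st) {
      sel <- ann$promoter & dmc$status == st
      unique(unlist(strsplit(ann$promoter_genes[sel], ",")))
    }
    list(hyper = genes_of("hyper"), hypo = genes_of("hypo"))
  }
  run_group <- function(group) {
    early <- ss$sample_id[ss$group == group & ss$stage %in% early_stages]
    late <- ss$sample_id[ss$group == group & ss$stage %in% late_stages]
    if (!length(early) || !length(late)) .stopf("empty %s stage pool", group)
    # late pool plays the 'case' role so positive diff = gain at malignancy
    rec <- contrast_loci(mat, late, early)
    rec$q <- adjust_q(rec$p)
    classify_dmcs(rec, diff_threshold, q_threshold)
  }
  case_rec <- run_group("case")
  ctrl_rec <- run_group("control")
  cg <- promoter_genes(case_rec)
  kg <- promoter_genes(ctrl_rec)
  hyper <- cg$hyper; hypo <- cg$hypo
  if (control_subtraction) {
    hyper <- setdiff(hyper, c(kg$hyper, kg$hypo))
    hypo <- setdiff(hypo, c(kg$hyper, kg$hypo))
  }
  list(hyper_genes = sort(hyper), hypo_genes = sort(hypo),
       control_hyper_genes = sort(kg$hyper), control_hypo_genes = sort(kg$hypo),
       case_records = case_rec, control_records = ctrl_rec)
}
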
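#' Estimate the DMC merge distance from inter-CpG spacing
#'
#' Fits a two-component Gaussian mixture to log10 nearest-neighbour
#' distances by EM (deterministic quantile-based initialisation, tolerance
#' 1e-8, at most 500 iterations). The merge distance `d*` is where the two
#' component posteriors cross between the component means. Falls back to a
#' fixed default when the input is too small or the mixture degenerates
#' (a component weight < 0.05 or means closer than 0.1 log10).
#'
#' @param positions Data frame with `chrom` and `pos` (or a numeric vector
#'   of positions on one chromosome).
#' @param fallback Fallback distance in bp (default 100).
#' @return Distance `d*` in bp; attributes `method` ("mixture" or
#'   "fallback") and `fit` (the EM parameters).
#' @export
estimate_gap_threshold <- function(positions, fallback = 100) {
  if (is.data.frame(positions)) {
    gaps <- unlist(lapply(split(positions$pos, positions$chrom), function(p) {
      p <- sort(unique(p)); if (length(p) > 1) diff(p) else numeric(0)
    }), use.names = FALSE)
  } else {
    p <- sort(unique(positions)); gaps <- diff(p)
  }
  gaps <- gaps[gaps > 0]
  if (length(gaps) < 100) {
    .warnf("only %d gap observations (< 100): using fallback d* = %g bp",
           length(gaps), fallback)
    return(structure(fallback, method = "fallback"))
  }
  x <- log10(gaps)
  fit <- em_normal_mixture_2(x)
  degenerate <- min(fit$weight) < 0.05 || abs(diff(fit$mean)) < 0.1
  if (degenerate) {
    return(structure(fallback, method = "fallback", fit = fit))
  }
  d_star <- 10^mixture_crossing(fit)
  structure(d_star, method = "mixture", fit = fit)
}

# Deterministic 2-component 1-D Gaussian EM: components initialised at the
# 25% / 75% quantiles, common initial sd, equal weights.
em_normal_mixture_2 <- function(x, tol = 1e-8, max_iter = 500) {
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  sd_ <- rep(max(stats::sd(x) / 2, 1e-3), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd_[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd_[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g <- d1 / tot
    w <- c(mean(g), 1 - mean(g))
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    sd_ <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                  sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    sd_ <- pmax(sd_, 1e-4)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  o <- order(mu)
  list(mean = mu[o], sd = sd_[o], weight = w[o], loglik = ll, iterations = it)
}

# Posterior crossing point between the two component means.
mixture_crossing <- function(fit) {
  f <- function(x) {
    log(fit$weight[1]) + stats::dnorm(x, fit$mean[1], fit$sd[1], log = TRUE) -
      log(fit$weight[2]) - stats::dnorm(x, fit$mean[2], fit$sd[2], log = TRUE)
  }
  lo <- fit$mean[1]; hi <- fit$mean[2]
  if (f(lo) * f(hi) > 0) return(mean(c(lo, hi)))
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Merge dense runs of DMCs into differentially methylated regions
#'
#' Seed-and-extend merge: consecutive same-direction DMCs on a chromosome
#' with inter-DMC gap at most `gap` form a candidate region; the candidate
#' spans from its first to its last DMC and includes every covered CpG in
#' that span. Candidates must contain at least `min_cpgs` covered CpGs and
#' `min_dmcs` DMCs and have an absolute mean methylation difference (over
#' all covered CpGs in the span) of at least `mean_diff_threshold`
#' percentage points. The region p-value combines per-CpG evidence by
#' Stouffer's method oriented by the region direction; q-values are BH
#' over the filtered candidates and regions with `q_region < q_threshold`
#' are reported.
#'
#' @param records Classified DMC records for one stage (all covered loci,
#'   including non-significant ones; see [call_dmcs()]).
#' @param gap Maximum inter-DMC distance in bp (see
#'   [estimate_gap_threshold()]).
#' @param min_cpgs Minimum covered CpGs per region (default 3).
#' @param min_dmcs Minimum DMCs per region (default 1).
#' @param mean_diff_threshold Minimum |mean difference| in percentage
#'   points (default 20).
#' @param q_threshold Region q-value cutoff (default 0.05; `NULL`
#'   disables).
#' @return A `dmr_set` data frame: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_cpgs`, `n_dmcs`, `mean_diff`, `p_region`, `q_region`,
#'   `status`, sorted by (chrom, start).
#' @export
call_dmrs <- function(records, gap, min_cpgs = 3, min_dmcs = 1,
                      mean_diff_threshold = 20, q_threshold = 0.05) {
  stopifnot(!is.null(records$status))
  dmc <- records[records$status != "ns", , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), n_dmcs = integer(),
                      mean_diff = numeric(), p_region = numeric(),
                      q_region = numeric(), status = character())
  if (!nrow(dmc)) return(structure(empty, class = c("dmr_set", "data.frame")))
  dmc <- dmc[order(dmc$chrom, dmc$pos), ]
  # candidate id: break at chromosome change, direction change, or gap > d*
  new_run <- c(TRUE, dmc$chrom[-1] != dmc$chrom[-nrow(dmc)] |
                 dmc$status[-1] != dmc$status[-nrow(dmc)] |
                 (dmc$pos[-1] - dmc$pos[-nrow(dmc)]) > gap)
  run_id <- cumsum(new_run)
  cand <- lapply(split(seq_len(nrow(dmc)), run_id), function(idx) {
    sub <- dmc[idx, ]
    span <- records$chrom == sub$chrom[1] &
      records$pos >= min(sub$pos) & records$pos <= max(sub$pos)
    covered <- records[span, ]
    direction <- if (sub$status[1] == "hyper") 1 else -1
    data.frame(chrom = sub$chrom[1],
               start = min(sub$pos), end = max(sub$pos),
               n_cpgs = nrow(covered), n_dmcs = nrow(sub),
               mean_diff = mean(covered$diff),
               p_region = stouffer_region_p(covered$p, covered$diff, direction),
               status = sub$status[1], stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  keep <- cand$n_cpgs >= min_cpgs & cand$n_dmcs >= min_dmcs &
    abs(cand$mean_diff) >= mean_diff_threshold
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(structure(empty, class = c("dmr_set", "data.frame")))
  cand$q_region <- adjust_q(cand$p_region)
  if (!is.null(q_threshold)) {
    cand <- cand[cand$q_region < q_threshold, , drop = FALSE]
  }
  cand <- cand[order(cand$chrom, cand$start),
               c("chrom", "start", "end", "n_cpgs", "n_dmcs", "mean_diff",
                 "p_region", "q_region", "status")]
  rownames(cand) <- NULL
  structure(cand, class = c("dmr_set", "data.frame"))
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("dmr_set: %d regions (%d hyper, %d hypo)",
              nrow(x), sum(x$status == "hyper"), sum(x$status == "hypo")))
  if (nrow(x)) {
    cat(sprintf("; median width %d bp", as.integer(stats::median(x$end - x$start + 1))))
  }
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Union of per-stage DMR lists with stage provenance
#'
#' Overlapping regions from different stages are merged into their union
#' span; each merged interval records which stages contributed.
#'
#' @param stage_dmrs Named list of `dmr_set` data frames, one per stage.
#' @return Data frame `chrom`, `start`, `end`, `stages` (comma-separated).
#' @export
union_dmrs <- function(stage_dmrs) {
  nonempty <- Filter(nrow, stage_dmrs)
  if (!length(nonempty)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stages = character()))
  }
  all_df <- do.call(rbind, Map(function(d, st) {
    data.frame(chrom = d$chrom, start = d$start, end = d$end, stage = st,
               stringsAsFactors = FALSE)
  }, nonempty, names(nonempty)))
  gr <- interval_granges(all_df)
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  stages_per <- split(all_df$stage[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits))
  stage_order <- names(stage_dmrs)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    stringsAsFactors = FALSE)
  out$stages <- vapply(seq_along(merged), function(i) {
    st <- unique(stages_per[[as.character(i)]])
    paste(stage_order[sort(match(st, stage_order))], collapse = ",")
  }, character(1))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Stage-trajectory matrix over the DMR union
#'
#' For each union interval and stage, the mean case-minus-control
#' methylation difference (percentage points) over all covered CpGs in the
#' interval. Intervals lacking coverage at a stage are imputed with that
#' stage's column mean (reported via message).
#'
#' @param union_df Output of [union_dmrs()].
#' @param stage_records Named list of per-stage DMC records (all covered
#'   loci), in stage order.
#' @return Numeric matrix, intervals x stages; row names are
#'   `chrom:start-end`.
#' @export
dmr_trajectory_matrix <- function(union_df, stage_records) {
  stages <- names(stage_records)
  mat <- matrix(NA_real_, nrow(union_df), length(stages),
                dimnames = list(sprintf("%s:%d-%d", union_df$chrom,
                                        union_df$start, union_df$end),
                                stages))
  iv <- interval_granges(union_df)
  for (s in seq_along(stages)) {
    rec <- stage_records[[s]]
    gr <- loci_granges(rec)
    hits <- GenomicRanges::findOverlaps(iv, gr)
    means <- tapply(rec$diff[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), mean)
    mat[as.integer(names(means)), s] <- means
  }
  n_miss <- sum(is.na(mat))
  if (n_miss) {
    message(sprintf("imputing %d missing trajectory cell(s) with stage means", n_miss))
    for (s in seq_len(ncol(mat))) {
      mat[is.na(mat[, s]), s] <- mean(mat[, s], na.rm = TRUE)
    }
  }
  mat
}

#' Cluster DMR trajectories into progression groups
#'
#' Agglomerative clustering (Ward linkage, Euclidean metric by default) of
#' the interval-by-stage difference matrix, cut into `k` groups. Groups
#' are relabelled 1..k by decreasing mean trajectory value so that a
#' hypermethylated group sorts first.
#'
#' @param traj Matrix from [dmr_trajectory_matrix()].
#' @param k Number of groups (default 3).
#' @param linkage `hclust` method (default `"ward.D2"`).
#' @param metric `dist` method (default `"euclidean"`).
#' @return List with `labels` (integer per row), `centers` (k x stages
#'   mean trajectories), `sizes`, and the `hclust` object.
#' @export
trajectory_cluster <- function(traj, k = 3, linkage = "ward.D2",
                               metric = "euclidean") {
  if (k > nrow(traj)) .stopf("k = %d exceeds number of rows (%d)", k, nrow(traj))
  hc <- stats::hclust(stats::dist(traj, method = metric), method = linkage)
  raw <- stats::cutree(hc, k = k)
  level_means <- tapply(rowMeans(traj), raw, mean)
  relabel <- match(names(sort(level_means, decreasing = TRUE)), names(level_means))
  labels <- match(raw, as.integer(names(level_means))[relabel])
  centers <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(traj[labels == g, , drop = FALSE])
  }))
  rownames(centers) <- paste0("group", seq_len(k))
  list(labels = labels, centers = centers,
       sizes = as.integer(table(factor(labels, levels = seq_len(k)))),
       hclust = hc)
}
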
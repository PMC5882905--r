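#' Hypergeometric gene-set overlap enrichment
#'
#' Tests a query gene list against a collection of gene sets restricted to
#' a universe: for each set, the upper-tail hypergeometric probability of
#' drawing at least the observed overlap in `|query|` draws without
#' replacement, with BH FDR across all tested sets.
#'
#' @param query Character vector of gene ids (must lie in `universe`).
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param universe Character vector of all eligible gene ids.
#' @return Data frame `set_name`, `n_universe`, `n_set`, `n_query`,
#'   `n_overlap`, `p`, `fdr`, `overlap_genes`, sorted by (fdr, p).
#' @export
overlap_enrichment <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) .stopf("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) {
    .stopf("%d query gene(s) outside the universe", sum(!query %in% universe))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- intersect(query, s)
    k <- length(ov)
    p <- stats::phyper(k - 1, length(s), length(universe) - length(s),
                       length(query), lower.tail = FALSE)
    data.frame(set_name = nm, n_universe = length(universe),
               n_set = length(s), n_query = length(query), n_overlap = k,
               p = p, overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- adjust_q(out$p)
  out <- out[order(out$fdr, out$p, out$set_name),
             c("set_name", "n_universe", "n_set", "n_query", "n_overlap",
               "p", "fdr", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Intersect promoter DMC gene lists with differential expression
#'
#' Splits differentially expressed genes (FDR below `de_fdr`) by direction
#' and intersects them with the promoter hyper-/hypomethylated gene lists,
#' yielding the four concordance classes. Genes carrying both hyper and
#' hypo promoter DMCs contribute to both branches (reported via message).
#'
#' @param hyper_genes,hypo_genes Character vectors of genes with promoter
#'   hyper-/hypomethylated DMCs.
#' @param expression Expression table (`gene_id`, `logFC`, `fdr`).
#' @param de_fdr Differential-expression FDR cutoff (default 0.05).
#' @return List with the four gene vectors `hypo_up`, `hypo_down`,
#'   `hyper_up`, `hyper_down` and a `counts` data frame.
#' @export
integrate_expression <- function(hyper_genes, hypo_genes, expression,
                                 de_fdr = 0.05) {
  both <- intersect(hyper_genes, hypo_genes)
  if (length(both)) {
    message(sprintf("%d gene(s) carry both hyper and hypo promoter DMCs", length(both)))
  }
  de <- expression[expression$fdr < de_fdr, ]
  up <- de$gene_id[de$logFC > 0]
  down <- de$gene_id[de$logFC < 0]
  out <- list(hypo_up = sort(intersect(hypo_genes, up)),
              hypo_down = sort(intersect(hypo_genes, down)),
              hyper_up = sort(intersect(hyper_genes, up)),
              hyper_down = sort(intersect(hyper_genes, down)))
  out$counts <- data.frame(class = names(out)[1:4],
                           n = vapply(out[1:4], length, integer(1)),
                           row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Compare expression between a target and a reference gene group
#'
#' Two-sided Wilcoxon rank-sum test of an expression value between a
#' target gene group and a reference group. Target genes are removed from
#' the reference so the groups are disjoint (noted in the output). The
#' exact null distribution is used when both groups have at most 10
#' members and the values are tie-free; otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param target_genes,reference_genes Character vectors of gene ids.
#' @param expression Expression table with `gene_id` and the value column.
#' @param value Column to compare (default `"logFC"`).
#' @return List with `p`, `median_target`, `median_reference`,
#'   `direction`, `n_target`, `n_reference`, `removed_from_reference`.
#' @export
compare_expression_distributions <- function(target_genes, reference_genes,
                                             expression, value = "logFC") {
  reference <- setdiff(reference_genes, target_genes)
  removed <- length(reference_genes) - length(reference)
  x <- expression[[value]][match(intersect(target_genes, expression$gene_id),
                                 expression$gene_id)]
  y <- expression[[value]][match(intersect(reference, expression$gene_id),
                                 expression$gene_id)]
  if (!length(x) || !length(y)) .stopf("empty gene group after matching to expression")
  use_exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
  list(p = wt$p.value,
       median_target = stats::median(x),
       median_reference = stats::median(y),
       direction = if (stats::median(x) < stats::median(y)) "lower" else "higher",
       n_target = length(x), n_reference = length(y),
       removed_from_reference = removed)
}
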
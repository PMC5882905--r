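#' Build a promoter/gene-body/enhancer annotation set
#'
#' Promoters are TSS +/- `promoter_window` (1-based inclusive, width
#' `2 * promoter_window + 1`); gene bodies span TSS..TES when a `tes`
#' column is present; enhancers are taken as given. A locus may belong to
#' several compartments at once; no precedence collapse is applied.
#'
#' @param genes Gene model data frame (`gene_id`, `chrom`, `strand`,
#'   `tss`, optional `tes`).
#' @param enhancers Data frame of 1-based inclusive enhancer intervals
#'   (`chrom`, `start`, `end`, optional `name`), or NULL.
#' @param promoter_window Half-width of the promoter window in bp
#'   (default 2000).
#' @param enhancer_target_window Maximum TSS-to-enhancer-edge distance for
#'   enhancer target assignment (default 10000).
#' @return An `annotation_set` object.
#' @export
build_annotation <- function(genes, enhancers = NULL, promoter_window = 2000,
                             enhancer_target_window = 10000) {
  promoters <- data.frame(
    chrom = genes$chrom,
    start = pmax(1L, genes$tss - as.integer(promoter_window)),
    end = genes$tss + as.integer(promoter_window),
    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  bodies <- NULL
  if (!is.null(genes$tes)) {
    bodies <- data.frame(
      chrom = genes$chrom,
      start = pmin(genes$tss, genes$tes),
      end = pmax(genes$tss, genes$tes),
      gene_id = genes$gene_id, stringsAsFactors = FALSE)
  }
  if (!is.null(enhancers) && nrow(enhancers)) {
    enhancers$name <- enhancers$name %||% sprintf("ENH%03d", seq_len(nrow(enhancers)))
  }
  structure(list(genes = genes, promoters = promoters, bodies = bodies,
                 enhancers = enhancers,
                 promoter_window = promoter_window,
                 enhancer_target_window = enhancer_target_window),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d promoters (TSS +/- %d bp), %d enhancer(s)%s\n",
              nrow(x$promoters), x$promoter_window,
              if (is.null(x$enhancers)) 0 else nrow(x$enhancers),
              if (is.null(x$bodies)) "" else sprintf(", %d gene bodies", nrow(x$bodies))))
  invisible(x)
}

#' Map loci to genomic compartments
#'
#' Each locus is tested for membership in promoters, gene bodies and
#' enhancers independently (memberships may overlap). Promoter gene
#' assignment lists every gene whose window contains the locus. Loci on
#' chromosomes absent from the annotation are labelled unannotated.
#'
#' @param loci Data frame with `chrom`, `pos`, `strand`.
#' @param annotation An `annotation_set`.
#' @return Data frame aligned with `loci`: logical `promoter`,
#'   `gene_body`, `enhancer`, `unannotated`, plus `promoter_genes`
#'   (comma-separated) and `compartment` (comma-separated labels, "other"
#'   when none).
#' @export
map_loci <- function(loci, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  n <- nrow(loci)
  gr <- loci_granges(loci)
  member <- function(iv_df) {
    out <- logical(n)
    if (is.null(iv_df) || !nrow(iv_df)) return(out)
    hits <- GenomicRanges::findOverlaps(gr, interval_granges(iv_df))
    out[unique(S4Vectors::queryHits(hits))] <- TRUE
    out
  }
  promoter <- logical(n); promoter_genes <- rep("", n)
  if (nrow(annotation$promoters)) {
    hits <- GenomicRanges::findOverlaps(gr, interval_granges(annotation$promoters))
    if (length(hits)) {
      gl <- split(annotation$promoters$gene_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
      idx <- as.integer(names(gl))
      promoter[idx] <- TRUE
      promoter_genes[idx] <- vapply(gl, function(g) paste(sort(unique(g)), collapse = ","),
                                    character(1))
    }
  }
  gene_body <- member(annotation$bodies)
  enhancer <- member(annotation$enhancers)
  ann_chroms <- unique(c(annotation$promoters$chrom,
                         annotation$bodies$chrom,
                         annotation$enhancers$chrom))
  unannotated <- !(loci$chrom %in% ann_chroms)
  compartment <- vapply(seq_len(n), function(i) {
    if (unannotated[i]) return("unannotated")
    lab <- c("promoter", "gene_body", "enhancer")[c(promoter[i], gene_body[i], enhancer[i])]
    if (!length(lab)) "other" else paste(lab, collapse = ",")
  }, character(1))
  data.frame(promoter = promoter, gene_body = gene_body, enhancer = enhancer,
             unannotated = unannotated, promoter_genes = promoter_genes,
             compartment = compartment, stringsAsFactors = FALSE)
}

#' Assign target genes to enhancers by nearest TSS within a window
#'
#' For each enhancer, the distance from every TSS to the nearest enhancer
#' edge (zero when the TSS falls inside the enhancer) is computed; the
#' nearest gene(s) are its targets iff that distance is at most `window`.
#' Exact ties are all included.
#'
#' @param annotation An `annotation_set` (or NULL to pass `enhancers` and
#'   `genes` directly).
#' @param enhancers,genes Optional explicit inputs overriding the
#'   annotation slots.
#' @param window Maximum distance in bp (default the annotation's
#'   `enhancer_target_window`).
#' @return Data frame `enhancer`, `gene_id`, `distance` (one row per
#'   assignment).
#' @export
enhancer_targets <- function(annotation = NULL, enhancers = NULL, genes = NULL,
                             window = NULL) {
  if (!is.null(annotation)) {
    enhancers <- enhancers %||% annotation$enhancers
    genes <- genes %||% annotation$genes
    window <- window %||% annotation$enhancer_target_window
  }
  window <- window %||% 10000
  out <- list()
  for (i in seq_len(NROW(enhancers))) {
    g <- genes[genes$chrom == enhancers$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- pmax(0, pmax(enhancers$start[i] - g$tss, g$tss - enhancers$end[i]))
    dmin <- min(d)
    if (dmin > window) next
    sel <- which(d == dmin)
    out[[length(out) + 1]] <- data.frame(
      enhancer = enhancers$name[i] %||% as.character(i),
      gene_id = g$gene_id[sel], distance = d[sel], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(enhancer = character(), gene_id = character(),
                      distance = numeric()))
  }
  do.call(rbind, out)
}

#' Permutation enrichment of a locus set in a compartment
#'
#' Draws `B` random locus sets of the same size, uniformly without
#' replacement from the captured-CpG universe, counts compartment
#' overlaps, and reports the one-sided (enrichment) empirical p-value with
#' add-one correction: `p = (1 + #replicates >= observed) / (B + 1)`.
#'
#' @param locus_set Character vector of locus keys (subset of universe).
#' @param compartment_loci Character vector of universe locus keys lying
#'   in the compartment.
#' @param universe Character vector of all captured locus keys.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed (recorded on the result).
#' @return List with `observed`, `p`, `B`, `seed`, `null_mean`.
#' @export
permutation_enrichment <- function(locus_set, compartment_loci, universe,
                                   B = 1000, seed = 1L) {
  n <- length(locus_set); N <- length(universe)
  if (n > N) .stopf("locus set (%d) larger than universe (%d)", n, N)
  if (!all(locus_set %in% universe)) .stopf("locus set must be a subset of the universe")
  in_comp <- universe %in% compartment_loci
  observed <- sum(locus_set %in% compartment_loci)
  local_seed(seed)
  null_counts <- vapply(seq_len(B), function(b) {
    sum(in_comp[sample.int(N, n)])
  }, numeric(1))
  list(observed = observed,
       p = (1 + sum(null_counts >= observed)) / (B + 1),
       B = B, seed = seed, null_mean = mean(null_counts))
}

#' Compartment composition of captured CpGs and DMCs
#'
#' Fractions of all captured CpGs, of DMCs, and of hyper-/hypomethylated
#' DMCs falling in each compartment (promoter, enhancer, gene body,
#' other; memberships may overlap, so fractions need not sum to 1), plus
#' permutation enrichment p-values for DMCs in enhancers and hyper-DMCs in
#' promoters against the captured-CpG universe.
#'
#' @param records Classified DMC records (all covered loci, with
#'   `status`).
#' @param annotation An `annotation_set`.
#' @param B Permutations (default 1000).
#' @param seed Integer seed.
#' @return A list with `fractions` (data frame), `p_dmc_enhancer`,
#'   `p_hyper_promoter` (NA when there are no qualifying loci), `B`,
#'   `seed`.
#' @export
compartment_summary <- function(records, annotation, B = 1000, seed = 1L) {
  ann <- map_loci(records, annotation)
  keys <- locus_key(records$chrom, records$pos, records$strand)
  sets <- list(all = rep(TRUE, nrow(records)),
               dmc = records$status != "ns",
               hyper = records$status == "hyper",
               hypo = records$status == "hypo")
  comps <- list(promoter = ann$promoter, enhancer = ann$enhancer,
                gene_body = ann$gene_body,
                other = !(ann$promoter | ann$enhancer | ann$gene_body))
  fractions <- do.call(rbind, lapply(names(sets), function(s) {
    sel <- sets[[s]]
    data.frame(set = s, n = sum(sel),
               t(vapply(comps, function(cmp) {
                 if (!sum(sel)) NA_real_ else mean(cmp[sel])
               }, numeric(1))),
               stringsAsFactors = FALSE)
  }))
  p_enh <- NA_real_; p_prom <- NA_real_
  if (sum(sets$dmc)) {
    p_enh <- permutation_enrichment(keys[sets$dmc], keys[comps$enhancer], keys,
                                    B = B, seed = derive_seed(seed, "enh"))$p
  }
  if (sum(sets$hyper)) {
    p_prom <- permutation_enrichment(keys[sets$hyper], keys[comps$promoter], keys,
                                     B = B, seed = derive_seed(seed, "prom"))$p
  }
  list(fractions = fractions, p_dmc_enhancer = p_enh,
       p_hyper_promoter = p_prom, B = B, seed = seed)
}
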
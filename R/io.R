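#' Read per-CpG methylation call tables
#'
#' Parses per-sample CpG methylation calls in either the methylKit text
#' dialect (`chrBase chr base strand coverage freqC freqT`, header line
#' present) or the Bismark coverage dialect
#' (`chrom start end meth_percent count_methylated count_unmethylated`,
#' no header, 1-based start == end). Internally all positions are 1-based
#' cytosine positions.
#'
#' @param path Path to the call table.
#' @param dialect `"methylkit"` or `"bismark_cov"`.
#' @return A data frame with columns `chrom`, `pos` (1-based), `strand`,
#'   `count_meth`, `count_unmeth`, sorted by (chrom, pos, strand).
#' @examples
#' f <- tempfile()
#' writeLines(c("chrBase\tchr\tbase\tstrand\tcoverage\tfreqC\tfreqT",
#'              "chr1.100\tchr1\t100\t+\t20\t75.0\t25.0"), f)
#' read_methylation_calls(f, "methylkit")
#' @export
read_methylation_calls <- function(path, dialect = c("methylkit", "bismark_cov")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (dialect == "methylkit") {
    if (length(lines) && grepl("^chrBase", lines[[1]])) lines <- lines[-1]
    offset <- 1L  # header line
  } else {
    offset <- 0L
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      count_meth = integer(), count_unmeth = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- if (dialect == "methylkit") 7L else 6L
  bad <- which(nf != want)
  if (length(bad)) {
    .stopf("malformed %s row at line %d of %s: expected %d fields, got %d",
           dialect, bad[[1]] + offset, path, want, nf[[bad[[1]]]])
  }
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  if (dialect == "methylkit") {
    coverage <- as.numeric(m[, 5])
    freqC <- as.numeric(m[, 6])
    freqT <- as.numeric(m[, 7])
    bad <- which(is.na(coverage) | is.na(freqC) | is.na(freqT))
    if (length(bad)) .stopf("malformed numeric field at line %d of %s",
                            bad[[1]] + offset, path)
    dev <- abs(freqC + freqT - 100)
    if (any(dev > 0.5)) {
      .stopf("freqC + freqT deviates from 100 by %.2f at line %d of %s",
             max(dev), which.max(dev) + offset, path)
    }
    if (any(coverage < 1)) {
      .stopf("coverage 0 at line %d of %s", which(coverage < 1)[[1]] + offset, path)
    }
    count_meth <- as.integer(round(coverage * freqC / 100))
    out <- data.frame(
      chrom = m[, 2], pos = as.integer(m[, 3]), strand = m[, 4],
      count_meth = count_meth,
      count_unmeth = as.integer(coverage) - count_meth,
      stringsAsFactors = FALSE
    )
  } else {
    cm <- as.numeric(m[, 5]); cu <- as.numeric(m[, 6])
    bad <- which(is.na(cm) | is.na(cu))
    if (length(bad)) .stopf("malformed numeric field at line %d of %s", bad[[1]], path)
    if (any(cm + cu < 1)) {
      .stopf("coverage 0 at line %d of %s", which(cm + cu < 1)[[1]], path)
    }
    out <- data.frame(
      # bismark coverage files carry 1-based start == end for CpGs; tolerate
      # the 0-based start variant by always taking the end column.
      chrom = m[, 1], pos = as.integer(m[, 3]), strand = "+",
      count_meth = as.integer(cm), count_unmeth = as.integer(cu),
      stringsAsFactors = FALSE
    )
  }
  if (!all(out$strand %in% c("+", "-"))) {
    .stopf("invalid strand in %s", path)
  }
  key <- locus_key(out$chrom, out$pos, out$strand)
  if (anyDuplicated(key)) .stopf("duplicated locus %s in %s", key[duplicated(key)][1], path)
  order_loci(out)
}

#' Write methylation calls in the methylKit text dialect
#'
#' @param calls Data frame as returned by [read_methylation_calls()].
#' @param path Output path.
#' @export
write_methylation_calls <- function(calls, path) {
  calls <- order_loci(calls)
  coverage <- calls$count_meth + calls$count_unmeth
  stopifnot(all(coverage >= 1))
  freqC <- round(100 * calls$count_meth / coverage, 2)
  df <- data.frame(
    chrBase = paste0(calls$chrom, ".", calls$pos),
    chr = calls$chrom, base = calls$pos, strand = calls$strand,
    coverage = coverage,
    freqC = sprintf("%.2f", freqC),
    freqT = sprintf("%.2f", 100 - freqC)
  )
  write_tsv(df, path)
}

#' Write genomic intervals as BED6
#'
#' Internal intervals are 1-based inclusive; on disk BED is 0-based
#' half-open. The conversion is done here (via the GRanges/rtracklayer
#' layer) and nowhere else.
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive), and optional `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (any(intervals$start > intervals$end)) .stopf("interval start > end")
  gr <- interval_granges(intervals, use_strand = TRUE)
  names(gr) <- intervals$name %||% paste0("iv", seq_len(nrow(intervals)))
  S4Vectors::mcols(gr)$score <- intervals$score %||% rep(0, nrow(intervals))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED file path.
#' @return Data frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character()))
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else paste0("iv", seq_along(gr)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member gene ids.
#' Duplicate members within a set are collapsed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; the `description` attribute of
#'   each element carries the set description.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) .stopf("GMT line %d has %d field(s); need >= 3", i, length(f))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) .stopf("GMT set '%s' (line %d) has no members", f[[1]], i)
    set <- members
    attr(set, "description") <- f[[2]]
    out[[f[[1]]]] <- set
  }
  out
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, attr(sets[[nm]], "description") %||% nm, sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `group` (case/control), `stage`,
#' `replicate`. Stage order is taken from the `stage_order` argument or,
#' by default, the order of first appearance.
#'
#' @param path TSV path.
#' @param stage_order Optional character vector giving the stage order.
#' @export
read_sample_sheet <- function(path, stage_order = NULL) {
  df <- read_tsv(path)
  validate_sample_sheet(df, stage_order)
}

#' Validate (and order) a sample sheet data frame
#' @param df Data frame with `sample_id`, `group`, `stage`, `replicate`.
#' @param stage_order Optional explicit stage order.
#' @export
validate_sample_sheet <- function(df, stage_order = NULL) {
  need <- c("sample_id", "group", "stage", "replicate")
  if (!all(need %in% names(df))) {
    .stopf("sample sheet needs columns: %s", paste(need, collapse = ", "))
  }
  if (!all(df$group %in% c("case", "control"))) {
    .stopf("sample sheet group must be 'case' or 'control'")
  }
  if (anyDuplicated(df$sample_id)) .stopf("duplicated sample_id in sample sheet")
  stages <- stage_order %||% unique(df$stage)
  df$stage <- factor(df$stage, levels = stages, ordered = TRUE)
  tab <- table(df$stage, factor(df$group, levels = c("case", "control")))
  if (any(tab == 0)) {
    .stopf("every stage needs >= 1 case and >= 1 control sample")
  }
  df
}

#' Read a gene model TSV
#'
#' Columns: `gene_id`, `chrom`, `strand`, `tss` (1-based) and optionally
#' `tes` (transcription end site) for gene bodies.
#' @param path TSV path.
#' @export
read_gene_model <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(df))) {
    .stopf("gene model needs columns: %s", paste(need, collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) .stopf("gene model strand must be + or -")
  if (anyDuplicated(df$gene_id)) .stopf("duplicated gene_id in gene model")
  df
}

#' Read a differential-expression table
#'
#' Columns: `gene_id`, `logFC`, `fdr` (one row per gene).
#' @param path TSV path.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "logFC", "fdr")
  if (!all(need %in% names(df))) {
    .stopf("expression table needs columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) .stopf("expression table: one row per gene required")
  df
}
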
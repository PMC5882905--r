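# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Canonical locus key: "chrom:pos:strand". Every cross-module identity
# comparison of CpG loci goes through this one function.
locus_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = ":")
}

# Deterministic locus ordering: chrom (lexical), then position, then strand.
order_loci <- function(df) {
  df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
}

# Loci (1-based single positions) as GRanges for overlap machinery.
loci_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$pos, width = 1L),
    strand = "*"
  )
}

# Internal intervals are 1-based inclusive [start, end].
interval_granges <- function(df, use_strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if (use_strand && !is.null(df$strand)) df$strand else "*"
  )
}

# Tab-separated writer with fixed conventions so that pipeline outputs are
# byte-identical across runs: no quoting, no row names, "NA" for missing.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# One-sided Stouffer combination of per-CpG evidence oriented by a region
# direction: z_i = Phi^{-1}(1 - p_i/2) * sign(diff_i) * dir. p-values are
# clipped away from 0 to keep qnorm finite.
stouffer_region_p <- function(p, diff, direction) {
  stopifnot(length(p) == length(diff), direction %in% c(1, -1))
  p <- pmax(p, 1e-300)
  z <- stats::qnorm(1 - p / 2) * sign(diff) * direction
  z[diff == 0] <- 0
  Z <- sum(z) / sqrt(length(z))
  stats::pnorm(Z, lower.tail = FALSE)
}

# Seed the RNG for the calling function only: the caller's random stream
# is restored when that function exits, so seeded library calls do not
# perturb surrounding user randomness.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  withr::defer({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(seed)
}

#' Derive a deterministic sub-seed from a global seed and a label
#'
#' Every randomised stage of the pipeline consumes its own seed derived
#' from the global seed and the stage name, so that one integer
#' reproduces a whole run. The result stays below 2^31.
#'
#' @param seed Global integer seed.
#' @param label Character label of the consuming stage.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1000003 + h * 97) %% 2147483000) + 1L
}
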
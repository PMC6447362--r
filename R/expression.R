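#' Read BED intervals as aligned reads
#'
#' Minimal BED3/BED6 reader for read alignments.  Blocks of a spliced
#' read may be given as several lines sharing one name (column 4); they
#' are grouped and counted once per read.  Lines without a name are
#' treated as independent single-block reads.
#'
#' @param path BED file path (`.gz` accepted).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (0-based half-open).
#' @export
read_bed_reads <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          fill = TRUE, showProgress = FALSE)
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), stringsAsFactors = FALSE))
  first <- as.character(dt[[1L]])
  dt <- dt[!grepl("^(track|browser|#)", first)]
  out <- data.frame(
    chrom = as.character(dt[[1L]]),
    start = as.integer(dt[[2L]]),
    end = as.integer(dt[[3L]]),
    name = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else
      paste0("read", seq_len(nrow(dt))),
    strand = if (ncol(dt) >= 6L) as.character(dt[[6L]]) else ".",
    stringsAsFactors = FALSE
  )
  if (!all(nzchar(out$name)))
    out$name[!nzchar(out$name)] <- paste0("read", which(!nzchar(out$name)))
  out
}

#' Union-exon read counting
#'
#' Assigns each read to a gene when any of its blocks overlaps that
#' gene's exonic union by at least one base.  Reads touching exons of
#' more than one gene are discarded as ambiguous; reads overlapping no
#' exon (including intron-only overlaps) are unassigned.  This mirrors
#' HTSeq-count's union mode at gene level.
#'
#' @param reads data.frame as from [read_bed_reads()]; multi-block reads
#'   share a `name`.
#' @param genes A `"gene_models"` data.frame (names must be unique; run
#'   [filter_genes()] first when in doubt).
#' @return Named integer vector of counts (one per gene, in input
#'   order), with attributes `ambiguous`, `unassigned` and `n_reads`.
#' @export
count_reads <- function(reads, genes) {
  counts <- stats::setNames(integer(nrow(genes)), genes$name)
  n_reads <- length(unique(reads$name))
  if (nrow(reads) == 0L || nrow(genes) == 0L) {
    attr(counts, "ambiguous") <- 0L
    attr(counts, "unassigned") <- n_reads
    attr(counts, "n_reads") <- n_reads
    return(counts)
  }
  exx <- exon_granges(genes)
  rgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$start + 1L, reads$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(rgr, exx, minoverlap = 1L, ignore.strand = TRUE))
  read_id <- match(reads$name, unique(reads$name))
  gene_of_hit <- S4Vectors::mcols(exx)$gene_idx[S4Vectors::subjectHits(hits)]
  read_of_hit <- read_id[S4Vectors::queryHits(hits)]
  if (length(read_of_hit)) {
    per_read <- split(gene_of_hit, read_of_hit)
    ngenes <- vapply(per_read, function(g) length(unique(g)), integer(1))
    uni <- vapply(per_read[ngenes == 1L], function(g) g[1L], integer(1))
    tab <- table(factor(uni, levels = seq_len(nrow(genes))))
    counts[] <- as.integer(tab)
    ambiguous <- sum(ngenes > 1L)
  } else {
    ambiguous <- 0L
  }
  attr(counts, "ambiguous") <- as.integer(ambiguous)
  attr(counts, "unassigned") <- as.integer(n_reads - sum(counts) - ambiguous)
  attr(counts, "n_reads") <- as.integer(n_reads)
  counts
}

exon_granges <- function(genes) {
  n_ex <- genes$n_exons
  gi <- rep.int(seq_len(nrow(genes)), n_ex)
  gr <- GenomicRanges::GRanges(
    genes$chrom[gi],
    IRanges::IRanges(unlist(genes$exon_starts, use.names = FALSE) + 1L,
                     unlist(genes$exon_ends, use.names = FALSE))
  )
  S4Vectors::mcols(gr)$gene_idx <- gi
  gr
}

exonic_length <- function(genes) {
  vapply(seq_len(nrow(genes)), function(i)
    sum(genes$exon_ends[[i]] - genes$exon_starts[[i]]), numeric(1))
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (exonic_length_bp * total_mapped)`.
#'
#' @param count Read count (vectorised).
#' @param exonic_length_bp Exonic length in bp (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return Numeric RPKM.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, exonic_length_bp, total_mapped) {
  if (any(exonic_length_bp <= 0)) stop("exonic_length_bp must be > 0", call. = FALSE)
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0", call. = FALSE)
  count * 1e9 / (exonic_length_bp * total_mapped)
}

#' Classify genes by RPKM activity
#'
#' `inactive` below `rpkm_active`, `high` strictly above `rpkm_high`,
#' `active` in between.  Boundaries are assigned upward for the active
#' cutoff (RPKM exactly 1 is active) and downward for the high cutoff
#' (RPKM exactly 5 is active, not high), following the strict "> 5"
#' convention.
#'
#' @param x Numeric RPKM values.
#' @param params An [analysis_params()] object.
#' @return Factor with levels `inactive`, `active`, `high`.
#' @export
classify_rpkm <- function(x, params = analysis_params()) {
  params <- as_analysis_params(params)
  stopifnot(all(x >= 0))
  cls <- ifelse(x < params$rpkm_active, "inactive",
                ifelse(x > params$rpkm_high, "high", "active"))
  factor(cls, levels = c("inactive", "active", "high"))
}

#' Full expression table from reads and gene models
#'
#' Counts reads (union-exon mode), converts to RPKM using the exonic
#' length and either a supplied library size or the number of assigned
#' plus unassigned reads, and attaches activity classes.
#'
#' @param reads data.frame of read intervals ([read_bed_reads()]).
#' @param genes A `"gene_models"` data.frame.
#' @param params An [analysis_params()] object.
#' @param total_mapped Library size used as the RPKM denominator; when
#'   `NULL`, the total number of distinct reads supplied.
#' @return data.frame of class `"expression_table"`: `gene`, `read_count`,
#'   `exonic_length_bp`, `rpkm`, `activity_class`, with counting stats as
#'   attributes.
#' @export
expression_table <- function(reads, genes, params = analysis_params(),
                             total_mapped = NULL) {
  params <- as_analysis_params(params)
  counts <- count_reads(reads, genes)
  if (is.null(total_mapped)) total_mapped <- attr(counts, "n_reads")
  len <- exonic_length(genes)
  vals <- rpkm(as.numeric(counts), len, total_mapped)
  out <- data.frame(
    gene = genes$name,
    read_count = as.integer(counts),
    exonic_length_bp = as.integer(len),
    rpkm = vals,
    activity_class = classify_rpkm(vals, params),
    stringsAsFactors = FALSE
  )
  attr(out, "total_mapped") <- total_mapped
  attr(out, "ambiguous") <- attr(counts, "ambiguous")
  attr(out, "unassigned") <- attr(counts, "unassigned")
  class(out) <- c("expression_table", "data.frame")
  out
}
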
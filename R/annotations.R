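#' Parse a refGene-style annotation table
#'
#' Reads UCSC refGene rows (tab-delimited, with or without the leading
#' `bin` column -- autodetected from the position of the strand field)
#' into a gene-model table.  Coordinates are kept in the native UCSC
#' convention: 0-based, half-open.  Each row must describe a transcript
#' whose exon list is sorted, non-overlapping and flush with the
#' transcript span; violations are reported as parse errors naming the
#' offending line.
#'
#' @param lines Character vector of raw table lines (as from
#'   [readLines()]); comment (`#`) lines are skipped.
#' @return A data.frame of class `"gene_models"` with one row per
#'   transcript and columns `name`, `name2`, `chrom`, `strand`, `start`,
#'   `end`, `n_exons`, plus list columns `exon_starts` and `exon_ends`
#'   holding integer vectors in genomic order.
#' @examples
#' gm <- parse_refgene(paste("t1", "chr1", "+", 100, 1100, 100, 1100, 2,
#'                           "100,600,", "300,1100,", 0, "g1", sep = "\t"))
#' gm$exon_starts[[1]]
#' @seealso [read_refgene()], [derive_features()], [filter_genes()]
#' @export
parse_refgene <- function(lines) {
  lines <- as.character(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_gene_models())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # strand sits in column 4 when a numeric bin column leads, column 3 otherwise
  probe <- fields[[1L]]
  has_bin <- length(probe) >= 4L && probe[4L] %in% c("+", "-", ".") &&
    !(probe[3L] %in% c("+", "-", "."))
  off <- if (has_bin) 1L else 0L
  need <- off + 10L
  if (any(nf < need)) {
    bad <- lineno[which(nf < need)[1L]]
    stop("refGene parse error at line ", bad, ": expected at least ",
         need, " tab-separated fields", call. = FALSE)
  }

  col <- function(i) vapply(fields, `[[`, character(1), i + off)
  name <- col(1L)
  chrom <- col(2L)
  strand <- col(3L)
  start <- suppressWarnings(as.integer(col(4L)))
  end <- suppressWarnings(as.integer(col(5L)))
  n_exons <- suppressWarnings(as.integer(col(8L)))
  exon_starts <- parse_pos_list(col(9L))
  exon_ends <- parse_pos_list(col(10L))
  # name2 (gene symbol) is column 12 of the bin-less schema when present
  name2 <- if (all(nf >= off + 12L)) col(12L) else name

  for (i in seq_along(lines)) {
    ln <- lineno[i]
    es <- exon_starts[[i]]
    ee <- exon_ends[[i]]
    if (is.na(start[i]) || is.na(end[i]) || is.na(n_exons[i]))
      stop("refGene parse error at line ", ln, ": non-numeric coordinates",
           call. = FALSE)
    if (length(es) != n_exons[i] || length(ee) != n_exons[i])
      stop("refGene parse error at line ", ln, ": exonCount (", n_exons[i],
           ") disagrees with exon list lengths (", length(es), ", ",
           length(ee), ")", call. = FALSE)
    if (any(ee <= es))
      stop("refGene parse error at line ", ln, ": empty or inverted exon",
           call. = FALSE)
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1L] < ee[-length(ee)]))
      stop("refGene parse error at line ", ln,
           ": exons unsorted or overlapping", call. = FALSE)
    if (es[1L] != start[i] || ee[length(ee)] != end[i])
      stop("refGene parse error at line ", ln,
           ": exon list does not span txStart..txEnd", call. = FALSE)
    if (!strand[i] %in% c("+", "-", "."))
      stop("refGene parse error at line ", ln, ": bad strand '",
           strand[i], "'", call. = FALSE)
  }

  gm <- data.frame(
    name = name, name2 = name2, chrom = chrom, strand = strand,
    start = start, end = end, n_exons = n_exons,
    stringsAsFactors = FALSE
  )
  gm$exon_starts <- exon_starts
  gm$exon_ends <- exon_ends
  class(gm) <- c("gene_models", "data.frame")
  gm
}

parse_pos_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.integer(v)
  })
}

empty_gene_models <- function() {
  gm <- data.frame(
    name = character(), name2 = character(), chrom = character(),
    strand = character(), start = integer(), end = integer(),
    n_exons = integer(), stringsAsFactors = FALSE
  )
  gm$exon_starts <- list()
  gm$exon_ends <- list()
  class(gm) <- c("gene_models", "data.frame")
  gm
}

#' Read a refGene table from a file
#'
#' @param path Path to a tab-delimited refGene table, optionally
#'   gzip-compressed (detected from a `.gz` suffix).
#' @return A `"gene_models"` data.frame; see [parse_refgene()].
#' @export
read_refgene <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  parse_refgene(readLines(con))
}

#' Write gene models as a refGene-style table
#'
#' Emits the bin-less 12-column layout accepted by [parse_refgene()]
#' (cdsStart/cdsEnd mirror the transcript span; score is 0).
#'
#' @param genes A `"gene_models"` data.frame.
#' @param path Output file path.
#' @export
write_refgene <- function(genes, path) {
  fmt_list <- function(l) vapply(l, function(v) paste0(paste(v, collapse = ","), ","), character(1))
  out <- data.frame(
    name = genes$name, chrom = genes$chrom, strand = genes$strand,
    txStart = genes$start, txEnd = genes$end,
    cdsStart = genes$start, cdsEnd = genes$end,
    exonCount = genes$n_exons,
    exonStarts = fmt_list(genes$exon_starts),
    exonEnds = fmt_list(genes$exon_ends),
    score = 0L, name2 = genes$name2,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models: ", nrow(x), " transcripts on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

#' Derive introns and exon-intron-exon triplets
#'
#' Introns are the gaps between consecutive exons of each transcript; a
#' triplet couples each retained intron with its two immediately
#' adjacent exons.  Triplets are kept only when the intron is strictly
#' longer than `params$min_intron_bp` (an intron of exactly that length
#' is excluded).  Outputs are in genomic (left-to-right) orientation
#' regardless of strand; the strand column allows downstream
#' strand-aware handling.
#'
#' @param genes A `"gene_models"` data.frame (one or many rows).
#' @param params An [analysis_params()] object.
#' @param deduplicate If `TRUE`, identical (chrom, left, intron, right)
#'   triplets arising from several transcripts are collapsed to one.
#' @return A list with `introns` (data.frame: gene, chrom, start, end,
#'   strand) and `triplets` (data.frame: gene, chrom, left_start,
#'   left_end, intron_start, intron_end, right_start, right_end,
#'   strand).  Single-exon genes contribute nothing.
#' @examples
#' gm <- parse_refgene(paste("t1", "chr1", "+", 100, 1100, 100, 1100, 2,
#'                           "100,600,", "300,1100,", 0, "g1", sep = "\t"))
#' derive_features(gm)$triplets
#' @export
derive_features <- function(genes, params = analysis_params(),
                            deduplicate = FALSE) {
  params <- as_analysis_params(params)
  n_int <- pmax(genes$n_exons - 1L, 0L)
  idx <- rep.int(seq_len(nrow(genes)), n_int)
  if (length(idx) == 0L) {
    return(list(introns = empty_introns(), triplets = empty_triplets()))
  }
  k <- unlist(lapply(n_int, seq_len), use.names = FALSE)  # intron ordinal
  es <- genes$exon_starts
  ee <- genes$exon_ends
  # for gene i, intron j spans (ee[[i]][j], es[[i]][j+1])
  left_start  <- mapply(function(i, j) es[[i]][j],     idx, k)
  left_end    <- mapply(function(i, j) ee[[i]][j],     idx, k)
  right_start <- mapply(function(i, j) es[[i]][j + 1L], idx, k)
  right_end   <- mapply(function(i, j) ee[[i]][j + 1L], idx, k)

  introns <- data.frame(
    gene = genes$name[idx], chrom = genes$chrom[idx],
    start = left_end, end = right_start, strand = genes$strand[idx],
    stringsAsFactors = FALSE
  )
  introns <- introns[introns$end > introns$start, , drop = FALSE]  # no zero-length gaps

  keep <- (right_start - left_end) > params$min_intron_bp
  triplets <- data.frame(
    gene = genes$name[idx], chrom = genes$chrom[idx],
    left_start = left_start, left_end = left_end,
    intron_start = left_end, intron_end = right_start,
    right_start = right_start, right_end = right_end,
    strand = genes$strand[idx],
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]

  if (deduplicate) {
    key <- with(triplets, paste(chrom, left_start, left_end, intron_end,
                                right_end, sep = ":"))
    triplets <- triplets[!duplicated(key), , drop = FALSE]
    ikey <- with(introns, paste(chrom, start, end, sep = ":"))
    introns <- introns[!duplicated(ikey), , drop = FALSE]
  }
  rownames(introns) <- NULL
  rownames(triplets) <- NULL
  list(introns = introns, triplets = triplets)
}

empty_introns <- function() {
  data.frame(gene = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), stringsAsFactors = FALSE)
}

empty_triplets <- function() {
  data.frame(gene = character(), chrom = character(),
             left_start = integer(), left_end = integer(),
             intron_start = integer(), intron_end = integer(),
             right_start = integer(), right_end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Write derived triplets to TSV
#'
#' @param triplets Triplet data.frame from [derive_features()].
#' @param path Output path.
#' @export
write_triplets <- function(triplets, path) {
  utils::write.table(triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter gene models for unambiguous signal extraction
#'
#' Two filters, applied in order and both motivated by signal bleed
#' between close or redundant annotation entries: (1) every entry whose
#' `name` occurs more than once is removed (all copies -- the table then
#' supports unambiguous cross-referencing by name); (2) every gene whose
#' span, extended by `flank_bp` on both sides, comes within
#' `min_separation_bp` of another gene's extended span on the same
#' chromosome is removed (both members of the close pair).  A gap of
#' exactly `min_separation_bp` is kept.  Output order is stable and the
#' filter is idempotent.
#'
#' @param genes A `"gene_models"` data.frame.
#' @param params An [analysis_params()] object.
#' @return The retained subset, same class and column layout.
#' @export
filter_genes <- function(genes, params = analysis_params()) {
  params <- as_analysis_params(params)
  if (nrow(genes) == 0L) return(genes)
  dup <- genes$name %in% genes$name[duplicated(genes$name)]
  genes <- genes[!dup, , drop = FALSE]
  if (nrow(genes) <= 1L) { rownames(genes) <- NULL; return(genes) }

  # conflict iff gap between flank-extended spans < min_separation_bp;
  # encoded as overlap of spans extended by flank on the left and by
  # flank + min_separation on the right (half-open)
  ext <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(
      start = genes$start - params$flank_bp + 1L,  # 1-based closed for IRanges
      end = genes$end + params$flank_bp + params$min_separation_bp
    )
  )
  hits <- GenomicRanges::findOverlaps(ext, ext, minoverlap = 1L)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  # the asymmetric right-extension still flags both members: if A's
  # extension reaches B then gap(A,B) < min_separation regardless of order
  clash <- union(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  out <- genes[setdiff(seq_len(nrow(genes)), clash), , drop = FALSE]
  rownames(out) <- NULL
  out
}
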
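#' Analysis parameters
#'
#' Bundles the tunable parameters shared by the annotation filters, the
#' metagene profiler, the expression classifier and the enrichment
#' statistics.  Defaults follow the conventions of metagene/occupancy
#' analyses of Drosophila ChIP-seq data: 500 bp per-base flanks around a
#' 16-bin scaled gene body, introns retained only when strictly longer
#' than 100 bp, RPKM activity cutoffs at 1 (active) and 5 (high), and a
#' 1 kb isolation distance between flank-extended gene spans.
#'
#' @param flank_bp Width in bp of the per-base flanking windows on either
#'   side of the gene body (default 500).
#' @param n_bins Number of equal-share bins the gene body is scaled to
#'   (default 16).
#' @param min_intron_bp Introns must be strictly longer than this many bp
#'   to enter the exon/intron/exon analysis (default 100).
#' @param rpkm_active RPKM at or above which a gene is called active
#'   (default 1).
#' @param rpkm_high RPKM strictly above which a gene is called highly
#'   expressed (default 5).
#' @param min_separation_bp Minimum distance in bp required between the
#'   flank-extended spans of neighbouring genes; genes closer than this
#'   are removed by [filter_genes()] (default 1000).
#' @param read_length_bp Read length used to approximate a mapped-read
#'   count from total signal when a track declares none (default 50).
#' @param pseudocount Pseudocount added before log10 in the exon
#'   correlation scatter (default 0.1).
#'
#' @return A list of class `"analysis_params"`.
#' @examples
#' p <- analysis_params(min_intron_bp = 250)
#' p$min_intron_bp
#' @export
analysis_params <- function(flank_bp = 500L, n_bins = 16L, min_intron_bp = 100L,
                            rpkm_active = 1, rpkm_high = 5,
                            min_separation_bp = 1000L, read_length_bp = 50L,
                            pseudocount = 0.1) {
  p <- list(
    flank_bp = as.integer(flank_bp),
    n_bins = as.integer(n_bins),
    min_intron_bp = as.integer(min_intron_bp),
    rpkm_active = as.numeric(rpkm_active),
    rpkm_high = as.numeric(rpkm_high),
    min_separation_bp = as.integer(min_separation_bp),
    read_length_bp = as.integer(read_length_bp),
    pseudocount = as.numeric(pseudocount)
  )
  stopifnot(
    p$flank_bp >= 0L, p$n_bins >= 1L, p$min_intron_bp >= 0L,
    p$rpkm_active > 0, p$rpkm_high >= p$rpkm_active,
    p$min_separation_bp >= 0L, p$read_length_bp >= 1L, p$pseudocount >= 0
  )
  class(p) <- "analysis_params"
  p
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_analysis_params <- function(x) {
  if (inherits(x, "analysis_params")) return(x)
  if (is.null(x)) return(analysis_params())
  stopifnot(is.list(x))
  do.call(analysis_params, x)
}

# restore the caller's RNG stream after a seeded computation
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
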
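#' Scaled occupancy profile of one gene
#'
#' Assembles, in 5' to 3' orientation, `flank_bp` per-base values
#' upstream of the TSS, `n_bins` bin means over the gene span (bins are
#' contiguous, of size `floor(L / n_bins)` or one more, the remainder
#' spread over the 5'-most `L %% n_bins` bins), and `flank_bp` per-base
#' values downstream of the gene end.  Minus-strand genes are read right
#' to left, so a mirrored annotation on a mirrored track yields the
#' identical profile.
#'
#' @param track A `"coverage_track"`.
#' @param gene One row of a `"gene_models"` data.frame.
#' @param params An [analysis_params()] object.
#' @return Numeric vector of length `2 * flank_bp + n_bins`, or `NULL`
#'   (with a message) when the gene span is shorter than `n_bins`.
#' @export
gene_profile <- function(track, gene, params = analysis_params()) {
  params <- as_analysis_params(params)
  L <- gene$end - gene$start
  if (L < params$n_bins) {
    message("gene ", gene$name, " skipped: span (", L,
            " bp) shorter than n_bins (", params$n_bins, ")")
    return(NULL)
  }
  r <- track$cov[[gene$chrom]]
  span_plus_flanks <- if (is.null(r)) {
    numeric(L + 2L * params$flank_bp)
  } else {
    window_rle(r, gene$start - params$flank_bp, gene$end + params$flank_bp)
  }
  # orient 5' -> 3' before binning so the remainder rule is strand-symmetric
  if (identical(gene$strand, "-"))
    span_plus_flanks <- rev(span_plus_flanks)
  fl <- params$flank_bp
  up <- span_plus_flanks[seq_len(fl)]
  body <- span_plus_flanks[fl + seq_len(L)]
  down <- span_plus_flanks[fl + L + seq_len(fl)]
  c(up, bin_means(body, params$n_bins), down)
}

# contiguous bin means; the length remainder goes to the earliest bins
bin_means <- function(v, n_bins) {
  L <- length(v)
  base <- L %/% n_bins
  rem <- L %% n_bins
  sizes <- base + (seq_len(n_bins) <= rem)
  ends <- cumsum(sizes)
  cs <- c(0, cumsum(v))
  (cs[ends + 1L] - cs[ends - sizes + 1L]) / sizes
}

#' Average gene profiles into a metagene curve
#'
#' Pointwise arithmetic mean across genes, multiplied by the track's
#' per-million scale so datasets of different depth are comparable.
#'
#' @param profiles List of equal-length numeric profiles (no `NULL`s) or
#'   a matrix with one row per gene.
#' @param track_summary A `"track_summary"` from [track_total()]; its
#'   `scale_per_million` is applied.  Pass `NULL` to skip scaling.
#' @param stratum Optional label (e.g. an RPKM class).
#' @return List of class `"metagene_profile"`: `mean` (numeric vector),
#'   `n_genes`, `scale_per_million`, `stratum`.
#' @export
metagene_average <- function(profiles, track_summary = NULL, stratum = NA) {
  if (is.list(profiles)) {
    if (length(profiles) == 0L) stop("no profiles to average", call. = FALSE)
    lens <- lengths(profiles)
    if (length(unique(lens)) != 1L)
      stop("profiles have differing lengths", call. = FALSE)
    profiles <- do.call(rbind, profiles)
  }
  if (!is.matrix(profiles) || nrow(profiles) == 0L)
    stop("no profiles to average", call. = FALSE)
  scale <- if (is.null(track_summary)) 1 else track_summary$scale_per_million
  structure(list(
    mean = colMeans(profiles) * scale,
    n_genes = nrow(profiles),
    scale_per_million = scale,
    stratum = stratum
  ), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("Metagene profile", if (!is.na(x$stratum)) paste0(" [", x$stratum, "]"),
      ": n = ", x$n_genes, ", length ", length(x$mean),
      ", scale/1e6 = ", format(x$scale_per_million), "\n", sep = "")
  invisible(x)
}

#' Metagene curves for a gene set, optionally stratified
#'
#' Convenience wrapper: profiles every gene (skipping those shorter than
#' `n_bins`) and averages within each stratum.
#'
#' @param track A `"coverage_track"`.
#' @param genes A `"gene_models"` data.frame.
#' @param params An [analysis_params()] object.
#' @param strata Optional vector (length `nrow(genes)`) of stratum
#'   labels, e.g. `expression_table()$activity_class`.
#' @param track_summary Optional precomputed [track_total()]; computed
#'   from the track otherwise.
#' @return Named list of `"metagene_profile"` objects (one per stratum,
#'   or a single `"all"` entry), with attribute `skipped` (gene names
#'   too short to profile).
#' @export
metagene <- function(track, genes, params = analysis_params(), strata = NULL,
                     track_summary = NULL) {
  params <- as_analysis_params(params)
  if (is.null(track_summary))
    track_summary <- track_total(track, params$read_length_bp)
  if (is.null(strata)) strata <- rep("all", nrow(genes))
  strata <- as.character(strata)
  profiles <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes)))
    profiles[[i]] <- gene_profile(track, genes[i, , drop = FALSE], params)
  ok <- !vapply(profiles, is.null, logical(1))
  out <- lapply(split(which(ok), strata[ok]), function(ix)
    metagene_average(profiles[ix], track_summary,
                     stratum = strata[ix[1L]]))
  attr(out, "skipped") <- genes$name[!ok]
  out
}

#' Position labels for a metagene vector
#'
#' `-flank..-1` upstream, `bin1..binK` for the body, `+1..+flank`
#' downstream (5' to 3').
#'
#' @param params An [analysis_params()] object.
#' @return Character vector of length `2 * flank_bp + n_bins`.
#' @export
metagene_positions <- function(params = analysis_params()) {
  params <- as_analysis_params(params)
  c(paste0(-(params$flank_bp:1)),
    paste0("bin", seq_len(params$n_bins)),
    paste0("+", seq_len(params$flank_bp)))
}

#' Write metagene curves to TSV
#'
#' Long format: `position`, `index`, `mean`, `stratum`, `n`.
#'
#' @param profiles Result of [metagene()] (named list) or a single
#'   `"metagene_profile"`.
#' @param path Output path.
#' @param params The [analysis_params()] the profiles were built with.
#' @export
write_metagene <- function(profiles, path, params = analysis_params()) {
  if (inherits(profiles, "metagene_profile")) profiles <- list(profiles)
  pos <- metagene_positions(params)
  rows <- lapply(profiles, function(p) data.frame(
    position = pos, index = seq_along(p$mean), mean = p$mean,
    stratum = as.character(p$stratum), n = p$n_genes,
    stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
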
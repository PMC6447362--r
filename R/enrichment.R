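#' Input-normalised enrichment over exon-intron-exon triplets
#'
#' For each triplet, the mean per-base ChIP and input coverage of the
#' left exon, intron and right exon are computed, each track is scaled
#' to per-million (so the ratio is invariant when both libraries scale
#' together), and the normalised value of a feature is
#' `chip_mean / input_mean`.  Records with a zero input mean -- or a
#' zero chip mean, which would make ratios and log2 fold-changes
#' degenerate -- on any of the three features are dropped (counts
#' reported separately); a pseudocount mode adds `pseudocount` to both
#' means instead and keeps everything.
#'
#' @param chip,input `"coverage_track"` objects on a shared chromosome
#'   namespace.
#' @param triplets Triplet data.frame from [derive_features()].
#' @param params An [analysis_params()] object (`read_length_bp` feeds
#'   the per-million normaliser when no read count is declared).
#' @param zero_input How to treat zero input coverage: `"drop"`
#'   (default) or `"pseudocount"`.
#' @param pseudocount Added to scaled chip and input means in
#'   pseudocount mode.
#' @return data.frame of class `"enrichment_table"`, one row per
#'   retained triplet: `gene`, `chrom`, per-feature chip/input means,
#'   `left_norm`, `intron_norm`, `right_norm`, `log2fc_left`,
#'   `log2fc_right` (exon over intron).  Attributes: `n_dropped`,
#'   `n_input_zero`, scale factors.
#' @export
triplet_enrichment <- function(chip, input, triplets,
                               params = analysis_params(),
                               zero_input = c("drop", "pseudocount"),
                               pseudocount = 0.1) {
  params <- as_analysis_params(params)
  zero_input <- match.arg(zero_input)
  if (nrow(triplets) == 0L) stop("empty triplet list", call. = FALSE)
  sc_chip <- track_total(chip, params$read_length_bp)$scale_per_million
  sc_input <- track_total(input, params$read_length_bp)$scale_per_million

  fmean <- function(track, s, e) track_means(track, triplets$chrom, s, e)
  chip_left <- fmean(chip, triplets$left_start, triplets$left_end) * sc_chip
  chip_intron <- fmean(chip, triplets$intron_start, triplets$intron_end) * sc_chip
  chip_right <- fmean(chip, triplets$right_start, triplets$right_end) * sc_chip
  in_left <- fmean(input, triplets$left_start, triplets$left_end) * sc_input
  in_intron <- fmean(input, triplets$intron_start, triplets$intron_end) * sc_input
  in_right <- fmean(input, triplets$right_start, triplets$right_end) * sc_input

  zero <- in_left == 0 | in_intron == 0 | in_right == 0
  chip_zero <- chip_left == 0 | chip_intron == 0 | chip_right == 0
  if (zero_input == "pseudocount") {
    chip_left <- chip_left + pseudocount; in_left <- in_left + pseudocount
    chip_intron <- chip_intron + pseudocount; in_intron <- in_intron + pseudocount
    chip_right <- chip_right + pseudocount; in_right <- in_right + pseudocount
    keep <- rep(TRUE, nrow(triplets))
  } else {
    # retained records must have strictly positive normalised values so
    # that ratios and log2 fold-changes stay finite
    keep <- !zero & !chip_zero
  }

  out <- data.frame(
    gene = triplets$gene[keep], chrom = triplets$chrom[keep],
    chip_left = chip_left[keep], chip_intron = chip_intron[keep],
    chip_right = chip_right[keep],
    input_left = in_left[keep], input_intron = in_intron[keep],
    input_right = in_right[keep],
    left_norm = chip_left[keep] / in_left[keep],
    intron_norm = chip_intron[keep] / in_intron[keep],
    right_norm = chip_right[keep] / in_right[keep],
    stringsAsFactors = FALSE
  )
  out$log2fc_left <- log2(out$left_norm / out$intron_norm)
  out$log2fc_right <- log2(out$right_norm / out$intron_norm)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_input_zero") <- sum(zero)
  attr(out, "n_chip_zero") <- sum(chip_zero & !zero)
  attr(out, "scale_chip") <- sc_chip
  attr(out, "scale_input") <- sc_input
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Exon-versus-intron summary statistics
#'
#' Runs three two-sided unpaired rank-sum tests on the normalised
#' values -- left exon vs intron, right exon vs intron, left vs right
#' exon -- and computes box-plot statistics per feature class (type-7
#' quartiles; whiskers at the most extreme data point within 1.5
#' interquartile ranges of the quartiles).
#'
#' @param records An `"enrichment_table"` from [triplet_enrichment()]
#'   with at least 2 rows.
#' @return List of class `"exon_intron_summary"`: `tests` (named list of
#'   `"rank_sum_test"`), `boxstats` (data.frame), `n_records`,
#'   `median_ratio_left`, `median_ratio_right` (median per-triplet
#'   exon/intron normalised ratios).
#' @export
exon_vs_intron_summary <- function(records) {
  if (nrow(records) < 2L) stop("need at least 2 enrichment records", call. = FALSE)
  tests <- list(
    left_vs_intron = rank_sum_test(records$left_norm, records$intron_norm),
    right_vs_intron = rank_sum_test(records$right_norm, records$intron_norm),
    left_vs_right = rank_sum_test(records$left_norm, records$right_norm)
  )
  boxstats <- do.call(rbind, lapply(
    c(left_exon = "left_norm", intron = "intron_norm", right_exon = "right_norm"),
    function(col) box_stats(records[[col]])))
  boxstats <- data.frame(feature = c("left_exon", "intron", "right_exon"),
                         boxstats, row.names = NULL)
  structure(list(
    tests = tests,
    boxstats = boxstats,
    n_records = nrow(records),
    median_ratio_left = stats::median(records$left_norm / records$intron_norm),
    median_ratio_right = stats::median(records$right_norm / records$intron_norm)
  ), class = "exon_intron_summary")
}

box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  data.frame(q1 = q[1], median = q[2], q3 = q[3],
             whisker_low = min(x[x >= lo_fence]),
             whisker_high = max(x[x <= hi_fence]),
             n_outliers = sum(x < lo_fence | x > hi_fence))
}

#' @export
print.exon_intron_summary <- function(x, ...) {
  cat("Exon vs intron enrichment summary (n = ", x$n_records, " triplets)\n",
      sep = "")
  for (nm in names(x$tests))
    cat(sprintf("  %-16s p = %.4g (U = %g)\n", nm,
                x$tests[[nm]]$p_value, x$tests[[nm]]$U))
  cat(sprintf("  median exon/intron ratio: left %.3f, right %.3f\n",
              x$median_ratio_left, x$median_ratio_right))
  invisible(x)
}

#' Percent-of-length enrichment profile
#'
#' For each feature the per-base chip/input ratio (both tracks
#' per-million scaled; bases with zero input are masked) is resampled
#' onto 100 percent-of-length positions: base `i` (0-based) of a
#' feature of length `L` contributes to percent bin
#' `floor((i + 0.5) * 100 / L)`, which covers every bin when `L >= 100`
#' and assigns each base of a shorter feature to its nearest bin.
#' Minus-strand features are flipped first so position 0% is the 5'
#' end.  The profile is the pointwise mean over features (bins with no
#' contributing base in a feature are ignored for that feature).
#'
#' @param chip,input `"coverage_track"` objects.
#' @param features data.frame with `chrom`, `start`, `end` and
#'   optionally `strand` (defaults to `+`).
#' @param params An [analysis_params()] object.
#' @return List of class `"percent_profile"`: `profile` (length-100
#'   numeric), `n_features`, `n_masked_bases`.
#' @export
percent_length_profile <- function(chip, input, features,
                                   params = analysis_params()) {
  params <- as_analysis_params(params)
  if (nrow(features) == 0L) stop("empty feature list", call. = FALSE)
  if (is.null(features$strand)) features$strand <- "+"
  sc_chip <- track_total(chip, params$read_length_bp)$scale_per_million
  sc_input <- track_total(input, params$read_length_bp)$scale_per_million
  acc <- matrix(0, nrow(features), 100L)
  cnt <- matrix(0L, nrow(features), 100L)
  masked <- 0L
  for (i in seq_len(nrow(features))) {
    ch <- features$chrom[i]; s <- features$start[i]; e <- features$end[i]
    L <- e - s
    cv <- (if (is.null(chip$cov[[ch]])) numeric(L) else window_rle(chip$cov[[ch]], s, e)) * sc_chip
    iv <- (if (is.null(input$cov[[ch]])) numeric(L) else window_rle(input$cov[[ch]], s, e)) * sc_input
    if (identical(features$strand[i], "-")) { cv <- rev(cv); iv <- rev(iv) }
    ok <- iv > 0
    masked <- masked + sum(!ok)
    if (!any(ok)) next
    ratio <- cv[ok] / iv[ok]
    bin <- pmin(floor(((which(ok) - 0.5) * 100) / L), 99L) + 1L
    sums <- numeric(100L)
    agg <- rowsum(ratio, bin)
    sums[as.integer(rownames(agg))] <- agg[, 1L]
    acc[i, ] <- sums
    cnt[i, ] <- tabulate(bin, nbins = 100L)
  }
  per_feature <- acc / ifelse(cnt > 0L, cnt, NA_real_)
  profile <- colMeans(per_feature, na.rm = TRUE)
  structure(list(profile = profile, n_features = nrow(features),
                 n_masked_bases = masked),
            class = "percent_profile")
}

#' Cross-track exon correlation
#'
#' Per exon of the supplied genes, the per-million-scaled mean coverage
#' in each track; Pearson correlation on `log10(x + pseudocount)` (the
#' default transform for depth-normalised read densities spanning
#' decades) with Spearman on the raw values alongside.
#'
#' @param trackA,trackB `"coverage_track"` objects.
#' @param genes A `"gene_models"` data.frame (>= 3 genes recommended).
#' @param params An [analysis_params()] object (`pseudocount` feeds the
#'   log transform).
#' @return List of class `"exon_correlation"`: `table` (gene, chrom,
#'   start, end, a, b), `pearson_log10`, `spearman`, `n_exons`,
#'   `pseudocount`; correlations are `NA` with `degenerate = TRUE` when
#'   either vector is constant.
#' @export
exon_correlation <- function(trackA, trackB, genes,
                             params = analysis_params()) {
  params <- as_analysis_params(params)
  if (nrow(genes) == 0L) stop("no genes supplied", call. = FALSE)
  scA <- track_total(trackA, params$read_length_bp)$scale_per_million
  scB <- track_total(trackB, params$read_length_bp)$scale_per_million
  n_ex <- genes$n_exons
  gi <- rep.int(seq_len(nrow(genes)), n_ex)
  ex <- data.frame(
    gene = genes$name[gi],
    chrom = genes$chrom[gi],
    start = unlist(genes$exon_starts, use.names = FALSE),
    end = unlist(genes$exon_ends, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  ex$a <- track_means(trackA, ex$chrom, ex$start, ex$end) * scA
  ex$b <- track_means(trackB, ex$chrom, ex$start, ex$end) * scB
  degenerate <- stats::sd(ex$a) == 0 || stats::sd(ex$b) == 0
  pc <- params$pseudocount
  structure(list(
    table = ex,
    pearson_log10 = if (degenerate) NA_real_ else
      stats::cor(log10(ex$a + pc), log10(ex$b + pc), method = "pearson"),
    spearman = if (degenerate) NA_real_ else
      stats::cor(ex$a, ex$b, method = "spearman"),
    degenerate = degenerate,
    n_exons = nrow(ex),
    pseudocount = pc
  ), class = "exon_correlation")
}

#' @export
print.exon_correlation <- function(x, ...) {
  cat("Exon correlation over ", x$n_exons, " exons: Pearson(log10) = ",
      format(x$pearson_log10, digits = 4), ", Spearman = ",
      format(x$spearman, digits = 4), "\n", sep = "")
  invisible(x)
}
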
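#' Build a coverage track from step intervals
#'
#' A coverage track holds stepwise per-base signal with Bedgraph
#' semantics: 0-based half-open steps, implicit zero everywhere not
#' covered by a step.  Internally each chromosome is stored as an
#' [S4Vectors::Rle] over `[0, last step end)`.
#'
#' @param steps data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open; values finite and >= 0).  Steps on one
#'   chromosome must not overlap.
#' @param label Optional track label.
#' @param total_mapped_reads Optional declared number of mapped reads in
#'   the library the track was computed from; used by [track_total()]
#'   for per-million scaling.
#' @return An object of class `"coverage_track"`.
#' @examples
#' tr <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 10, value = 2))
#' track_query(tr, "chr1", 0, 10)$mean
#' @export
coverage_track <- function(steps, label = "track", total_mapped_reads = NULL) {
  stopifnot(is.data.frame(steps),
            all(c("chrom", "start", "end", "value") %in% names(steps)))
  validate_steps(steps)
  cov <- list()
  for (ch in unique(steps$chrom)) {
    s <- steps[steps$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    cov[[ch]] <- steps_to_rle(s$start, s$end, s$value)
  }
  structure(list(cov = cov, label = label,
                 total_mapped_reads = total_mapped_reads),
            class = "coverage_track")
}

validate_steps <- function(steps, lineno = NULL) {
  bad_at <- function(i, msg) {
    where <- if (is.null(lineno)) paste0("step ", i) else paste0("line ", lineno[i])
    stop("Bedgraph format error at ", where, ": ", msg, call. = FALSE)
  }
  if (nrow(steps) == 0L) return(invisible(TRUE))
  if (any(!is.finite(steps$value))) bad_at(which(!is.finite(steps$value))[1L], "non-finite value")
  if (any(steps$value < 0)) bad_at(which(steps$value < 0)[1L], "negative value")
  if (any(steps$end <= steps$start)) bad_at(which(steps$end <= steps$start)[1L], "empty interval")
  if (any(steps$start < 0)) bad_at(which(steps$start < 0)[1L], "negative coordinate")
  for (ch in unique(steps$chrom)) {
    i <- which(steps$chrom == ch)
    o <- i[order(steps$start[i])]
    if (length(o) > 1L) {
      ovl <- which(steps$start[o][-1L] < steps$end[o][-length(o)])
      if (length(ovl)) bad_at(o[ovl[1L] + 1L], paste0("overlapping steps on ", ch))
    }
  }
  invisible(TRUE)
}

steps_to_rle <- function(start, end, value) {
  # interleave explicit zero runs for the gaps
  n <- length(start)
  gap_start <- c(0L, end[-n])
  gap_len <- start - gap_start
  lens <- as.numeric(rbind(gap_len, end - start))
  vals <- as.numeric(rbind(numeric(n), value))
  keep <- lens > 0
  S4Vectors::Rle(vals[keep], lens[keep])
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                             as.numeric(S4Vectors::runLength(r))), numeric(1)))
  cat("Coverage track '", x$label, "': ", length(x$cov),
      " chromosome(s), total signal ", format(tot), "\n", sep = "")
  invisible(x)
}

#' Read a Bedgraph file
#'
#' Accepts 4-column Bedgraph (chrom, start, end, value; 0-based
#' half-open), optionally gzip-compressed.  `track`/`browser`/comment
#' header lines are skipped.  Zero-valued lines (as `genomeCoverageBed
#' -bga` emits) are accepted; gaps are implicit zeros.  Overlapping
#' steps or negative values raise a format error naming the line.
#'
#' @param path File path (`.gz` handled transparently).
#' @inheritParams coverage_track
#' @return A `"coverage_track"`.
#' @export
read_bedgraph <- function(path, label = basename(path),
                          total_mapped_reads = NULL) {
  # count leading track/browser/comment lines so fread sees data rows only
  head_con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  head_lines <- readLines(head_con, n = 100L)
  close(head_con)
  is_hdr <- grepl("^(track|browser|#)", head_lines) | !nzchar(head_lines)
  n_skip <- if (all(is_hdr)) length(head_lines) else which(!is_hdr)[1L] - 1L
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "auto", fill = TRUE,
                      skip = n_skip, colClasses = list(character = 1),
                      blank.lines.skip = FALSE, showProgress = FALSE),
    error = function(e) NULL
  )
  empty <- coverage_track(
    data.frame(chrom = character(), start = integer(), end = integer(),
               value = numeric()),
    label = label, total_mapped_reads = total_mapped_reads)
  if (is.null(dt) || nrow(dt) == 0L) return(empty)
  first <- dt[[1L]]
  is_header <- grepl("^(track|browser|#)", first) | !nzchar(first)
  lineno <- n_skip + which(!is_header)
  dt <- dt[!is_header]
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 4L)
    stop("Bedgraph format error: fewer than 4 columns", call. = FALSE)
  steps <- data.frame(
    chrom = dt[[1L]],
    start = suppressWarnings(as.numeric(dt[[2L]])),
    end = suppressWarnings(as.numeric(dt[[3L]])),
    value = suppressWarnings(as.numeric(dt[[4L]])),
    stringsAsFactors = FALSE
  )
  if (anyNA(steps$start) || anyNA(steps$end) || anyNA(steps$value)) {
    bad <- which(is.na(steps$start) | is.na(steps$end) | is.na(steps$value))[1L]
    stop("Bedgraph format error at line ", lineno[bad],
         ": non-numeric field", call. = FALSE)
  }
  validate_steps(steps, lineno = lineno)
  keep <- steps$value != 0
  coverage_track(steps[keep, , drop = FALSE], label = label,
                 total_mapped_reads = total_mapped_reads)
}

#' Write a coverage track as Bedgraph
#'
#' Adjacent equal-valued steps are merged (they are stored merged);
#' zero runs are omitted since Bedgraph treats gaps as zero.  Values are
#' printed with the shortest representation that round-trips at double
#' precision, so `read_bedgraph(write_bedgraph(x))` reproduces every
#' per-base value exactly.
#'
#' @param track A `"coverage_track"`.
#' @param path Output path (`.gz` suffix writes gzip).
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  pieces <- lapply(names(track$cov), function(ch) {
    r <- track$cov[[ch]]
    v <- as.numeric(S4Vectors::runValue(r))
    l <- as.numeric(S4Vectors::runLength(r))
    e <- cumsum(l)
    s <- e - l
    keep <- v != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = ch, start = s[keep], end = e[keep],
                           value = fmt_double(v[keep]))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- if (length(pieces)) data.table::rbindlist(pieces) else
    data.table::data.table(chrom = character(), start = numeric(),
                           end = numeric(), value = character())
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

fmt_double <- function(v) {
  s <- sprintf("%.15g", v)
  bad <- as.numeric(s) != v
  if (any(bad)) s[bad] <- sprintf("%.17g", v[bad])
  s
}

#' Query per-base coverage over an interval
#'
#' Returns the per-base values and their mean for a 0-based half-open
#' interval.  Positions outside any recorded step (including beyond the
#' track or, with a warning, on a chromosome the track does not know)
#' are zero.
#'
#' @param track A `"coverage_track"`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval, `end > start`.
#' @return List with `values` (numeric, length `end - start`), `mean`,
#'   and `unknown_chrom` flag.
#' @export
track_query <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"), end > start)
  r <- track$cov[[chrom]]
  n <- as.integer(end - start)
  if (is.null(r)) {
    warning("chromosome '", chrom, "' not present in track '",
            track$label, "'; returning zeros", call. = FALSE)
    return(list(values = numeric(n), mean = 0, unknown_chrom = TRUE))
  }
  values <- window_rle(r, start, end)
  list(values = values, mean = sum(values) / n, unknown_chrom = FALSE)
}

# per-base values of rle over 0-based half-open [start, end), zero-padded
window_rle <- function(r, start, end) {
  len <- length(r)
  lo <- max(start, 0)
  hi <- min(end, len)
  if (hi <= lo) return(numeric(end - start))
  mid <- as.numeric(S4Vectors::window(r, start = lo + 1L, end = hi))
  c(numeric(lo - start), mid, numeric(end - hi))
}

#' Mean coverage over many intervals
#'
#' Vectorised companion to [track_query()]: per-interval mean per-base
#' coverage (intervals outside the track contribute zeros).
#'
#' @param track A `"coverage_track"`.
#' @param chrom,start,end Parallel vectors of 0-based half-open intervals.
#' @return Numeric vector of means.
#' @export
track_means <- function(track, chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            all(end > start))
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    r <- track$cov[[ch]]
    if (is.null(r)) next
    cs <- c(0, cumsum(as.numeric(r)))
    len <- length(r)
    lo <- pmin(pmax(start[i], 0), len)
    hi <- pmin(pmax(end[i], 0), len)
    out[i] <- (cs[hi + 1L] - cs[lo + 1L]) / (end[i] - start[i])
  }
  out
}

#' Track totals and per-million scaling
#'
#' `total_signal` is the sum of value x length over all steps.  The
#' per-million normaliser is the track's declared mapped-read count when
#' available; otherwise it is approximated by `total_signal /
#' read_length_bp` (mode `"reads"`) or taken as the total mapped bases
#' (mode `"bases"`).
#'
#' @param track A `"coverage_track"`.
#' @param read_length_bp Read length for the reads-from-signal proxy.
#' @param mode `"reads"` (default) or `"bases"`.
#' @return List of class `"track_summary"` with `total_signal`,
#'   `normaliser`, `scale_per_million`, `mode`, `label`.
#' @export
track_total <- function(track, read_length_bp = 50L,
                        mode = c("reads", "bases")) {
  stopifnot(inherits(track, "coverage_track"))
  mode <- match.arg(mode)
  total <- sum(vapply(track$cov, function(r)
    sum(as.numeric(S4Vectors::runValue(r)) * as.numeric(S4Vectors::runLength(r))),
    numeric(1)))
  normaliser <- if (!is.null(track$total_mapped_reads)) {
    as.numeric(track$total_mapped_reads)
  } else if (mode == "reads") {
    total / read_length_bp
  } else {
    total
  }
  structure(list(
    total_signal = total,
    normaliser = normaliser,
    scale_per_million = if (normaliser > 0) 1e6 / normaliser else NA_real_,
    mode = mode, label = track$label
  ), class = "track_summary")
}

#' @export
print.track_summary <- function(x, ...) {
  cat("Track summary '", x$label, "': total signal ", format(x$total_signal),
      ", normaliser ", format(x$normaliser), " (", x$mode, "), scale/1e6 ",
      format(x$scale_per_million), "\n", sep = "")
  invisible(x)
}

#' Scale all step values of a track by a constant
#'
#' @param track A `"coverage_track"`.
#' @param factor Non-negative multiplier.
#' @return A new `"coverage_track"`; a declared read count is scaled too.
#' @export
scale_track <- function(track, factor) {
  stopifnot(inherits(track, "coverage_track"), factor >= 0)
  track$cov <- lapply(track$cov, function(r) r * factor)
  if (!is.null(track$total_mapped_reads))
    track$total_mapped_reads <- track$total_mapped_reads * factor
  track
}

# internal: build a track from a per-base numeric vector on one chromosome
track_from_vector <- function(values, chrom, label = "track",
                              total_mapped_reads = NULL) {
  structure(list(cov = stats::setNames(list(S4Vectors::Rle(values)), chrom),
                 label = label, total_mapped_reads = total_mapped_reads),
            class = "coverage_track")
}
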
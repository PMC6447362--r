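#' Simulation parameters with ground truth
#'
#' Defines the generative model for a synthetic chromosome: gene
#' structures (exon counts and log-uniform exon/intron lengths), gene
#' expression spanning the inactive/active/high RPKM classes
#' (log10-normal), an input library of uniformly started fragments, and
#' ChIP libraries built from the same fragment-pileup background with a
#' multiplicative occupancy field -- an exon multiplier `f_exon` for a
#' UPF1-like track, a Gaussian TSS bump for a Ser2 Pol II-like track.
#' Every draw is fixed by `seed`.
#'
#' Defaults model a compact Drosophila-like locus set: 1--8 exons per
#' gene, exons log-uniform 100--1500 bp, introns log-uniform 60--5000
#' bp, intergenic gaps 2--6 kb (guaranteeing the default 1 kb isolation
#' with 500 bp flanks), 200 bp chromatin fragments, and sequencing
#' depths giving tens-fold mean coverage so per-feature ratio estimates
#' are stable.
#'
#' @param seed Integer seed; annotation uses `seed`, tracks `seed + 1`,
#'   reads `seed + 2`.
#' @param n_genes Number of genes.
#' @param chrom Chromosome name of the synthetic contig.
#' @param chrom_bp Optional fixed chromosome length; errors when the
#'   generated genes do not fit.  `NULL` grows the contig as needed.
#' @param exon_count_range Inclusive integer range of exons per gene.
#' @param exon_bp_range,intron_bp_range,gap_bp_range Log-uniform length
#'   ranges (bp) for exons, introns and intergenic gaps.
#' @param expression_log10_mean,expression_log10_sd Parameters of the
#'   log10-normal true-RPKM distribution (defaults span RPKM < 1 to
#'   > 5).
#' @param input_rate Fragment-start rate per base of the input library.
#' @param chip_background_rate Fragment-start rate per base outside and
#'   inside genes for ChIP libraries (background component).
#' @param chip_rate_per_rpkm Additional per-base fragment-start rate per
#'   unit of true RPKM inside a gene span.
#' @param f_exon Multiplicative exon occupancy of the UPF1-like track
#'   (introns have multiplier 1).
#' @param tss_peak_height,tss_peak_sd Height (above 1) and Gaussian sd
#'   (bp) of the TSS occupancy bump of the Pol II-like track.
#' @param fragment_bp Chromatin fragment length (bp).
#' @param read_bp RNA-seq read length (bp).
#' @param rna_total_mapped Declared mapped-read total of the notional
#'   full RNA-seq library; gene counts are Poisson with mean
#'   `rpkm * exonic_length * rna_total_mapped / 1e9`, so measured RPKM
#'   recovers the truth.
#' @return List of class `"simulation_spec"`.
#' @export
simulation_spec <- function(seed = 1L, n_genes = 500L, chrom = "chrS",
                            chrom_bp = NULL,
                            exon_count_range = c(1L, 8L),
                            exon_bp_range = c(100, 1500),
                            intron_bp_range = c(60, 5000),
                            gap_bp_range = c(2000, 6000),
                            expression_log10_mean = 0.3,
                            expression_log10_sd = 0.6,
                            input_rate = 0.05,
                            chip_background_rate = 0.01,
                            chip_rate_per_rpkm = 0.04,
                            f_exon = 3,
                            tss_peak_height = 4,
                            tss_peak_sd = 150,
                            fragment_bp = 200L,
                            read_bp = 50L,
                            rna_total_mapped = 1e7) {
  spec <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes), chrom = chrom,
    chrom_bp = chrom_bp,
    exon_count_range = as.integer(exon_count_range),
    exon_bp_range = as.numeric(exon_bp_range),
    intron_bp_range = as.numeric(intron_bp_range),
    gap_bp_range = as.numeric(gap_bp_range),
    expression_log10_mean = expression_log10_mean,
    expression_log10_sd = expression_log10_sd,
    input_rate = input_rate,
    chip_background_rate = chip_background_rate,
    chip_rate_per_rpkm = chip_rate_per_rpkm,
    f_exon = f_exon,
    tss_peak_height = tss_peak_height,
    tss_peak_sd = tss_peak_sd,
    fragment_bp = as.integer(fragment_bp),
    read_bp = as.integer(read_bp),
    rna_total_mapped = rna_total_mapped
  )
  stopifnot(
    spec$n_genes >= 0L, spec$fragment_bp >= 1L, spec$read_bp >= 1L,
    all(spec$exon_count_range >= 1L), diff(spec$exon_count_range) >= 0,
    all(spec$exon_bp_range > 0), all(spec$intron_bp_range > 0),
    all(spec$gap_bp_range > 0),
    spec$input_rate >= 0, spec$chip_background_rate >= 0,
    spec$chip_rate_per_rpkm >= 0, spec$f_exon > 0,
    spec$tss_peak_height >= 0, spec$tss_peak_sd > 0,
    spec$rna_total_mapped > 0
  )
  class(spec) <- "simulation_spec"
  spec
}

rloguniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Simulate a refGene-like annotation
#'
#' Draws `n_genes` non-overlapping gene models on one chromosome,
#' alternating strands, with exon counts, exon/intron lengths and
#' intergenic gaps from the spec's distributions.  Deterministic given
#' the seed.  Also draws each gene's true expression (RPKM).
#'
#' @param spec A [simulation_spec()].
#' @return A `"gene_models"` data.frame with extra attributes
#'   `true_rpkm` (named numeric) and `chrom_bp` (contig length used).
#' @export
simulate_annotation <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    if (n == 0L) {
      gm <- empty_gene_models()
      attr(gm, "true_rpkm") <- stats::setNames(numeric(0), character(0))
      attr(gm, "chrom_bp") <- spec$chrom_bp %||% 0L
      return(gm)
    }
    n_ex <- sample(seq(spec$exon_count_range[1], spec$exon_count_range[2]),
                   n, replace = TRUE)
    name <- sprintf("tx%04d", seq_len(n))
    name2 <- sprintf("gene%04d", seq_len(n))
    strand <- rep(c("+", "-"), length.out = n)
    exon_starts <- vector("list", n)
    exon_ends <- vector("list", n)
    start <- integer(n); end <- integer(n)
    pos <- 0
    for (i in seq_len(n)) {
      gap <- round(rloguniform(1, spec$gap_bp_range))
      ex_len <- round(rloguniform(n_ex[i], spec$exon_bp_range))
      in_len <- if (n_ex[i] > 1L) round(rloguniform(n_ex[i] - 1L, spec$intron_bp_range)) else numeric(0)
      s <- pos + gap
      es <- s + cumsum(c(0, ex_len[-n_ex[i]] + in_len))
      ee <- es + ex_len
      exon_starts[[i]] <- as.integer(es)
      exon_ends[[i]] <- as.integer(ee)
      start[i] <- as.integer(s)
      end[i] <- as.integer(ee[n_ex[i]])
      pos <- end[i]
    }
    final_gap <- round(rloguniform(1, spec$gap_bp_range))
    needed <- pos + final_gap
    chrom_bp <- if (is.null(spec$chrom_bp)) needed else spec$chrom_bp
    if (chrom_bp < needed)
      stop("chromosome length ", chrom_bp, " too short for ", n,
           " genes (need ", needed, " bp)", call. = FALSE)
    rpkm_true <- 10^stats::rnorm(n, spec$expression_log10_mean,
                                 spec$expression_log10_sd)
    gm <- data.frame(
      name = name, name2 = name2, chrom = spec$chrom, strand = strand,
      start = start, end = end, n_exons = as.integer(n_ex),
      stringsAsFactors = FALSE
    )
    gm$exon_starts <- exon_starts
    gm$exon_ends <- exon_ends
    class(gm) <- c("gene_models", "data.frame")
    attr(gm, "true_rpkm") <- stats::setNames(rpkm_true, name)
    attr(gm, "chrom_bp") <- as.integer(chrom_bp)
    gm
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate matched ChIP, input and RNA-seq data
#'
#' Coverage tracks are built by fragment pileup: per-base fragment-start
#' counts are Poisson with rate `chip_background_rate +
#' chip_rate_per_rpkm * rpkm` inside gene spans (`input_rate` uniform
#' for the input), each start contributing a `fragment_bp`-long unit of
#' coverage.  The pileup is then multiplied by a per-base occupancy
#' field: `f_exon` on exons (UPF1-like track), a `1 + h *
#' exp(-(x - TSS)^2 / (2 sd^2))` bump at each TSS (Pol II-like track),
#' and 1 everywhere for the input, whose total signal therefore equals
#' fragment count x fragment length exactly.  Modelling occupancy as a
#' multiplicative field on the sampled chromatin background keeps the
#' exon multiplier identifiable from per-feature coverage ratios at any
#' fragment length, which is what the parameter-recovery tests exploit.
#' RNA-seq reads are placed uniformly within exons with per-gene Poisson
#' counts matching the true RPKM at the declared library size.
#'
#' @param spec A [simulation_spec()].
#' @param genes Annotation from [simulate_annotation()] (attributes
#'   `true_rpkm` and `chrom_bp` required).
#' @return List with `"coverage_track"`s `chip_upf1`, `chip_pol2`,
#'   `input` (each declaring its fragment count as mapped reads),
#'   `rna_reads` (BED-style data.frame), and `truth` (list: per-gene
#'   `rpkm`, `f_exon`, TSS parameters, fragment counts, declared RNA
#'   library size).
#' @export
simulate_tracks <- function(spec, genes) {
  stopifnot(inherits(spec, "simulation_spec"))
  rpkm_true <- attr(genes, "true_rpkm")
  chrom_bp <- attr(genes, "chrom_bp")
  if (is.null(rpkm_true) || is.null(chrom_bp))
    stop("genes must come from simulate_annotation()", call. = FALSE)
  d <- spec$fragment_bp
  L <- as.integer(chrom_bp)

  with_seed(spec$seed + 1L, {
    # per-base fragment-start rates; the expression component covers every
    # start whose fragment overlaps the gene span, so pileup coverage is
    # stationary across the whole transcription unit (no 5' ramp artefact)
    chip_rate <- rep(spec$chip_background_rate, L)
    for (i in seq_len(nrow(genes))) {
      ix <- max(1L, genes$start[i] - d + 2L):genes$end[i]
      chip_rate[ix] <- chip_rate[ix] + spec$chip_rate_per_rpkm * rpkm_true[i]
    }

    # multiplicative occupancy fields
    m_upf1 <- rep(1, L)
    for (i in seq_len(nrow(genes))) {
      es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
      for (j in seq_along(es)) m_upf1[(es[j] + 1L):ee[j]] <- spec$f_exon
    }
    m_pol2 <- rep(1, L)
    w <- 4 * spec$tss_peak_sd
    for (i in seq_len(nrow(genes))) {
      tss <- if (genes$strand[i] == "-") genes$end[i] - 1L else genes$start[i]
      ix <- max(1L, tss - w):min(L, tss + w)
      m_pol2[ix] <- m_pol2[ix] +
        spec$tss_peak_height * exp(-((ix - 1L) - tss)^2 / (2 * spec$tss_peak_sd^2))
    }

    pileup <- function(rate) {
      k <- stats::rpois(L, rate)
      cs <- cumsum(as.numeric(k))
      # coverage at x = starts within (x - d, x]; runs d - 1 past the end
      full <- c(cs, rep(cs[L], d - 1L))
      cov <- full - c(numeric(d), full[seq_len(L + d - 1L - d)])
      list(cov = cov, n_fragments = sum(k))
    }
    p_in <- pileup(rep(spec$input_rate, L))
    p_u <- pileup(chip_rate)
    p_p <- pileup(chip_rate)

    pad <- function(m) c(m, rep(1, d - 1L))
    input <- track_from_vector(p_in$cov, spec$chrom, "input",
                               total_mapped_reads = p_in$n_fragments)
    chip_upf1 <- track_from_vector(p_u$cov * pad(m_upf1), spec$chrom, "chip_upf1",
                                   total_mapped_reads = p_u$n_fragments)
    chip_pol2 <- track_from_vector(p_p$cov * pad(m_pol2), spec$chrom, "chip_pol2",
                                   total_mapped_reads = p_p$n_fragments)

    rna_reads <- simulate_rna_reads(spec, genes, rpkm_true)

    list(
      chip_upf1 = chip_upf1, chip_pol2 = chip_pol2, input = input,
      rna_reads = rna_reads,
      truth = list(
        rpkm = rpkm_true, f_exon = spec$f_exon,
        tss_peak_height = spec$tss_peak_height,
        tss_peak_sd = spec$tss_peak_sd,
        n_fragments = c(input = p_in$n_fragments, chip_upf1 = p_u$n_fragments,
                        chip_pol2 = p_p$n_fragments),
        fragment_bp = d,
        rna_total_mapped = spec$rna_total_mapped,
        seed = spec$seed
      )
    )
  })
}

simulate_rna_reads <- function(spec, genes, rpkm_true) {
  with_seed(spec$seed + 2L, {
    rows <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
      ex_len <- ee - es
      len <- sum(ex_len)
      n <- stats::rpois(1, rpkm_true[i] * len * spec$rna_total_mapped / 1e9)
      if (n == 0L) next
      ex <- sample.int(length(es), n, replace = TRUE, prob = ex_len)
      rl <- pmin(spec$read_bp, ex_len[ex])
      off <- floor(stats::runif(n) * (ex_len[ex] - rl + 1L))
      rows[[i]] <- data.frame(
        chrom = genes$chrom[i],
        start = as.integer(es[ex] + off),
        end = as.integer(es[ex] + off + rl),
        name = sprintf("%s_r%05d", genes$name[i], seq_len(n)),
        score = 0L,
        strand = genes$strand[i],
        stringsAsFactors = FALSE
      )
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(), score = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete dataset
#'
#' Annotation plus tracks/reads/ground truth in one call.
#'
#' @param spec A [simulation_spec()].
#' @return List: `genes`, plus everything [simulate_tracks()] returns.
#' @export
simulate_dataset <- function(spec) {
  genes <- simulate_annotation(spec)
  c(list(genes = genes), simulate_tracks(spec, genes))
}

#' Write a simulated dataset to files
#'
#' Emits the refGene-style annotation, Bedgraph tracks, BED reads and a
#' ground-truth JSON (with the seed echoed for provenance) into a
#' directory.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.refgene.tsv"),
    chip_upf1 = file.path(dir, "chip_upf1.bedgraph"),
    chip_pol2 = file.path(dir, "chip_pol2.bedgraph"),
    input = file.path(dir, "input.bedgraph"),
    rna_reads = file.path(dir, "rna_reads.bed"),
    truth = file.path(dir, "truth.json")
  )
  write_refgene(sim$genes, paths["annotation"])
  write_bedgraph(sim$chip_upf1, paths["chip_upf1"])
  write_bedgraph(sim$chip_pol2, paths["chip_pol2"])
  write_bedgraph(sim$input, paths["input"])
  utils::write.table(sim$rna_reads, paths["rna_reads"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- sim$truth
  truth$rpkm <- as.list(truth$rpkm)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}
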
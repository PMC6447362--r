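#' Read a pipeline run configuration
#'
#' YAML with top-level keys: `seed`, `output_dir`, `params` (overrides
#' for [analysis_params()]), and either `simulation:` (overrides for
#' [simulation_spec()]; presence enables simulation) or explicit input
#' paths `annotation`, `chip`, `input`, `pol2` (optional), `reads`
#' (optional).  Optional `total_mapped:` (named: chip/input/pol2/reads)
#' declares library sizes for per-million scaling.
#'
#' @param path YAML file path.
#' @return Config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.null(cfg$output_dir)) stop("config error: output_dir missing", call. = FALSE)
  sim_on <- !is.null(cfg$simulation)
  if (!sim_on) {
    for (k in c("annotation", "chip", "input")) {
      if (is.null(cfg[[k]]))
        stop("config error: '", k,
             "' path required when simulation is disabled", call. = FALSE)
      if (!file.exists(cfg[[k]]))
        stop("config error: file not found: ", cfg[[k]], call. = FALSE)
    }
    for (k in c("pol2", "reads")) {
      if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
        stop("config error: file not found: ", cfg[[k]], call. = FALSE)
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: (1) simulate or load inputs; (2) filter
#' gene models (duplicate names, isolation); (3) derive introns and
#' exon/intron/exon triplets; (4) expression table and RPKM classes
#' (when reads are available); (5) metagene profiles stratified by
#' activity class, for ChIP and input tracks; (6) triplet enrichment,
#' rank-sum summary, percent-length profiles and (when a second ChIP
#' track exists) exon correlation.  Outputs are TSV tables plus a
#' `summary.json` and a `manifest.json`; both are free of timestamps so
#' identical configs yield identical bytes.  On stage failure, partial
#' outputs are removed and the error is re-thrown with a stage label.
#'
#' @param config A `"run_config"` (from [read_run_config()]) or a list
#'   with the same fields.
#' @return The run manifest (list), invisibly.  Side effect: files under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(unclass(config))
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  on_fail <- function(e) {
    suppressWarnings(file.remove(written[file.exists(written)]))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  tryCatch({
    params <- as_analysis_params(cfg$params)

    stage <- "inputs"
    if (!is.null(cfg$simulation)) {
      sim_args <- cfg$simulation
      sim_args$seed <- sim_args$seed %||% cfg$seed
      spec <- do.call(simulation_spec, sim_args)
      sim <- simulate_dataset(spec)
      genes <- sim$genes
      chip <- sim$chip_upf1
      input <- sim$input
      pol2 <- sim$chip_pol2
      reads <- sim$rna_reads
      total_reads <- spec$rna_total_mapped
    } else {
      genes <- read_refgene(cfg$annotation)
      tm <- cfg$total_mapped %||% list()
      chip <- read_bedgraph(cfg$chip, label = "chip",
                            total_mapped_reads = tm$chip)
      input <- read_bedgraph(cfg$input, label = "input",
                             total_mapped_reads = tm$input)
      pol2 <- if (!is.null(cfg$pol2))
        read_bedgraph(cfg$pol2, label = "pol2", total_mapped_reads = tm$pol2)
      reads <- if (!is.null(cfg$reads)) read_bed_reads(cfg$reads)
      total_reads <- tm$reads
    }

    stage <- "filter_genes"
    kept <- filter_genes(genes, params)

    stage <- "derive_features"
    feats <- derive_features(kept, params)

    stage <- "expression"
    expr <- NULL
    if (!is.null(reads) && nrow(reads) > 0L) {
      expr <- expression_table(reads, kept, params, total_mapped = total_reads)
      emit("rpkm.tsv", function(p) utils::write.table(
        expr, p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    stage <- "metagene"
    strata <- if (!is.null(expr)) as.character(expr$activity_class) else NULL
    mg_chip <- metagene(chip, kept, params, strata = strata)
    mg_input <- metagene(input, kept, params, strata = strata)
    emit("metagene_chip.tsv", function(p) write_metagene(mg_chip, p, params))
    emit("metagene_input.tsv", function(p) write_metagene(mg_input, p, params))
    mg_pol2 <- NULL
    if (!is.null(pol2)) {
      mg_pol2 <- metagene(pol2, kept, params, strata = strata)
      emit("metagene_pol2.tsv", function(p) write_metagene(mg_pol2, p, params))
    }

    stage <- "enrichment"
    enr <- NULL; summ <- NULL; pct_ex <- NULL; pct_in <- NULL
    if (nrow(feats$triplets) >= 2L) {
      enr <- triplet_enrichment(chip, input, feats$triplets, params)
      emit("enrichment.tsv", function(p) utils::write.table(
        enr, p, sep = "\t", quote = FALSE, row.names = FALSE))
      summ <- exon_vs_intron_summary(enr)
      exon_feats <- data.frame(
        chrom = c(feats$triplets$chrom, feats$triplets$chrom),
        start = c(feats$triplets$left_start, feats$triplets$right_start),
        end = c(feats$triplets$left_end, feats$triplets$right_end),
        strand = c(feats$triplets$strand, feats$triplets$strand),
        stringsAsFactors = FALSE)
      pct_ex <- percent_length_profile(chip, input, exon_feats, params)
      intron_feats <- feats$triplets[, c("chrom", "intron_start", "intron_end", "strand")]
      names(intron_feats) <- c("chrom", "start", "end", "strand")
      pct_in <- percent_length_profile(chip, input, intron_feats, params)
      emit("percent_profile.tsv", function(p) utils::write.table(
        data.frame(percent = 1:100, exon_mean = pct_ex$profile,
                   intron_mean = pct_in$profile),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    stage <- "correlation"
    corr <- NULL
    if (!is.null(pol2) && nrow(kept) >= 3L) {
      corr <- exon_correlation(chip, pol2, kept, params)
      emit("exon_correlation.tsv", function(p) utils::write.table(
        corr$table, p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    stage <- "report"
    summary <- list(
      seed = cfg$seed,
      n_genes_in = nrow(genes),
      n_genes_kept = nrow(kept),
      n_introns = nrow(feats$introns),
      n_triplets = nrow(feats$triplets),
      normalisers = list(
        chip = track_total(chip, params$read_length_bp)$normaliser,
        input = track_total(input, params$read_length_bp)$normaliser
      ),
      expression = if (!is.null(expr)) as.list(table(expr$activity_class)),
      enrichment = if (!is.null(summ)) list(
        n_records = summ$n_records,
        n_dropped_zero_input = attr(enr, "n_dropped"),
        median_ratio_left = summ$median_ratio_left,
        median_ratio_right = summ$median_ratio_right,
        p_left_vs_intron = summ$tests$left_vs_intron$p_value,
        p_right_vs_intron = summ$tests$right_vs_intron$p_value,
        p_left_vs_right = summ$tests$left_vs_right$p_value,
        U_left_vs_intron = summ$tests$left_vs_intron$U,
        exon_gt_intron_significant =
          summ$tests$left_vs_intron$p_value < 0.001 &&
          summ$tests$right_vs_intron$p_value < 0.001 &&
          summ$median_ratio_left > 1 && summ$median_ratio_right > 1
      ),
      correlation = if (!is.null(corr)) list(
        pearson_log10 = corr$pearson_log10, spearman = corr$spearman,
        n_exons = corr$n_exons)
    )
    summary_path <- emit("summary.json", function(p)
      jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                           null = "null"))

    manifest <- list(
      package_version = as.character(utils::packageVersion("cotx")),
      seed = cfg$seed,
      params = unclass(params),
      simulation = cfg$simulation,
      inputs = cfg[intersect(names(cfg), c("annotation", "chip", "input",
                                           "pol2", "reads"))],
      normalisers = summary$normalisers,
      outputs = basename(written),
      summary_md5 = unname(tools::md5sum(summary_path))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(manifest)
  }, error = on_fail)
}
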
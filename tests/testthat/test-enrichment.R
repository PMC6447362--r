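triplet_df <- function(chrom = "chr1", left = c(100L, 300L), intron = c(300L, 600L),
                       right = c(600L, 800L), gene = "g1", strand = "+") {
  data.frame(gene = gene, chrom = chrom,
             left_start = left[1], left_end = left[2],
             intron_start = intron[1], intron_end = intron[2],
             right_start = right[1], right_end = right[2],
             strand = strand, stringsAsFactors = FALSE)
}

uniform_track <- function(value, end = 10000L, chrom = "chr1", reads = 1e6) {
  coverage_track(data.frame(chrom = chrom, start = 0L, end = end, value = value),
                 total_mapped_reads = reads)
}

test_that("triplet enrichment normalises chip by input per feature", {
  trip <- triplet_df()
  # equal declared depths: per-million scales cancel
  enr <- triplet_enrichment(uniform_track(4), uniform_track(2), trip)
  expect_equal(enr$left_norm, 2)
  expect_equal(enr$intron_norm, 2)
  expect_equal(enr$right_norm, 2)
  expect_equal(enr$log2fc_left, 0)
  expect_equal(enr$log2fc_right, 0)

  # exon 6 / intron 2 / exon 6 over input 2 -> (3, 1, 3), log2FC = log2(3)
  chip <- coverage_track(data.frame(
    chrom = "chr1", start = c(100L, 300L, 600L), end = c(300L, 600L, 800L),
    value = c(6, 2, 6)), total_mapped_reads = 1e6)
  enr2 <- triplet_enrichment(chip, uniform_track(2), trip)
  expect_equal(enr2$left_norm, 3)
  expect_equal(enr2$intron_norm, 1)
  expect_equal(enr2$log2fc_left, log2(3))
  expect_equal(enr2$log2fc_right, log2(3))
})

test_that("zero input on any feature drops the record and is counted", {
  trip <- rbind(triplet_df(gene = "g1"),
                triplet_df(gene = "g2", left = c(2000L, 2200L),
                           intron = c(2200L, 2500L), right = c(2500L, 2700L)))
  # input covers only g1's region
  input <- coverage_track(data.frame(chrom = "chr1", start = 0L, end = 1000L,
                                     value = 2), total_mapped_reads = 1e6)
  enr <- triplet_enrichment(uniform_track(4), input, trip)
  expect_equal(nrow(enr), 1L)
  expect_equal(enr$gene, "g1")
  expect_equal(attr(enr, "n_dropped"), 1L)
  # pseudocount mode retains everything
  enr_pc <- triplet_enrichment(uniform_track(4), input, trip,
                               zero_input = "pseudocount")
  expect_equal(nrow(enr_pc), 2L)
  expect_error(triplet_enrichment(uniform_track(4), input, trip[0, ]), "empty")
})

test_that("joint library rescaling leaves normalised values and p-values unchanged", {
  set.seed(41)
  steps <- random_steps(n_steps = 10, span = 900L)
  chip <- coverage_track(steps, total_mapped_reads = 1e6)
  input <- uniform_track(2, end = 900L)
  trip <- rbind(triplet_df(), triplet_df(gene = "g2", left = c(30L, 90L),
                                         intron = c(90L, 300L), right = c(300L, 420L)))
  base <- triplet_enrichment(chip, input, trip)
  scaled <- triplet_enrichment(scale_track(chip, 7), scale_track(input, 7), trip)
  expect_equal(scaled$left_norm, base$left_norm)
  expect_equal(scaled$intron_norm, base$intron_norm)
  s1 <- exon_vs_intron_summary(base); s2 <- exon_vs_intron_summary(scaled)
  expect_equal(s2$tests$left_vs_intron$p_value, s1$tests$left_vs_intron$p_value)
})

test_that("summary tests and box statistics follow their stated rules", {
  # identical exon and intron values: all p = 1
  trip <- triplet_df()
  enr <- triplet_enrichment(uniform_track(4), uniform_track(2), trip)
  enr <- rbind(enr, enr)
  class(enr) <- c("enrichment_table", "data.frame")
  s <- exon_vs_intron_summary(enr)
  expect_equal(s$tests$left_vs_intron$p_value, 1)
  expect_equal(s$tests$left_vs_right$p_value, 1)

  # type-7 quartiles of {1,2,3,4}
  bs <- cotx:::box_stats(c(1, 2, 3, 4))
  expect_equal(bs$q1, 1.75)
  expect_equal(bs$median, 2.5)
  expect_equal(bs$q3, 3.25)
  expect_equal(bs$whisker_low, 1)   # all points inside the 1.5 IQR fences
  expect_equal(bs$whisker_high, 4)
  bs2 <- cotx:::box_stats(c(1, 2, 3, 4, 100))
  expect_equal(bs2$n_outliers, 1L)
  expect_equal(bs2$whisker_high, 4)

  expect_error(exon_vs_intron_summary(enr[1, ]), "at least 2")
})

test_that("stochastically larger exons give the designed significance pattern", {
  set.seed(42)
  n <- 80
  enr <- data.frame(
    left_norm = rlnorm(n, log(2), 0.3),
    intron_norm = rlnorm(n, log(1), 0.3),
    right_norm = rlnorm(n, log(2), 0.3)
  )
  class(enr) <- c("enrichment_table", "data.frame")
  s <- exon_vs_intron_summary(enr)
  expect_lt(s$tests$left_vs_intron$p_value, 1e-6)
  expect_lt(s$tests$right_vs_intron$p_value, 1e-6)
  expect_gt(s$tests$left_vs_right$p_value, 0.01)
  expect_lt(s$tests$left_vs_intron$p_value, s$tests$left_vs_right$p_value)
})

test_that("percent-length profiles resample ratios onto 100 points", {
  feat <- data.frame(chrom = "chr1", start = 100L, end = 300L, strand = "+")
  pp <- percent_length_profile(uniform_track(6), uniform_track(2), feat)
  expect_length(pp$profile, 100L)
  expect_equal(pp$profile, rep(3, 100))

  # linear ramp over 200 bp: strictly increasing resampled profile
  ramp <- coverage_track(data.frame(chrom = "chr1", start = 100:299,
                                    end = 101:300, value = 1:200),
                         total_mapped_reads = 1e6)
  pr <- percent_length_profile(ramp, uniform_track(1), feat)
  expect_true(all(diff(pr$profile) > 0))
  # brute-force oracle: mean of the two bases in each percent bin (both
  # tracks declare 1e6 reads, so per-million scales are 1)
  expect_equal(pr$profile, colMeans(matrix(1:200, nrow = 2)))

  # minus-strand feature of the mirrored track gives the identical profile
  m_feat <- data.frame(chrom = "chr1", start = 700L, end = 900L, strand = "-")
  m_ramp <- coverage_track(data.frame(chrom = "chr1", start = 700:899,
                                      end = 701:900, value = 200:1),
                           total_mapped_reads = 1e6)
  pm <- percent_length_profile(m_ramp, uniform_track(1), m_feat)
  expect_equal(pm$profile, pr$profile)

  # short feature: each of its 40 bases lands in its nearest percent bin;
  # bins no base reaches stay undefined for a single feature
  short <- data.frame(chrom = "chr1", start = 100L, end = 140L, strand = "+")
  ps <- percent_length_profile(uniform_track(6), uniform_track(2), short)
  expect_equal(sum(is.finite(ps$profile)), 40L)
  expect_equal(unique(ps$profile[is.finite(ps$profile)]), 3)
  expect_error(percent_length_profile(uniform_track(1), uniform_track(1),
                                      feat[0, ]), "empty")
})

test_that("exon correlation is 1 for proportional tracks, -1 Spearman when reversed", {
  set.seed(43)
  steps <- random_steps(n_steps = 10, span = 5000L)
  steps$value <- steps$value + 1  # ensure nonzero
  a <- coverage_track(steps, total_mapped_reads = 1e6)
  b <- scale_track(a, 2)
  genes <- genes_rbind(
    one_gene("g1", exon_starts = c(0L, 1000L), exon_ends = c(500L, 1500L)),
    one_gene("g2", exon_starts = 2000L, exon_ends = 2600L),
    one_gene("g3", exon_starts = c(3000L, 4000L), exon_ends = c(3500L, 4800L))
  )
  cc <- exon_correlation(a, b, genes)
  expect_equal(cc$spearman, 1)
  expect_equal(cc$n_exons, 5L)
  # equal per-million depth declared: scaled values identical => Pearson 1
  expect_equal(cc$pearson_log10, 1)

  # anti-monotone pairing
  ex_means <- cc$table$a
  flip <- coverage_track(data.frame(chrom = "chr1", start = cc$table$start,
                                    end = cc$table$end,
                                    value = max(ex_means) + 1 - ex_means),
                         total_mapped_reads = 1e6)
  cc2 <- exon_correlation(a, flip, genes)
  expect_equal(cc2$spearman, -1)

  # degenerate constant vector reported as such
  const <- uniform_track(2, end = 5000L)
  cc3 <- exon_correlation(const, a, genes)
  expect_true(cc3$degenerate)
  expect_true(is.na(cc3$pearson_log10))
})
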
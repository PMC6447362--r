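refgene_line <- function(name = "t1", chrom = "chr1", strand = "+",
                         txStart = 100, txEnd = 1100, exonCount = 2,
                         starts = "100,600,", ends = "300,1100,",
                         name2 = "g1", bin = NULL) {
  fields <- c(bin, name, chrom, strand, txStart, txEnd, txStart, txEnd,
              exonCount, starts, ends, 0, name2, "none", "none", "-1,-1,")
  paste(fields, collapse = "\t")
}

test_that("refGene lines map to gene models, with and without bin column", {
  for (bin in list(NULL, 585)) {
    gm <- parse_refgene(refgene_line(bin = bin))
    expect_equal(nrow(gm), 1L)
    expect_equal(gm$name, "t1")
    expect_equal(gm$name2, "g1")
    expect_equal(gm$exon_starts[[1]], c(100L, 600L))
    expect_equal(gm$exon_ends[[1]], c(300L, 1100L))
    expect_equal(gm$start, 100L)
    expect_equal(gm$end, 1100L)
  }
  expect_equal(nrow(parse_refgene(character(0))), 0L)
  expect_equal(nrow(parse_refgene(c("# comment", ""))), 0L)
})

test_that("malformed refGene rows raise parse errors naming the line", {
  bad_count <- refgene_line(exonCount = 2, starts = "100,400,600,",
                            ends = "300,500,1100,")
  expect_error(parse_refgene(c(refgene_line(), bad_count)),
               "line 2.*exonCount", ignore.case = TRUE)
  unsorted <- refgene_line(starts = "600,100,", ends = "1100,300,")
  expect_error(parse_refgene(unsorted), "line 1")
  not_flush <- refgene_line(txStart = 50)
  expect_error(parse_refgene(not_flush), "span")
})

test_that("refGene tables round-trip through write_refgene, including gzip", {
  gm <- genes_rbind(
    one_gene("t1", exon_starts = c(100L, 600L), exon_ends = c(300L, 1100L)),
    one_gene("t2", strand = "-", exon_starts = 2000L, exon_ends = 2500L)
  )
  plain <- tempfile(fileext = ".tsv")
  write_refgene(gm, plain)
  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "wt"); writeLines(readLines(plain), con); close(con)
  for (path in c(plain, gz)) {
    back <- read_refgene(path)
    expect_equal(back$name, gm$name)
    expect_equal(back$strand, gm$strand)
    expect_equal(back$exon_starts, gm$exon_starts)
    expect_equal(back$exon_ends, gm$exon_ends)
  }
})

test_that("introns are the exon gaps and triplets obey the strict length cutoff", {
  gm <- one_gene(exon_starts = c(100L, 600L), exon_ends = c(300L, 1100L))
  f <- derive_features(gm)
  expect_equal(f$introns$start, 300L)
  expect_equal(f$introns$end, 600L)
  expect_equal(nrow(f$triplets), 1L)  # length 300 > 100
  expect_equal(f$triplets$left_end, f$triplets$intron_start)
  expect_equal(f$triplets$intron_end, f$triplets$right_start)

  single <- one_gene(exon_starts = 100L, exon_ends = 300L)
  f1 <- derive_features(single)
  expect_equal(nrow(f1$introns), 0L)
  expect_equal(nrow(f1$triplets), 0L)

  # intron of exactly min_intron_bp excluded, one base longer retained
  at_cut <- one_gene(exon_starts = c(0L, 150L), exon_ends = c(50L, 400L))
  above <- one_gene(exon_starts = c(0L, 151L), exon_ends = c(50L, 400L))
  expect_equal(nrow(derive_features(at_cut)$triplets), 0L)
  expect_equal(nrow(derive_features(above)$triplets), 1L)
})

test_that("exons and introns tile the gene span exactly", {
  set.seed(31)
  for (rep in 1:20) {
    n_ex <- sample(1:6, 1)
    lens <- sample(50:400, 2 * n_ex - 1, replace = TRUE)
    pos <- 1000L + cumsum(c(0L, lens))
    es <- pos[seq(1, 2 * n_ex - 1, 2)]
    ee <- pos[seq(2, 2 * n_ex, 2) - 0]
    ee <- es + lens[seq(1, 2 * n_ex - 1, 2)]
    gm <- one_gene(exon_starts = es, exon_ends = ee,
                   strand = sample(c("+", "-"), 1))
    f <- derive_features(gm, analysis_params(min_intron_bp = 0L))
    pieces <- rbind(data.frame(s = es, e = ee),
                    data.frame(s = f$introns$start, e = f$introns$end))
    pieces <- pieces[order(pieces$s), ]
    expect_equal(pieces$s[1], gm$start)
    expect_equal(pieces$e[nrow(pieces)], gm$end)
    expect_true(all(pieces$s[-1] == pieces$e[-nrow(pieces)]))
    # idempotent and strand-independent (genomic orientation)
    expect_identical(derive_features(gm, analysis_params(min_intron_bp = 0L)), f)
  }
})

test_that("duplicate names and close neighbours are filtered, idempotently", {
  p <- analysis_params()  # flank 500, separation 1000
  dup1 <- one_gene("g1", exon_starts = 1000L, exon_ends = 2000L)
  dup2 <- one_gene("g1", exon_starts = 50000L, exon_ends = 51000L)
  far <- one_gene("g2", exon_starts = 100000L, exon_ends = 101000L)
  out <- filter_genes(genes_rbind(dup1, dup2, far), p)
  expect_equal(out$name, "g2")  # both duplicates removed

  # 10 kb apart: kept; extended spans overlapping: both removed
  a <- one_gene("a", exon_starts = 1000L, exon_ends = 2000L)
  b <- one_gene("b", exon_starts = 12000L, exon_ends = 13000L)
  expect_equal(filter_genes(genes_rbind(a, b), p)$name, c("a", "b"))
  c2 <- one_gene("c", exon_starts = 2500L, exon_ends = 3500L)  # 500bp-ext spans overlap
  expect_equal(nrow(filter_genes(genes_rbind(a, c2), p)), 0L)

  # gap between extended spans exactly min_separation is kept
  d1 <- one_gene("d1", exon_starts = 0L, exon_ends = 1000L)    # ext [, 1500)
  d2 <- one_gene("d2", exon_starts = 3000L, exon_ends = 4000L) # ext [2500, ); gap 1000
  expect_equal(filter_genes(genes_rbind(d1, d2), p)$name, c("d1", "d2"))
  d3 <- one_gene("d3", exon_starts = 2999L, exon_ends = 4000L) # gap 999
  expect_equal(nrow(filter_genes(genes_rbind(d1, d3), p)), 0L)

  # different chromosomes never conflict; output subset + idempotence
  e1 <- one_gene("e1", chrom = "chr2", exon_starts = 1000L, exon_ends = 2000L)
  e2 <- one_gene("e2", chrom = "chr3", exon_starts = 1000L, exon_ends = 2000L)
  mix <- genes_rbind(a, c2, e1, e2)
  out <- filter_genes(mix, p)
  expect_true(all(out$name %in% mix$name))
  expect_identical(filter_genes(out, p), out)
})
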
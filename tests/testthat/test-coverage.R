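test_that("bedgraph steps have per-base semantics with implicit zero gaps", {
  tr <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 10, value = 2))
  q <- track_query(tr, "chr1", 0, 10)
  expect_equal(q$values, rep(2, 10))
  expect_equal(q$mean, 2)

  tr2 <- coverage_track(data.frame(chrom = "chr1", start = c(0, 20),
                                   end = c(10, 30), value = c(2, 4)))
  expect_equal(track_query(tr2, "chr1", 0, 30)$mean, 2)  # (10*2+10*0+10*4)/30

  tr3 <- coverage_track(data.frame(chrom = "chr1", start = c(0, 4),
                                   end = c(4, 8), value = c(1, 3)))
  q3 <- track_query(tr3, "chr1", 2, 6)
  expect_equal(q3$values, c(1, 1, 3, 3))
  expect_equal(q3$mean, 2)
})

test_that("overlapping or negative steps are format errors with positions", {
  path <- tempfile(fileext = ".bedgraph")
  writeLines(c("track type=bedGraph", "chr1\t0\t10\t1", "chr1\t5\t15\t1"), path)
  expect_error(read_bedgraph(path), "line 3")
  writeLines(c("chr1\t0\t10\t-1"), path)
  expect_error(read_bedgraph(path), "negative")
  expect_error(
    coverage_track(data.frame(chrom = "chr1", start = c(0, 5),
                              end = c(10, 15), value = 1)),
    "overlap")
})

test_that("unknown chromosome queries return zeros with a warning", {
  tr <- coverage_track(data.frame(chrom = "chr2", start = 0, end = 5, value = 1))
  expect_warning(q <- track_query(tr, "chr3", 0, 4), "chr3")
  expect_equal(q$values, numeric(4))
  expect_equal(q$mean, 0)
  expect_true(q$unknown_chrom)
})

test_that("query means match the brute-force per-base oracle on random tracks", {
  set.seed(101)
  for (rep in 1:40) {
    steps <- random_steps()
    tr <- coverage_track(steps)
    for (k in 1:5) {
      b <- sort(sample.int(450, 2))
      start <- b[1] - 1L; end <- b[2]
      expect_identical(track_query(tr, "chr1", start, end)$mean,
                       brute_mean(steps, "chr1", start, end, upto = 450L))
      expect_identical(track_means(tr, "chr1", start, end),
                       brute_mean(steps, "chr1", start, end, upto = 450L))
    }
  }
})

test_that("write then read reproduces per-base values and merges equal neighbours", {
  # equal adjacent steps are emitted as one line
  tr <- coverage_track(data.frame(chrom = "chr1", start = c(0, 5),
                                  end = c(5, 10), value = c(1, 1)))
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  expect_equal(readLines(path), "chr1\t0\t10\t1")

  # empty track writes an empty file
  empty <- coverage_track(data.frame(chrom = character(), start = integer(),
                                     end = integer(), value = numeric()))
  write_bedgraph(empty, path)
  expect_length(readLines(path), 0L)

  set.seed(202)
  for (rep in 1:30) {
    steps <- random_steps()
    steps$value <- steps$value + round(runif(nrow(steps)), 3)  # non-integers too
    tr <- coverage_track(steps, label = "t")
    write_bedgraph(tr, path)
    back <- read_bedgraph(path)
    expect_identical(track_query(back, "chr1", 0, 450)$values,
                     track_query(tr, "chr1", 0, 450)$values)
  }
})

test_that("total signal is additive, split- and round-trip-invariant, and scales", {
  tr <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 10, value = 2))
  expect_equal(track_total(tr)$total_signal, 20)
  empty <- coverage_track(data.frame(chrom = character(), start = integer(),
                                     end = integer(), value = numeric()))
  expect_equal(track_total(empty)$total_signal, 0)

  set.seed(303)
  steps <- random_steps(n_steps = 6)
  tr <- coverage_track(steps)
  total <- track_total(tr)$total_signal

  # splitting a step in two leaves the total unchanged
  i <- which.max(steps$end - steps$start)
  mid <- floor((steps$start[i] + steps$end[i]) / 2)
  split_steps <- rbind(
    steps[-i, ],
    data.frame(chrom = "chr1", start = steps$start[i], end = mid,
               value = steps$value[i]),
    data.frame(chrom = "chr1", start = mid, end = steps$end[i],
               value = steps$value[i])
  )
  expect_equal(track_total(coverage_track(split_steps))$total_signal, total)

  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  expect_equal(track_total(read_bedgraph(path))$total_signal, total)

  # concatenating chromosomes adds totals
  steps2 <- random_steps(chrom = "chr2")
  both <- coverage_track(rbind(steps, steps2))
  expect_equal(track_total(both)$total_signal,
               total + track_total(coverage_track(steps2))$total_signal)

  # scaling values by c scales total and query means by c
  sc <- scale_track(tr, 2.5)
  expect_equal(track_total(sc)$total_signal, 2.5 * total)
  expect_equal(track_query(sc, "chr1", 10, 60)$mean,
               2.5 * track_query(tr, "chr1", 10, 60)$mean)
})

test_that("per-million normaliser prefers a declared read count", {
  steps <- data.frame(chrom = "chr1", start = 0, end = 100, value = 5)
  declared <- coverage_track(steps, total_mapped_reads = 2e6)
  expect_equal(track_total(declared)$scale_per_million, 0.5)
  proxy <- coverage_track(steps)
  s <- track_total(proxy, read_length_bp = 50)
  expect_equal(s$normaliser, 500 / 50)  # total 500 signal / 50 bp reads
  expect_equal(track_total(proxy, mode = "bases")$normaliser, 500)
})
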
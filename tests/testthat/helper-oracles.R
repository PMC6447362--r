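# Independent oracles used across tests: everything here works by brute
# force on explicit per-base vectors or full enumeration, never through
# the code paths it checks.

# expand a step data.frame to an explicit per-base vector over [0, end)
brute_expand <- function(steps, chrom, upto) {
  v <- numeric(upto)
  s <- steps[steps$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(s))) {
    ix <- (s$start[i] + 1):min(s$end[i], upto)
    if (length(ix)) v[ix] <- s$value[i]
  }
  v
}

brute_mean <- function(steps, chrom, start, end, upto = 10000L) {
  v <- brute_expand(steps, chrom, max(upto, end))
  mean(v[(start + 1):end])
}

# a random non-overlapping step set with integer values (fp-exact sums)
random_steps <- function(n_steps = 8, chrom = "chr1", span = 400L) {
  bounds <- sort(sample.int(span, 2L * n_steps))
  data.frame(
    chrom = chrom,
    start = bounds[seq(1, 2 * n_steps, 2)] - 1L,
    end = bounds[seq(2, 2 * n_steps, 2)],
    value = sample(0:9, n_steps, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# two-sided rank-sum p by full enumeration of all choose(n1+n2, n1)
# labelings of the pooled sample (distinct values assumed)
perm_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(n1 + n2, n1)
  us <- apply(labelings, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# one-gene annotation builder
one_gene <- function(name = "t1", chrom = "chr1", strand = "+",
                     exon_starts = c(100L, 600L), exon_ends = c(300L, 1100L),
                     name2 = name) {
  gm <- data.frame(
    name = name, name2 = name2, chrom = chrom, strand = strand,
    start = exon_starts[1], end = exon_ends[length(exon_ends)],
    n_exons = length(exon_starts), stringsAsFactors = FALSE
  )
  gm$exon_starts <- list(as.integer(exon_starts))
  gm$exon_ends <- list(as.integer(exon_ends))
  class(gm) <- c("gene_models", "data.frame")
  gm
}

genes_rbind <- function(...) {
  gl <- list(...)
  out <- do.call(rbind, lapply(gl, function(g) { class(g) <- "data.frame"; g }))
  class(out) <- c("gene_models", "data.frame")
  out
}

# mirror a step set (and an annotation) through position `size`, for
# strand-symmetry checks
mirror_steps <- function(steps, size) {
  data.frame(chrom = steps$chrom, start = size - steps$end,
             end = size - steps$start, value = steps$value,
             stringsAsFactors = FALSE)
}

mirror_genes <- function(genes, size) {
  out <- genes
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    out$exon_starts[[i]] <- rev(size - ee)
    out$exon_ends[[i]] <- rev(size - es)
    out$start[i] <- size - genes$end[i]
    out$end[i] <- size - genes$start[i]
    out$strand[i] <- if (genes$strand[i] == "+") "-" else "+"
  }
  out
}
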
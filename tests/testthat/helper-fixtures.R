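## Shared fixtures and independent oracles used across the suite.

## Quick gene-catalog builder (0-based half-open input, the BED-like
## dialect used throughout the tests).
make_genes <- function(start0, end0, strand, chrom = "chr1",
                       contig_len = 10000L, ids = NULL) {
  n <- length(start0)
  ids <- ids %||% sprintf("tRNA-Ala-AGC-%d", seq_len(n))
  chrom <- rep_len(chrom, n)
  ctg <- if (n) unique(chrom) else "chr1"
  cl <- setNames(rep(contig_len, length(ctg)), ctg)
  trna_genes(data.frame(
    chrom = chrom, start = start0, end = end0, strand = strand,
    gene_id = ids, amino_acid = rep("Ala", n), anticodon = rep("AGC", n),
    stringsAsFactors = FALSE
  ), dialect = "zero_half_open", contig_lengths = cl)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Write hand-crafted alignments to a BAM file. `reads` needs columns
## qname, chrom, pos (1-based), len, strand ("+"/"-"), nh; unmapped
## reads have chrom = NA.
write_test_bam <- function(reads, contig_lengths, dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      unname(contig_lengths)))
  recs <- character(0)
  if (nrow(reads)) {
    mapped <- !is.na(reads$chrom)
    m <- reads[mapped, , drop = FALSE]
    if (nrow(m))
      recs <- sprintf("%s\t%d\t%s\t%d\t50\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
                      m$qname, ifelse(m$strand == "-", 16L, 0L), m$chrom,
                      m$pos, m$len, strrep("A", m$len), strrep("I", m$len),
                      m$nh)
    u <- reads[!mapped, , drop = FALSE]
    if (nrow(u))
      recs <- c(recs, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                              u$qname, strrep("A", u$len), strrep("I", u$len)))
  }
  sam <- file.path(dir, "t.sam")
  writeLines(c(header, recs), sam)
  Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE)
}

## Independent brute-force assignment oracle: per read, loop over loci
## with plain interval arithmetic (no GRanges machinery).
oracle_assign <- function(reads, loci_df, strandedness = "same") {
  vapply(seq_len(nrow(reads)), function(i) {
    if (reads$nh[i] > 1L) return("MULTIMAPPED")
    rs <- reads$pos[i]; re <- reads$pos[i] + reads$len[i] - 1L
    hits <- character(0)
    for (j in seq_len(nrow(loci_df))) {
      if (reads$chrom[i] != loci_df$chrom[j]) next
      ok_strand <- switch(strandedness,
        same = reads$strand[i] == loci_df$strand[j],
        opposite = reads$strand[i] != loci_df$strand[j],
        ignore = TRUE)
      if (!ok_strand) next
      if (rs <= loci_df$end[j] && re >= loci_df$start[j])
        hits <- c(hits, loci_df$id[j])
    }
    hits <- unique(hits)
    if (length(hits) == 0L) "NONE"
    else if (length(hits) > 1L) "AMBIGUOUS"
    else hits
  }, "")
}

loci_as_df <- function(loci) {
  data.frame(id = loci$locus_id,
             chrom = as.character(GenomeInfoDb::seqnames(loci)),
             start = BiocGenerics::start(loci),
             end = BiocGenerics::end(loci),
             strand = as.character(BiocGenerics::strand(loci)),
             stringsAsFactors = FALSE)
}

## Literal step-up BH definition: adj_(i) = min over j >= i of m/j p_(j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min((m / i:m) * ps[i:m]))
  out <- numeric(m)
  out[o] <- adj
  out
}

## Brute-force moderated t: per-feature OLS means/variances plus the
## explicit moment-matching equations, with trigamma inverted by uniroot.
oracle_moderated_t <- function(m, g) {
  lv <- levels(g)
  i1 <- which(g == lv[1]); i2 <- which(g == lv[2])
  n1 <- length(i1); n2 <- length(i2); d <- n1 + n2 - 2
  nf <- nrow(m)
  m1 <- m2 <- s2 <- numeric(nf)
  for (f in seq_len(nf)) {
    m1[f] <- mean(m[f, i1]); m2[f] <- mean(m[f, i2])
    s2[f] <- (sum((m[f, i1] - m1[f])^2) + sum((m[f, i2] - m2[f])^2)) / d
  }
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- sum((e - mean(e))^2) / (nf - 1) - trigamma(d / 2)
  stopifnot(evar > 0)
  half_d0 <- uniroot(function(y) trigamma(y) - evar,
                     lower = 1e-6, upper = 1e6, tol = 1e-12)$root
  d0 <- 2 * half_d0
  s0 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  s2post <- (d0 * s0 + d * s2) / (d0 + d)
  tmod <- (m2 - m1) / sqrt(s2post * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tmod), df = d0 + d)
  list(logFC = m2 - m1, t = tmod, p = p, d0 = d0, s0 = s0)
}

## Construct a vector with exact Pearson correlation r against x.
vector_with_r <- function(x, r, seed = 1) {
  set.seed(seed)
  e <- rnorm(length(x))
  e <- resid(lm(e ~ x))
  as.numeric(r * scale(x) + sqrt(1 - r^2) * scale(e))
}

## Minimal TPM-matrix object for filter tests (documented structure of
## NormalizedMatrix).
make_tpm_matrix <- function(values) {
  structure(list(values = values, method = "TPM",
                 pseudocount_used = NA_real_, provenance = "test",
                 feature_ids = rownames(values),
                 sample_ids = colnames(values)),
            class = "NormalizedMatrix")
}

## Count-matrix object from a plain matrix + totals, bypassing BAM IO.
make_count_matrix <- function(counts, total_mapped = colSums(counts)) {
  structure(list(
    counts = counts,
    diagnostics = data.frame(sample_id = colnames(counts),
                             total_mapped = total_mapped,
                             stringsAsFactors = FALSE),
    feature_ids = rownames(counts), sample_ids = colnames(counts)
  ), class = "CountMatrix")
}
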
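## Small two-gene annotation used by most counting tests.
quant_ann <- function() {
  g <- make_genes(c(100, 500), c(172, 572), c("+", "-"))
  l5 <- build_leader_loci(g, contig_lengths = c(chr1 = 10000L))
  frag <- import_fragment_records(data.frame(
    id = c("t5_a", "t3_a", "ts_a"),
    chrom = "chr1", start = c(100, 152, 172), end = c(120, 172, 200),
    strand = "+", class = c("tRF-5", "tRF-3", "tsRNA"),
    parent = g$gene_id[1], stringsAsFactors = FALSE
  ), dialect = "zero_half_open", genes = g)
  stopifnot(nrow(frag$quarantined) == 0)
  annotation_set(g, c(l5, frag$loci))
}

test_that("single-overlap, junction-ambiguous and multi-mapped reads assign as specified", {
  ann <- quant_ann()
  reads <- data.frame(
    qname = c("r1", "r2", "r3", "r4", "r5"),
    chrom = "chr1",
    # r1 inside t5_a; r2 straddles the abutting tRF-3/tsRNA junction;
    # r3 reports 3 hits; r4 overlaps nothing; r5 antisense to t5_a
    pos = c(103, 165, 103, 3000, 103),
    len = c(15, 20, 15, 20, 15),
    strand = c("+", "+", "+", "+", "-"),
    nh = c(1, 1, 3, 1, 1), stringsAsFactors = FALSE
  )
  bam <- write_test_bam(reads, c(chr1 = 10000L))
  gal <- read_bam_alignments(bam)
  # BAM records come back coordinate-sorted; reorder to the input reads
  ord <- match(reads$qname, S4Vectors::mcols(gal)$qname)
  asg <- assign_reads(gal, ann, strandedness = "same")[ord]
  expect_identical(asg, c("t5_a", "AMBIGUOUS", "MULTIMAPPED", "NONE", "NONE"))
  # antisense read is picked up in opposite mode, dropped in same mode
  asg_opp <- assign_reads(gal, ann, strandedness = "opposite")[ord]
  expect_identical(asg_opp[5], "t5_a")
  expect_identical(assign_reads(gal, ann, strandedness = "ignore")[ord][5],
                   "t5_a")
})

test_that("count_bam tallies uniquely assigned reads with exact conservation", {
  ann <- quant_ann()
  reads <- data.frame(
    qname = sprintf("r%02d", 1:10), chrom = "chr1", pos = 103, len = 15,
    strand = "+", nh = 1, stringsAsFactors = FALSE
  )
  bam <- write_test_bam(reads, c(chr1 = 10000L))
  col <- count_bam(bam, ann, "s1")
  expect_equal(unname(col$counts["t5_a"]), 10L)
  expect_equal(sum(col$counts), 10L)
  d <- col$diagnostics
  expect_equal(d$total_mapped, 10L)
  expect_equal(d$n_ambiguous_feature + d$n_multimapped_discarded +
                 d$n_unassigned, 0L)
})

test_that("empty and unmapped-only BAMs give all-zero columns", {
  ann <- quant_ann()
  empty <- write_test_bam(data.frame(qname = character(), chrom = character(),
                                     pos = integer(), len = integer(),
                                     strand = character(), nh = integer()),
                          c(chr1 = 10000L))
  col <- count_bam(empty, ann, "s0")
  expect_true(all(col$counts == 0L))
  expect_equal(col$diagnostics$total_mapped, 0L)

  unm <- write_test_bam(data.frame(qname = "u1", chrom = NA_character_,
                                   pos = NA_integer_, len = 20L,
                                   strand = NA_character_, nh = 1L),
                        c(chr1 = 10000L))
  col2 <- count_bam(unm, ann, "s0b")
  expect_equal(col2$diagnostics$total_mapped, 0L)
  expect_equal(col2$diagnostics$n_unmapped, 1L)
  expect_error(count_bam(tempfile(fileext = ".bam"), ann, "sX"), "not found")
})

test_that("multi-mapping falls back to duplicated query names when NH is absent", {
  ann <- quant_ann()
  dir <- tempfile("nonh"); dir.create(dir)
  sam <- file.path(dir, "t.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000",
               # d1 appears twice (two placements), u1 once, no NH tags
               "d1\t0\tchr1\t103\t50\t15M\t*\t0\t0\tAAAAAAAAAAAAAAA\tIIIIIIIIIIIIIII",
               "d1\t0\tchr1\t3000\t50\t15M\t*\t0\t0\tAAAAAAAAAAAAAAA\tIIIIIIIIIIIIIII",
               "u1\t0\tchr1\t103\t50\t15M\t*\t0\t0\tAAAAAAAAAAAAAAA\tIIIIIIIIIIIIIII"),
             sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE)
  col <- count_bam(bam, ann, "s1")
  expect_equal(unname(col$counts["t5_a"]), 1L)  # only u1
  expect_equal(col$diagnostics$n_multimapped_discarded, 2L)
})

test_that("counting equals the brute-force per-read oracle on simulated data", {
  cfg <- simulation_config(seed = 31, n_trna_genes = 12, n_reads = 3000,
                           fraction_multimapped = 0.1,
                           fraction_feature_ambiguous = 0.08)
  gc_ <- simulate_genome_and_catalog(cfg)
  ann <- simulate_annotation(gc_$catalog, cfg)
  dir <- tempfile("oracle")
  sim <- simulate_reads(cfg, gc_$genome, ann, dir)
  col <- count_bam(sim$bam, ann, "s1")

  tr <- sim$truth
  reads <- data.frame(qname = tr$read_id, chrom = tr$chrom, pos = tr$start,
                      len = tr$end - tr$start + 1L, strand = tr$strand,
                      nh = ifelse(tr$multimapped, 2L, 1L),
                      stringsAsFactors = FALSE)
  oracle <- oracle_assign(reads, loci_as_df(ann$loci), "same")
  exp_counts <- table(factor(oracle[!oracle %in% c("AMBIGUOUS", "NONE",
                                                   "MULTIMAPPED")],
                             levels = ann$loci$locus_id))
  expect_equal(unname(col$counts), unname(as.integer(exp_counts)))
  expect_equal(col$diagnostics$n_ambiguous_feature, sum(oracle == "AMBIGUOUS"))
  expect_equal(col$diagnostics$n_multimapped_discarded,
               sum(oracle == "MULTIMAPPED"))
  expect_equal(col$diagnostics$n_unassigned, sum(oracle == "NONE"))
  # conservation, exactly
  expect_equal(sum(col$counts) + col$diagnostics$n_ambiguous_feature +
                 col$diagnostics$n_multimapped_discarded +
                 col$diagnostics$n_unassigned,
               col$diagnostics$total_mapped)
})

test_that("counting is invariant under read order and monotone under read addition", {
  ann <- quant_ann()
  set.seed(99)
  n <- 200
  reads <- data.frame(
    qname = sprintf("r%03d", 1:n), chrom = "chr1",
    pos = sample(c(85, 103, 155, 165, 180, 3000), n, replace = TRUE),
    len = 15L, strand = sample(c("+", "-"), n, TRUE, prob = c(0.8, 0.2)),
    nh = sample(c(1L, 2L), n, TRUE, prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE
  )
  bam1 <- write_test_bam(reads, c(chr1 = 10000L))
  bam2 <- write_test_bam(reads[sample(n), ], c(chr1 = 10000L))
  c1 <- count_bam(bam1, ann, "s")
  c2 <- count_bam(bam2, ann, "s")
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$diagnostics, c2$diagnostics)

  # adding one read changes at most one feature count, by exactly +1,
  # or only diagnostics
  extra <- data.frame(qname = "extra", chrom = "chr1", pos = 103, len = 15L,
                      strand = "+", nh = 1L, stringsAsFactors = FALSE)
  c3 <- count_bam(write_test_bam(rbind(reads, extra), c(chr1 = 10000L)),
                  ann, "s")
  delta <- c3$counts - c1$counts
  expect_equal(sum(delta != 0), 1L)
  expect_equal(sum(delta), 1L)
})

test_that("merge_counts aligns features, zero-fills and rejects duplicate samples", {
  mk_col <- function(sid, ids, counts, total) {
    structure(list(sample_id = sid, counts = setNames(counts, ids),
                   diagnostics = data.frame(sample_id = sid,
                                            total_mapped = total)),
              class = "trf_count_column")
  }
  a <- mk_col("s1", c("f1", "f2"), c(3L, 0L), 10L)
  b <- mk_col("s2", c("f2", "f3"), c(5L, 7L), 20L)
  cm <- merge_counts(list(a, b))
  expect_equal(dim(cm$counts), c(3L, 2L))
  expect_equal(cm$counts["f1", "s2"], 0L)
  expect_equal(cm$counts["f3", "s2"], 7L)
  expect_equal(cm$counts["f2", ], c(s1 = 0L, s2 = 5L))
  # merge of one column is that column; two identical ids error
  expect_equal(unname(merge_counts(list(a))$counts[, 1]), unname(a$counts))
  expect_error(merge_counts(list(a, a)), "duplicate")
  # identical columns under different ids give two equal columns
  a2 <- mk_col("s3", c("f1", "f2"), c(3L, 0L), 10L)
  cm2 <- merge_counts(list(a, a2))
  expect_equal(unname(cm2$counts[, 1]), unname(cm2$counts[, 2]))
})

test_that("count matrices round-trip through TSV", {
  cfg <- simulation_config(seed = 5, n_reads = 500)
  dir <- tempfile("io")
  sim <- simulate_dataset(cfg, dir, n_samples = 2)
  cm <- merge_counts(lapply(names(sim$samples), function(s)
    count_bam(sim$samples[[s]]$bam, sim$ann, s)))
  cp <- file.path(dir, "counts.tsv"); dp <- file.path(dir, "diag.tsv")
  write_counts(cm, cp, dp)
  back <- read_counts(cp, dp)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$diagnostics, cm$diagnostics)
})
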
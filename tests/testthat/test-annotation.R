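test_that("leader loci sit immediately 5' of their gene with default length 20", {
  cl <- c(chr1 = 10000L)
  # plus-strand gene at 0-based [100, 172): leader is 0-based [80, 100)
  g <- make_genes(100, 172, "+")
  l <- build_leader_loci(g, contig_lengths = cl)
  expect_equal(BiocGenerics::start(l), 81L)  # 0-based 80
  expect_equal(BiocGenerics::end(l), 100L)
  expect_equal(BiocGenerics::width(l), 20L)
  expect_false(has_flag(l, "truncated"))
  expect_identical(l$frag_class, "LEADER5")
  expect_identical(l$parent_id, g$gene_id)

  # minus-strand gene at the same coordinates: leader is 0-based [172, 192)
  gm <- make_genes(100, 172, "-")
  lm_ <- build_leader_loci(gm, contig_lengths = cl)
  expect_equal(BiocGenerics::start(lm_), 173L)
  expect_equal(BiocGenerics::end(lm_), 192L)
  expect_equal(BiocGenerics::width(lm_), 20L)
})

test_that("leader loci are clipped and flagged at contig boundaries, rejected at zero space", {
  cl <- c(chr1 = 10000L)
  # plus-strand gene starting at 0-based position 5: leader [0, 5), length 5
  g <- make_genes(5, 77, "+")
  l <- build_leader_loci(g, contig_lengths = cl)
  expect_equal(BiocGenerics::start(l), 1L)
  expect_equal(BiocGenerics::end(l), 5L)
  expect_equal(BiocGenerics::width(l), 5L)
  expect_true(has_flag(l, "truncated"))

  # gene flush with the contig start: no upstream base, locus rejected
  g0 <- make_genes(0, 72, "+")
  l0 <- build_leader_loci(g0, contig_lengths = cl)
  expect_length(l0, 0)
  rej <- attr(l0, "rejected")
  expect_equal(nrow(rej), 1L)
  expect_match(rej$reason, "upstream")

  # minus-strand gene flush with the contig end
  ge <- make_genes(10000 - 72, 10000, "-")
  le <- build_leader_loci(ge, contig_lengths = cl)
  expect_length(le, 0)
})

test_that("strand reflection of the catalog mirrors leader coordinates", {
  cl <- c(chr1 = 10000L)
  set.seed(42)
  s0 <- sort(sample(500:9000, 20)) * 1L
  g_plus <- make_genes(s0, s0 + 72L, "+")
  # reflect: x0 -> L - x0 on the 0-based axis, strands flipped
  g_minus <- make_genes(10000L - (s0 + 72L), 10000L - s0, "-",
                        ids = g_plus$gene_id)
  lp <- build_leader_loci(g_plus, contig_lengths = cl)
  lm_ <- build_leader_loci(g_minus, contig_lengths = cl)
  # leader of reflected gene = reflection of the leader
  expect_equal(BiocGenerics::start(lm_) - 1L,       # to 0-based
               10000L - BiocGenerics::end(lp))
  expect_equal(BiocGenerics::end(lm_),
               10000L - (BiocGenerics::start(lp) - 1L))
})

test_that("fragment records import with dialect conversion, tRF-1 aliasing and quarantine", {
  g <- make_genes(100, 172, "+")
  recs <- data.frame(
    id = c("f1", "f2", "f3", "f4"),
    chrom = "chr1",
    start = c(101, 101, 180, 150),
    end = c(120, 118, 200, 170),
    strand = "+",
    class = c("tRF-5", "trf5", "tRF-1", "tsRNA"),
    parent = c("tRNA-Ala-AGC-1", "tRNA-Ala-AGC-1", "tRNA-Ala-AGC-1",
               "tRNA-Ala-AGC-1"),
    stringsAsFactors = FALSE
  )
  # one-based inclusive record (101, 120) becomes internal length 20,
  # 0-based [100, 120)
  out <- import_fragment_records(recs, dialect = "one_inclusive", genes = g)
  f1 <- out$loci[out$loci$locus_id == "f1"]
  expect_equal(BiocGenerics::start(f1), 101L)
  expect_equal(BiocGenerics::end(f1), 120L)
  expect_equal(BiocGenerics::width(f1), 20L)
  # tRF-1 is an alias for the tsRNA (3' trailer) class
  expect_identical(out$loci$frag_class[out$loci$locus_id == "f3"], "TSRNA")
  # tsRNA record upstream of the parent 3' end violates the trailer
  # definition and is quarantined, not thrown
  expect_true("f4" %in% out$quarantined$id)
  expect_match(out$quarantined$reason[out$quarantined$id == "f4"], "downstream")

  # unresolvable parent id
  recs$parent[1] <- "no-such-gene"
  out2 <- import_fragment_records(recs, dialect = "one_inclusive", genes = g)
  expect_match(out2$quarantined$reason[out2$quarantined$id == "f1"],
               "parent")
})

test_that("tRF length validation flags outside 14-30 nt and is monotone in the bounds", {
  g <- make_genes(100, 200, "+")
  mk <- function(len, cls) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(101, width = len), "+",
    locus_id = paste0(cls, len), frag_class = cls,
    parent_id = g$gene_id, subclass = NA_character_, flags = "")
  loci <- c(mk(14, "TRF5"), mk(31, "TRF3"), mk(13, "TRF5"), mk(30, "TRF3"))
  out <- validate_trf_length(loci)
  expect_equal(has_flag(out, "length_out_of_range"), c(FALSE, TRUE, TRUE, FALSE))
  # flag-only policy: nothing removed
  expect_length(out, 4)
  # widening the window never adds flags
  wide <- validate_trf_length(loci, min_len = 13, max_len = 31)
  expect_true(all(!has_flag(wide, "length_out_of_range")))
  # LEADER5 loci are never length-flagged
  ldr <- mk(45, "LEADER5")
  expect_false(has_flag(validate_trf_length(ldr), "length_out_of_range"))
})

test_that("annotation round-trips exactly through GTF and BED", {
  cfg <- simulation_config(seed = 11, n_trna_genes = 8,
                           boundary_gene_fraction = 0.25)
  gc_ <- simulate_genome_and_catalog(cfg)
  ann <- simulate_annotation(gc_$catalog, cfg)
  ann$loci <- assign_subclass(validate_trf_length(ann$loci))

  for (fmt in c("GTF", "BED")) {
    path <- tempfile(fileext = paste0(".", tolower(fmt)))
    write_annotation(ann, path, fmt)
    back <- read_annotation(path, fmt)
    expect_identical(as.data.frame(ann$genes), as.data.frame(back$genes),
                     label = fmt)
    d1 <- as.data.frame(ann$loci); rownames(d1) <- NULL
    d2 <- as.data.frame(back$loci); rownames(d2) <- NULL
    d1$seqnames <- as.character(d1$seqnames); d2$seqnames <- as.character(d2$seqnames)
    d1$strand <- as.character(d1$strand); d2$strand <- as.character(d2$strand)
    expect_identical(d1[order(d1$locus_id), ], d2[order(d2$locus_id), ],
                     label = fmt)
  }
})

test_that("GTF is 1-based inclusive and BED 0-based half-open on the same locus", {
  g <- make_genes(100, 172, "+")
  l <- build_leader_loci(g, contig_lengths = c(chr1 = 10000L))  # 0-based [80,100)
  ann <- annotation_set(g, l)
  gtf <- tempfile(fileext = ".gtf"); bed <- tempfile(fileext = ".bed")
  write_annotation(ann, gtf, "GTF")
  write_annotation(ann, bed, "BED")
  gline <- grep("LEADER5", readLines(gtf), value = TRUE)
  expect_equal(as.integer(strsplit(gline, "\t")[[1]][4:5]), c(81L, 100L))
  bline <- grep("LEADER5", readLines(bed), value = TRUE)
  expect_equal(as.integer(strsplit(bline, "\t")[[1]][2:3]), c(80L, 100L))
})

test_that("empty annotation writes header-only files that read back empty", {
  genes <- make_genes(integer(), integer(), character())
  ann <- annotation_set(genes, GenomicRanges::GRanges(
    locus_id = character(), frag_class = character(),
    parent_id = character(), subclass = character(), flags = character()),
    genome_id = "toy")
  for (fmt in c("GTF", "BED")) {
    path <- tempfile()
    write_annotation(ann, path, fmt)
    expect_true(all(grepl("^#", readLines(path))))
    back <- read_annotation(path, fmt)
    expect_length(back$genes, 0)
    expect_length(back$loci, 0)
    expect_identical(back$genome_id, "toy")
  }
})

test_that("annotation_set enforces referential integrity", {
  g <- make_genes(100, 172, "+")
  l <- build_leader_loci(g, contig_lengths = c(chr1 = 10000L))
  expect_s3_class(annotation_set(g, l), "AnnotationSet")
  bad <- l; bad$parent_id <- "ghost-gene"
  expect_error(annotation_set(g, bad), "parent")
  dup <- c(l, l)
  expect_error(annotation_set(g, dup), "duplicate")
})

test_that("gene catalog validation rejects malformed records", {
  expect_error(make_genes(172, 100, "+"), "end precedes start")
  expect_error(make_genes(100, 10172, "+"), "past contig end")
  expect_error(trna_genes(data.frame(
    chrom = "chr1", start = 1, end = 70, strand = "+", gene_id = "g",
    amino_acid = "Ala", anticodon = "AGCX"), "zero_half_open"), "anticodon")
  # introns must nest strictly inside the gene and not overlap
  expect_error(trna_genes(data.frame(
    chrom = "chr1", start = 100, end = 172, strand = "+", gene_id = "g",
    amino_acid = "Ala", anticodon = "AGC", introns = "90-110"),
    "zero_half_open"), "inside")
})
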
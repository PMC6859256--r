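#' Configuration for the synthetic small-RNA dataset generator
#'
#' Captures every knob of the simulator: genome layout, tRNA gene
#' placement, the abundance table of fragment loci, read number, per-base
#' substitution error rate, and the fractions of multi-mapping and
#' feature-ambiguous reads. Fragment abundance fractions plus the
#' ambiguous fraction must sum to at most 1; the remainder becomes
#' background reads drawn from non-tRNA regions.
#'
#' @param seed integer seed; the whole simulation is deterministic given
#'   the config.
#' @param n_contigs,contig_len toy genome layout (default 2 x 10 kb).
#' @param n_trna_genes number of tRNA genes (default 10).
#' @param minus_strand_fraction probability a gene is placed on the minus
#'   strand (default 0.5).
#' @param boundary_gene_fraction fraction of genes placed at a contig
#'   start with fewer than `leader_len` upstream bases, to exercise
#'   leader clipping (default 0; at most one per contig).
#' @param n_reads number of reads to emit (default 10000).
#' @param error_rate per-base substitution probability (default 0.001,
#'   a typical Illumina scale).
#' @param fraction_multimapped probability a fragment or background read
#'   is marked as reporting >1 alignment (default 0.05).
#' @param fraction_feature_ambiguous fraction of reads straddling the
#'   junction between an abutting tRF-3 locus and tsRNA locus, hence
#'   overlapping two features (default 0.05).
#' @param leader_len 5' leader length in nt (default 20).
#' @param abundance optional named vector of expected read fractions per
#'   fragment locus id; `NULL` splits a total fragment mass of 0.85
#'   equally across all loci once the annotation is built.
#' @return validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, n_contigs = 2L, contig_len = 10000L,
                              n_trna_genes = 10L, minus_strand_fraction = 0.5,
                              boundary_gene_fraction = 0,
                              n_reads = 10000L, error_rate = 0.001,
                              fraction_multimapped = 0.05,
                              fraction_feature_ambiguous = 0.05,
                              leader_len = 20L, abundance = NULL) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_len = as.integer(contig_len),
              n_trna_genes = as.integer(n_trna_genes),
              minus_strand_fraction = minus_strand_fraction,
              boundary_gene_fraction = boundary_gene_fraction,
              n_reads = as.integer(n_reads), error_rate = error_rate,
              fraction_multimapped = fraction_multimapped,
              fraction_feature_ambiguous = fraction_feature_ambiguous,
              leader_len = as.integer(leader_len), abundance = abundance)
  fr <- c(minus_strand_fraction, boundary_gene_fraction, error_rate,
          fraction_multimapped, fraction_feature_ambiguous)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_reads < 0) stop("n_reads must be >= 0")
  if (!is.null(abundance)) {
    if (is.null(names(abundance)) || any(abundance < 0))
      stop("abundance must be a named vector of non-negative fractions")
    if (sum(abundance) + fraction_feature_ambiguous > 1 + 1e-12)
      stop("abundance fractions plus ambiguous fraction exceed 1")
  }
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a toy genome and tRNA gene catalog
#'
#' Places `n_trna_genes` genes (70-90 bp bodies) on random-sequence
#' contigs, non-overlapping and with at least `leader_len` upstream and
#' 40 nt downstream clearance, except for boundary-case genes (see
#' `boundary_gene_fraction`) which start within `leader_len` of a contig
#' start. Strand is drawn per gene. Deterministic given `cfg$seed`.
#'
#' @param cfg a `SimulationConfig`.
#' @return list with `genome` (named `DNAStringSet`) and `catalog`
#'   (gene `GRanges` with seqlengths).
#' @export
simulate_genome_and_catalog <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  contigs <- sprintf("ctg%d", seq_len(cfg$n_contigs))
  genome <- Biostrings::DNAStringSet(vapply(contigs, function(x)
    paste(sample(c("A", "C", "G", "T"), cfg$contig_len, replace = TRUE),
          collapse = ""), ""))
  names(genome) <- contigs
  contig_lengths <- setNames(rep(cfg$contig_len, cfg$n_contigs), contigs)
  if (cfg$n_trna_genes == 0L)
    return(list(genome = genome,
                catalog = trna_genes(data.frame(
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), gene_id = character(),
                  amino_acid = character(), anticodon = character()),
                  contig_lengths = contig_lengths)))

  n_boundary <- min(round(cfg$boundary_gene_fraction * cfg$n_trna_genes),
                    cfg$n_contigs)
  n_slotted <- cfg$n_trna_genes - n_boundary
  slot_w <- 200L
  reserve <- 300L  # head of each contig kept for boundary genes
  slots_per_contig <- (cfg$contig_len - reserve) %/% slot_w
  if (slots_per_contig * cfg$n_contigs < n_slotted)
    stop("genes cannot fit: need contig_len >= ",
         reserve + slot_w * ceiling(n_slotted / cfg$n_contigs))

  chrom <- character(cfg$n_trna_genes)
  start <- integer(cfg$n_trna_genes)
  end <- integer(cfg$n_trna_genes)
  strand <- ifelse(rbinom(cfg$n_trna_genes, 1, cfg$minus_strand_fraction) == 1,
                   "-", "+")
  body_len <- sample(70:90, cfg$n_trna_genes, replace = TRUE)
  i <- 0L
  for (b in seq_len(n_boundary)) {
    i <- i + 1L
    chrom[i] <- contigs[b]
    start[i] <- sample(seq_len(cfg$leader_len), 1L)  # < leader_len upstream
    end[i] <- start[i] + body_len[i] - 1L
    strand[i] <- "+"  # keep the clipped leader on the upstream-left side
  }
  slot_chrom <- rep(contigs, each = slots_per_contig)[seq_len(n_slotted)]
  slot_idx <- unlist(lapply(contigs, function(x) seq_len(slots_per_contig)))[seq_len(n_slotted)]
  for (s in seq_len(n_slotted)) {
    i <- i + 1L
    chrom[i] <- slot_chrom[s]
    start[i] <- reserve + (slot_idx[s] - 1L) * slot_w + cfg$leader_len + 1L
    end[i] <- start[i] + body_len[i] - 1L
  }
  aa <- sample(c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val"), cfg$n_trna_genes, replace = TRUE)
  ac <- vapply(seq_len(cfg$n_trna_genes), function(i)
    paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = ""), "")
  catalog <- trna_genes(data.frame(
    chrom = chrom, start = start, end = end, strand = strand,
    gene_id = sprintf("tRNA-%s-%s-%d", aa, ac, seq_len(cfg$n_trna_genes)),
    amino_acid = aa, anticodon = ac, stringsAsFactors = FALSE
  ), dialect = "one_inclusive", contig_lengths = contig_lengths)
  list(genome = genome, catalog = catalog)
}

#' Build a class-faithful fragment annotation over a simulated catalog
#'
#' For each gene, constructs one locus per fragment class with the
#' class-anchored geometry the pipeline assumes: a 5' leader locus
#' (via [build_leader_loci()]), a tRF-5 locus starting at the gene 5'
#' end with length drawn from the tRF-5 subclass windows (14-16, 22-24,
#' 28-30 nt), a tRF-3 locus ending at the gene 3' end with length from
#' the tRF-3 windows (17-19, 21-23 nt), and a tsRNA locus beginning
#' immediately after the gene 3' end with length uniform on 16-40 nt.
#' Deterministic given `cfg$seed`.
#'
#' @param catalog gene `GRanges` from [simulate_genome_and_catalog()].
#' @param cfg a `SimulationConfig`.
#' @return an `AnnotationSet`.
#' @export
simulate_annotation <- function(catalog, cfg) {
  set.seed(cfg$seed + 1L)
  contig_lengths <- GenomeInfoDb::seqlengths(catalog)
  leaders <- build_leader_loci(catalog, leader_len = cfg$leader_len,
                               contig_lengths = contig_lengths)
  n <- length(catalog)
  chrom <- as.character(GenomeInfoDb::seqnames(catalog))
  strand <- as.character(BiocGenerics::strand(catalog))
  gstart <- BiocGenerics::start(catalog)
  gend <- BiocGenerics::end(catalog)
  clen <- unname(contig_lengths[chrom])
  plus <- strand == "+"

  len5 <- sample(c(14:16, 22:24, 28:30), n, replace = TRUE)
  len3 <- sample(c(17:19, 21:23), n, replace = TRUE)
  lents <- sample(16:40, n, replace = TRUE)

  t5_start <- ifelse(plus, gstart, gend - len5 + 1L)
  t5_end <- ifelse(plus, gstart + len5 - 1L, gend)
  t3_start <- ifelse(plus, gend - len3 + 1L, gstart)
  t3_end <- ifelse(plus, gend, gstart + len3 - 1L)
  ts_start <- ifelse(plus, gend + 1L, pmax(1L, gstart - lents))
  ts_end <- ifelse(plus, pmin(clen, gend + lents), gstart - 1L)

  mk <- function(st, en, cls, suffix) GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(st, en), strand = strand,
    locus_id = paste0(catalog$gene_id, suffix), frag_class = cls,
    parent_id = catalog$gene_id, subclass = NA_character_, flags = "",
    seqinfo = GenomeInfoDb::Seqinfo(names(contig_lengths),
                                    unname(contig_lengths))
  )
  loci <- c(mk(t5_start, t5_end, "TRF5", "_trf5"),
            mk(t3_start, t3_end, "TRF3", "_trf3"),
            mk(ts_start, ts_end, "TSRNA", "_tsrna"),
            leaders)
  names(loci) <- loci$locus_id
  annotation_set(catalog, loci, genome_id = "synthetic")
}

#' Simulate small-RNA reads with a paired truth table and truth BAM
#'
#' Samples each read's category from the abundance table (fragment loci),
#' the feature-ambiguous fraction (reads straddling the abutting
#' tRF-3/tsRNA junction at a gene 3' end) and background (uniform
#' intervals outside all genes and loci). Fragment reads copy the sense
#' sequence of their source locus exactly; substitution errors are then
#' applied at `error_rate` per base. A designated fraction of fragment
#' and background reads carries a reported hit count of 2 (`NH:i:2`) to
#' exercise multi-mapper removal; ambiguous-junction reads are never so
#' marked, keeping the ambiguous fraction an unbiased binomial draw.
#' Reads are written as FASTQ and as a truth-aligned BAM whose alignment
#' is the generating interval.
#'
#' @param cfg a `SimulationConfig`.
#' @param genome named `DNAStringSet`.
#' @param ann `AnnotationSet` from [simulate_annotation()].
#' @param dir output directory (created if needed).
#' @param sample_id basename for the FASTQ/BAM/truth files.
#' @param seed RNG seed for this library (default `cfg$seed + 2`), so
#'   multiple samples can be drawn from one config.
#' @return list with `fastq`, `bam`, `truth_path` (file paths) and
#'   `truth` (data.frame: `read_id`, `source`, `true_locus`,
#'   `true_class`, `chrom`, `start`, `end`, `strand`, `multimapped`).
#' @export
simulate_reads <- function(cfg, genome, ann, dir, sample_id = "sample1",
                           seed = cfg$seed + 2L) {
  stopifnot(is(cfg, "SimulationConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  loci <- ann$loci
  if (length(loci) == 0L && (is.null(cfg$abundance) || length(cfg$abundance)))
    stop("annotation has no loci to draw fragment reads from")
  abundance <- cfg$abundance
  if (is.null(abundance))
    abundance <- setNames(rep(0.85 / length(loci), length(loci)),
                          loci$locus_id)
  unknown <- setdiff(names(abundance), loci$locus_id)
  if (length(unknown))
    stop("abundance references unknown fragment(s): ",
         paste(unknown, collapse = ", "))

  p_bg <- 1 - sum(abundance) - cfg$fraction_feature_ambiguous
  cats <- c(names(abundance), "__ambiguous__", "__background__")
  probs <- c(unname(abundance), cfg$fraction_feature_ambiguous, p_bg)
  category <- sample(cats, cfg$n_reads, replace = TRUE, prob = probs)

  chrom_l <- as.character(GenomeInfoDb::seqnames(loci))
  strand_l <- as.character(BiocGenerics::strand(loci))
  lstart <- BiocGenerics::start(loci)
  lend <- BiocGenerics::end(loci)
  names(chrom_l) <- names(strand_l) <- names(lstart) <- names(lend) <- loci$locus_id

  # junction templates: genes carrying both a TRF3 and a TSRNA locus
  genes <- ann$genes
  catalog_has <- function(cls) catalog_parent_ids(loci, cls)
  j_parents <- intersect(catalog_has("TRF3"), catalog_has("TSRNA"))
  if (cfg$fraction_feature_ambiguous > 0 && !length(j_parents))
    stop("no tRF-3/tsRNA junction available for ambiguous reads")

  n <- cfg$n_reads
  chrom <- character(n); start <- integer(n); end <- integer(n)
  strand <- character(n); source <- category
  true_locus <- rep(NA_character_, n); true_class <- rep(NA_character_, n)

  is_frag <- !category %in% c("__ambiguous__", "__background__")
  if (any(is_frag)) {
    id <- category[is_frag]
    chrom[is_frag] <- chrom_l[id]
    start[is_frag] <- lstart[id]
    end[is_frag] <- lend[id]
    strand[is_frag] <- strand_l[id]
    true_locus[is_frag] <- id
    cls <- setNames(loci$frag_class, loci$locus_id)
    true_class[is_frag] <- cls[id]
  }
  is_amb <- category == "__ambiguous__"
  if (any(is_amb)) {
    gi <- match(sample(j_parents, sum(is_amb), replace = TRUE), genes$gene_id)
    gplus <- as.character(BiocGenerics::strand(genes))[gi] == "+"
    g3 <- ifelse(gplus, BiocGenerics::end(genes)[gi],
                 BiocGenerics::start(genes)[gi])
    chrom[is_amb] <- as.character(GenomeInfoDb::seqnames(genes))[gi]
    start[is_amb] <- ifelse(gplus, g3 - 9L, g3 - 10L)
    end[is_amb] <- ifelse(gplus, g3 + 10L, g3 + 9L)
    strand[is_amb] <- ifelse(gplus, "+", "-")
    source[is_amb] <- "ambiguous_junction"
    true_class[is_amb] <- "AMBIGUOUS"
  }
  is_bg <- category == "__background__"
  if (any(is_bg)) {
    occupied <- c(GenomicRanges::granges(loci), GenomicRanges::granges(genes))
    bg <- sample_background_intervals(sum(is_bg), genome, occupied, width = 20L)
    chrom[is_bg] <- bg$chrom
    start[is_bg] <- bg$start
    end[is_bg] <- bg$end
    strand[is_bg] <- bg$strand
    source[is_bg] <- "background"
    true_class[is_bg] <- "BACKGROUND"
  }

  multimapped <- rep(FALSE, n)
  eligible <- is_frag | is_bg
  multimapped[eligible] <- runif(sum(eligible)) < cfg$fraction_multimapped

  seqs <- extract_sense(genome, chrom, start, end, strand)
  seqs <- apply_substitution_errors(seqs, cfg$error_rate)
  read_id <- sprintf("read%07d", seq_len(n))

  fastq <- file.path(dir, paste0(sample_id, ".fastq"))
  write_fastq(read_id, seqs, fastq)
  bam <- write_truth_bam(read_id, seqs, chrom, start, strand, multimapped,
                         genome, file.path(dir, sample_id))
  truth <- data.frame(read_id = read_id, source = source,
                      true_locus = true_locus, true_class = true_class,
                      chrom = chrom, start = start, end = end,
                      strand = strand, multimapped = multimapped,
                      stringsAsFactors = FALSE)
  truth_path <- file.path(dir, paste0(sample_id, ".truth.tsv"))
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fastq = fastq, bam = bam, truth = truth, truth_path = truth_path)
}

catalog_parent_ids <- function(loci, cls) {
  unique(loci$parent_id[loci$frag_class == cls])
}

sample_background_intervals <- function(k, genome, occupied, width = 20L,
                                        max_tries = 10000L) {
  contigs <- names(genome)
  clen <- setNames(Biostrings::width(genome), contigs)
  out_chrom <- character(k); out_start <- integer(k)
  filled <- 0L; tries <- 0L
  while (filled < k) {
    tries <- tries + 1L
    if (tries > max_tries) stop("cannot place background reads off-annotation")
    m <- k - filled
    ch <- sample(contigs, m, replace = TRUE)
    st <- vapply(ch, function(x) sample.int(clen[x] - width, 1L), 1L)
    cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = width))
    ok <- GenomicRanges::countOverlaps(cand, occupied, ignore.strand = TRUE) == 0
    nok <- sum(ok)
    if (nok) {
      idx <- filled + seq_len(nok)
      out_chrom[idx] <- ch[ok]
      out_start[idx] <- st[ok]
      filled <- filled + nok
    }
  }
  list(chrom = out_chrom, start = out_start, end = out_start + width - 1L,
       strand = sample(c("+", "-"), k, replace = TRUE))
}

extract_sense <- function(genome, chrom, start, end, strand) {
  s <- vapply(seq_along(chrom), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], start[i], end[i])), "")
  minus <- strand == "-"
  if (any(minus)) {
    rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(s[minus]))
    s[minus] <- as.character(rc)
  }
  s
}

apply_substitution_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

write_fastq <- function(ids, seqs, path) {
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  path
}

## Truth alignments: one record per read at its generating interval;
## multi-map status is encoded via NH (the read is not re-placed).
write_truth_bam <- function(ids, seqs, chrom, pos, strand, multimapped,
                            genome, dest_prefix) {
  plus_seq <- seqs
  minus <- strand == "-"
  if (any(minus))
    plus_seq[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  rec <- sprintf("%s\t%d\t%s\t%d\t50\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
                 ids, ifelse(minus, 16L, 0L), chrom, pos, nchar(plus_seq),
                 plus_seq, strrep("I", nchar(plus_seq)),
                 ifelse(multimapped, 2L, 1L))
  sam <- paste0(dest_prefix, ".sam")
  writeLines(c(header, rec), sam)
  bam <- Rsamtools::asBam(sam, dest_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: genome + catalog, fragment annotation, and one or
#' more read libraries, all written under `dir` (genome FASTA, GTF
#' annotation, per-sample FASTQ/BAM/truth TSV).
#'
#' @param cfg a `SimulationConfig`.
#' @param dir output directory.
#' @param n_samples number of read libraries (default 1), seeded
#'   `cfg$seed + 2, + 3, ...`.
#' @return list with `genome`, `catalog`, `ann`, `genome_fasta`,
#'   `annotation_gtf`, and `samples` (per-sample [simulate_reads()]
#'   results, named `sample1..sampleN`).
#' @export
simulate_dataset <- function(cfg, dir, n_samples = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gc_ <- simulate_genome_and_catalog(cfg)
  ann <- simulate_annotation(gc_$catalog, cfg)
  genome_fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(gc_$genome, genome_fasta)
  annotation_gtf <- file.path(dir, "annotation.gtf")
  write_annotation(ann, annotation_gtf, format = "GTF")
  samples <- lapply(seq_len(n_samples), function(s)
    simulate_reads(cfg, gc_$genome, ann, dir,
                   sample_id = paste0("sample", s), seed = cfg$seed + 1L + s))
  names(samples) <- paste0("sample", seq_len(n_samples))
  list(genome = gc_$genome, catalog = gc_$catalog, ann = ann,
       genome_fasta = genome_fasta, annotation_gtf = annotation_gtf,
       samples = samples)
}
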
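#' Construct a tRNA gene catalog
#'
#' Builds a validated `GRanges` of tRNA genes from a coordinate table.
#' Coordinates are stored 1-based inclusive internally (the GRanges
#' convention); the input dialect must be declared explicitly so that
#' 0-based half-open tables (BED-like, GtRNAdb exports) and 1-based
#' inclusive tables (GTF-like) are both imported unambiguously.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `amino_acid` (3-letter code or `"Und"`), `anticodon`
#'   (3 nt over A/C/G/T/N), and optionally `introns` (semicolon-separated
#'   `start-end` pairs in the same dialect, empty string for none).
#' @param dialect coordinate convention of `start`/`end` in `df`.
#' @param contig_lengths optional named integer vector of contig lengths,
#'   used to check that genes lie within their contigs and retained as
#'   `seqlengths` on the result.
#' @return a `GRanges` with metadata columns `gene_id`, `amino_acid`,
#'   `anticodon`, `introns`.
#' @examples
#' g <- trna_genes(data.frame(
#'   chrom = "chr1", start = 100, end = 172, strand = "+",
#'   gene_id = "tRNA-Ala-AGC-1", amino_acid = "Ala", anticodon = "AGC"
#' ), dialect = "zero_half_open", contig_lengths = c(chr1 = 10000))
#' @export
trna_genes <- function(df, dialect = c("zero_half_open", "one_inclusive"),
                       contig_lengths = NULL) {
  dialect <- match.arg(dialect)
  need <- c("chrom", "start", "end", "strand", "gene_id", "amino_acid", "anticodon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in catalog")
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (!all(grepl("^[ACGTN]{3}$", df$anticodon)))
    stop("anticodon must be a 3-mer over A/C/G/T/N")

  co <- coords_to_internal(df$start, df$end, dialect)
  if (any(co$end < co$start)) stop("gene end precedes start")
  if (any(co$start < 1L)) stop("gene start before contig origin")
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(unique(df$chrom), names(contig_lengths))
    if (length(unknown)) stop("contig length missing for: ", paste(unknown, collapse = ", "))
    if (any(co$end > contig_lengths[df$chrom]))
      stop("gene extends past contig end")
  }

  introns <- if ("introns" %in% names(df)) as.character(df$introns) else rep("", nrow(df))
  introns[is.na(introns)] <- ""
  for (i in seq_len(nrow(df))) {
    iv <- parse_introns(introns[i], dialect)
    if (nrow(iv)) {
      if (any(iv$start <= co$start[i]) || any(iv$end >= co$end[i]))
        stop("intron of gene ", df$gene_id[i], " not strictly inside gene body")
      o <- order(iv$start)
      if (nrow(iv) > 1 && any(iv$start[o][-1] <= iv$end[o][-nrow(iv)]))
        stop("overlapping introns in gene ", df$gene_id[i])
      introns[i] <- paste(sprintf("%d-%d", iv$start, iv$end), collapse = ";")
    } else introns[i] <- ""
  }

  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = co$start, end = co$end),
    strand = df$strand,
    gene_id = as.character(df$gene_id),
    amino_acid = as.character(df$amino_acid),
    anticodon = as.character(df$anticodon),
    introns = introns
  )
  if (!is.null(contig_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(contig_lengths)
    GenomeInfoDb::seqlengths(gr) <- unname(contig_lengths)
  }
  names(gr) <- df$gene_id
  gr
}

## Introns parsed to internal 1-based inclusive coordinates.
parse_introns <- function(s, dialect) {
  if (is.na(s) || s == "") return(data.frame(start = integer(), end = integer()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  st <- as.integer(vapply(parts, `[`, "", 1))
  en <- as.integer(vapply(parts, `[`, "", 2))
  co <- coords_to_internal(st, en, dialect)
  data.frame(start = co$start, end = co$end)
}

#' Read a tRNA gene catalog from file
#'
#' Supports a GtRNAdb-style tab-delimited table (columns as in
#' [trna_genes()], dialect declared on a `# dialect=` header line or via
#' the argument), BED6 (name = gene id, amino acid/anticodon parsed from
#' ids of the form `tRNA-Ala-AGC-1` when possible) and GFF3.
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"bed"`, `"gff3"`.
#' @param dialect coordinate dialect for `format = "tsv"` when the file
#'   has no `# dialect=` header (BED and GFF3 dialects are fixed by their
#'   standards).
#' @param contig_lengths optional named vector, see [trna_genes()].
#' @return a `GRanges` gene catalog.
#' @export
read_trna_genes <- function(path, format = c("tsv", "bed", "gff3"),
                            dialect = "zero_half_open", contig_lengths = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    head_lines <- readLines(path, n = 10L)
    dial_line <- grep("^#\\s*dialect=", head_lines, value = TRUE)
    if (length(dial_line))
      dialect <- sub("^#\\s*dialect=\\s*", "", dial_line[1])
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    return(trna_genes(df, dialect = dialect, contig_lengths = contig_lengths))
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3")
  id <- if (format == "bed") gr$name else (gr$ID %||% gr$Name %||% gr$gene_id)
  aa <- rep("Und", length(gr))
  ac <- rep("NNN", length(gr))
  m <- regmatches(id, regexec("^tRNA-([A-Za-z]{3})-([ACGTN]{3})", id))
  ok <- lengths(m) == 3
  aa[ok] <- vapply(m[ok], `[`, "", 2)
  ac[ok] <- vapply(m[ok], `[`, "", 3)
  trna_genes(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    gene_id = id, amino_acid = aa, anticodon = ac
  ), dialect = "one_inclusive", contig_lengths = contig_lengths)
}

#' Build 5' leader loci upstream of tRNA genes
#'
#' For each gene, constructs the locus covering the `leader_len`
#' nucleotides immediately 5' of the gene on its own strand: upstream-left
#' for plus-strand genes, upstream-right (in genome coordinates) for
#' minus-strand genes. This models the pre-tRNA 5' leader bounded by the
#' RNase P cleavage site. Loci running past a contig boundary are clipped
#' and flagged `truncated`; genes with zero upstream bases yield no locus
#' and are reported in the `rejected` attribute. Leader loci that overlap
#' a neighboring gene are flagged `overlaps_gene` but kept.
#'
#' @param genes a gene catalog from [trna_genes()].
#' @param leader_len leader length in nt (default 20).
#' @param contig_lengths named contig lengths; taken from
#'   `seqlengths(genes)` when omitted.
#' @return `GRanges` of `LEADER5` loci with metadata columns `locus_id`,
#'   `frag_class`, `parent_id`, `subclass`, `flags`, plus an attribute
#'   `rejected` (data.frame of gene_id, reason) for genes with no
#'   upstream space.
#' @export
build_leader_loci <- function(genes, leader_len = 20L, contig_lengths = NULL) {
  stopifnot(leader_len >= 1)
  if (is.null(contig_lengths)) {
    contig_lengths <- GenomeInfoDb::seqlengths(genes)
    if (any(is.na(contig_lengths)))
      stop("contig lengths unavailable; supply contig_lengths")
  }
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  strand <- as.character(BiocGenerics::strand(genes))
  gstart <- BiocGenerics::start(genes)
  gend <- BiocGenerics::end(genes)
  clen <- unname(contig_lengths[chrom])

  plus <- strand == "+"
  avail <- ifelse(plus, gstart - 1L, clen - gend)
  lstart <- ifelse(plus, pmax(1L, gstart - leader_len), gend + 1L)
  lend <- ifelse(plus, gstart - 1L, pmin(clen, gend + leader_len))

  keep <- avail >= 1L
  rejected <- data.frame(
    gene_id = genes$gene_id[!keep],
    reason = rep("no upstream bases before contig boundary", sum(!keep)),
    stringsAsFactors = FALSE
  )

  flags <- rep("", length(genes))
  flags <- add_flag(flags, "truncated", avail < leader_len)
  loci <- GenomicRanges::GRanges(
    seqnames = chrom[keep],
    ranges = IRanges::IRanges(start = lstart[keep], end = lend[keep]),
    strand = strand[keep],
    locus_id = paste0(genes$gene_id, "_leader5")[keep],
    frag_class = rep("LEADER5", sum(keep)),
    parent_id = genes$gene_id[keep],
    subclass = rep(NA_character_, sum(keep)),
    flags = flags[keep],
    seqinfo = GenomeInfoDb::Seqinfo(names(contig_lengths), unname(contig_lengths))
  )
  ov <- GenomicRanges::countOverlaps(loci, genes, ignore.strand = TRUE) > 0
  loci$flags <- add_flag(loci$flags, "overlaps_gene", ov)
  names(loci) <- loci$locus_id
  attr(loci, "rejected") <- rejected
  loci
}

#' Import tRF-5 / tRF-3 / tsRNA fragment records
#'
#' Converts a fragment coordinate table (tRFdb-style for tRF-5/tRF-3/tRF-1,
#' or a tsRNA coordinate table) to validated fragment loci. Records labeled
#' `tRF-1` are aliased to the `TSRNA` class (3' trailer fragments). Records
#' failing validation (unresolvable parent, strand/coordinate violations of
#' the class definition) are quarantined with a reason, never thrown.
#'
#' @param records data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, `class`, `parent`; or a path to a TSV with those columns
#'   (optionally with a `# dialect=` header line).
#' @param dialect coordinate convention of the records.
#' @param genes gene catalog used to resolve `parent` ids and validate
#'   class geometry.
#' @return list with `loci` (a `GRanges`) and `quarantined` (data.frame of
#'   `id`, `reason`).
#' @export
import_fragment_records <- function(records,
                                    dialect = c("zero_half_open", "one_inclusive"),
                                    genes) {
  if (is.character(records) && length(records) == 1L) {
    head_lines <- readLines(records, n = 10L)
    dial_line <- grep("^#\\s*dialect=", head_lines, value = TRUE)
    if (length(dial_line)) dialect <- sub("^#\\s*dialect=\\s*", "", dial_line[1])
    records <- read.delim(records, comment.char = "#", stringsAsFactors = FALSE)
  }
  dialect <- match.arg(dialect)
  need <- c("id", "chrom", "start", "end", "strand", "class", "parent")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("fragment table lacks columns: ", paste(miss, collapse = ", "))

  cls <- normalize_frag_class(records$class)
  co <- coords_to_internal(records$start, records$end, dialect)
  gidx <- match(records$parent, genes$gene_id)

  reason <- rep(NA_character_, nrow(records))
  reason[is.na(cls) | cls == "LEADER5"] <- "unknown fragment class"
  reason[is.na(reason) & co$end < co$start] <- "end precedes start"
  reason[is.na(reason) & is.na(gidx)] <- "unresolvable parent gene id"

  ok <- is.na(reason)
  if (any(ok)) {
    gi <- gidx[ok]
    gstart <- BiocGenerics::start(genes)[gi]
    gend <- BiocGenerics::end(genes)[gi]
    gstrand <- as.character(BiocGenerics::strand(genes))[gi]
    gchrom <- as.character(GenomeInfoDb::seqnames(genes))[gi]
    st <- co$start[ok]; en <- co$end[ok]; k <- cls[ok]
    bad <- rep(NA_character_, sum(ok))
    bad[records$chrom[ok] != gchrom] <- "fragment on different contig than parent"
    mism <- is.na(bad) & records$strand[ok] != gstrand
    bad[mism] <- "fragment strand differs from parent"
    # mature-body fragments must lie within the gene span
    body <- is.na(bad) & k %in% c("TRF5", "TRF3")
    bad[body & (st < gstart | en > gend)] <- "tRF locus outside parent gene span"
    # trailer fragments begin at/after the gene 3' end on the gene strand
    tr <- is.na(bad) & k == "TSRNA"
    bad[tr & gstrand == "+" & st <= gend] <- "tsRNA locus not downstream of parent 3' end"
    bad[tr & gstrand == "-" & en >= gstart] <- "tsRNA locus not downstream of parent 3' end"
    reason[ok] <- bad
  }

  ok <- is.na(reason)
  loci <- GenomicRanges::GRanges(
    seqnames = records$chrom[ok],
    ranges = IRanges::IRanges(start = co$start[ok], end = co$end[ok]),
    strand = records$strand[ok],
    locus_id = as.character(records$id[ok]),
    frag_class = cls[ok],
    parent_id = as.character(records$parent[ok]),
    subclass = NA_character_,
    flags = ""
  )
  sl <- GenomeInfoDb::seqlengths(genes)
  if (length(sl) && !any(is.na(sl))) {
    GenomeInfoDb::seqlevels(loci) <- names(sl)
    GenomeInfoDb::seqlengths(loci) <- unname(sl)
  }
  names(loci) <- loci$locus_id
  list(
    loci = loci,
    quarantined = data.frame(
      id = as.character(records$id[!ok]), reason = reason[!ok],
      stringsAsFactors = FALSE
    )
  )
}

#' Flag tRF loci with lengths outside the canonical range
#'
#' tRFs derived from mature tRNAs span 14-30 nt; loci outside
#' `[min_len, max_len]` receive a `length_out_of_range` flag. The policy
#' is flag-only: no locus is ever removed.
#'
#' @param loci fragment loci (`GRanges`); only `TRF5`/`TRF3` loci are
#'   examined.
#' @param min_len,max_len inclusive length bounds in nt (defaults 14, 30).
#' @return `loci` with updated `flags`.
#' @export
validate_trf_length <- function(loci, min_len = 14L, max_len = 30L) {
  len <- BiocGenerics::width(loci)
  bad <- loci$frag_class %in% c("TRF5", "TRF3") & (len < min_len | len > max_len)
  loci$flags <- add_flag(loci$flags, "length_out_of_range", bad)
  loci
}

#' Assemble an annotation set
#'
#' Bundles a gene catalog and its fragment loci and validates referential
#' integrity: unique locus ids, every `parent_id` resolving to a gene.
#'
#' @param genes gene catalog (`GRanges`).
#' @param loci fragment loci (`GRanges`); multiple `GRanges` may be passed
#'   as a list and are concatenated.
#' @param genome_id free-text genome identifier.
#' @return an object of class `AnnotationSet` (list with `genes`, `loci`,
#'   `genome_id`).
#' @export
annotation_set <- function(genes, loci, genome_id = "") {
  if (is.list(loci) && !is(loci, "GRanges"))
    loci <- do.call(c, unname(loci))
  if (length(loci)) {
    if (anyDuplicated(loci$locus_id)) stop("duplicate locus ids")
    parents <- unique(unlist(strsplit(loci$parent_id, ",", fixed = TRUE)))
    orphan <- setdiff(parents, genes$gene_id)
    if (length(orphan))
      stop("locus parent ids not in gene catalog: ", paste(orphan, collapse = ", "))
    if (!all(loci$frag_class %in% FRAG_CLASSES)) stop("invalid frag_class")
    names(loci) <- loci$locus_id
  }
  structure(list(genes = genes, loci = loci, genome_id = genome_id),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", length(x$genes), "tRNA genes,",
      length(x$loci), "fragment loci")
  if (nzchar(x$genome_id)) cat(" [", x$genome_id, "]", sep = "")
  cat("\n")
  if (length(x$loci)) {
    tb <- table(factor(x$loci$frag_class, levels = FRAG_CLASSES))
    cat("  ", paste(names(tb), tb, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Feature lengths of an annotation set
#'
#' @param ann an `AnnotationSet`.
#' @return named integer vector of locus lengths in nt (the TPM length
#'   denominator).
#' @export
feature_lengths <- function(ann) {
  setNames(BiocGenerics::width(ann$loci), ann$loci$locus_id)
}

#' Write an annotation set to GTF or BED
#'
#' GTF is emitted 1-based inclusive with class, parent and flag
#' information in the attribute column; BED is 0-based half-open with the
#' same information encoded in the name field. Both round-trip losslessly
#' through [read_annotation()].
#'
#' @param ann an `AnnotationSet`.
#' @param path output file.
#' @param format `"GTF"` or `"BED"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("GTF", "BED")) {
  format <- match.arg(format)
  genes <- ann$genes; loci <- ann$loci
  header <- c(
    sprintf("# tRFkit annotation v%s", as.character(packageVersion("tRFkit"))),
    sprintf("# genome_id=%s", ann$genome_id)
  )
  enc <- function(x) { x[is.na(x) | x == ""] <- "."; x }
  if (format == "GTF") {
    glines <- sprintf(
      paste0('%s\ttRFkit\ttRNA_gene\t%d\t%d\t.\t%s\t.\t',
             'gene_id "%s"; amino_acid "%s"; anticodon "%s"; introns "%s";'),
      as.character(GenomeInfoDb::seqnames(genes)),
      BiocGenerics::start(genes), BiocGenerics::end(genes),
      as.character(BiocGenerics::strand(genes)),
      genes$gene_id, genes$amino_acid, genes$anticodon, enc(genes$introns)
    )
    llines <- if (length(loci)) sprintf(
      paste0('%s\ttRFkit\tfragment\t%d\t%d\t.\t%s\t.\t',
             'gene_id "%s"; locus_id "%s"; frag_class "%s"; parent_id "%s"; ',
             'subclass "%s"; flags "%s";'),
      as.character(GenomeInfoDb::seqnames(loci)),
      BiocGenerics::start(loci), BiocGenerics::end(loci),
      as.character(BiocGenerics::strand(loci)),
      loci$parent_id, loci$locus_id, loci$frag_class, loci$parent_id,
      enc(loci$subclass), enc(loci$flags)
    ) else character()
    writeLines(c(header, glines, llines), path)
  } else {
    bed_line <- function(gr, name) {
      bed <- coords_to_bed(BiocGenerics::start(gr), BiocGenerics::end(gr))
      sprintf("%s\t%d\t%d\t%s\t0\t%s",
              as.character(GenomeInfoDb::seqnames(gr)), bed$start, bed$end,
              name, as.character(BiocGenerics::strand(gr)))
    }
    gname <- sprintf("%s|GENE|%s|%s|%s", genes$gene_id, genes$amino_acid,
                     genes$anticodon, enc(genes$introns))
    lname <- if (length(loci))
      sprintf("%s|%s|%s|%s|%s", loci$locus_id, loci$frag_class,
              loci$parent_id, enc(loci$subclass), enc(loci$flags))
      else character()
    writeLines(c(header,
                 if (length(genes)) bed_line(genes, gname) else character(),
                 if (length(loci)) bed_line(loci, lname) else character()),
               path)
  }
  invisible(path)
}

#' Read an annotation set written by [write_annotation()]
#'
#' @param path input file.
#' @param format `"GTF"` or `"BED"`.
#' @param contig_lengths optional named contig lengths attached as
#'   `seqlengths`.
#' @return an `AnnotationSet`.
#' @export
read_annotation <- function(path, format = c("GTF", "BED"),
                            contig_lengths = NULL) {
  format <- match.arg(format)
  head_lines <- readLines(path, n = 5L)
  gid_line <- grep("^#\\s*genome_id=", head_lines, value = TRUE)
  genome_id <- if (length(gid_line)) sub("^#\\s*genome_id=", "", gid_line[1]) else ""
  body <- grep("^[^#]", readLines(path), value = TRUE)
  dec <- function(x) { x <- as.character(x); x[x == "."] <- ""; x }
  if (!length(body)) {
    genes <- GenomicRanges::GRanges(gene_id = character(), amino_acid = character(),
                                    anticodon = character(), introns = character())
    loci <- empty_loci()
    return(annotation_set(genes, loci, genome_id))
  }
  if (format == "GTF") {
    gr <- rtracklayer::import(path, format = "gtf")
    is_gene <- as.character(gr$type) == "tRNA_gene"
    g <- gr[is_gene]
    genes <- trna_genes(data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(g)),
      start = BiocGenerics::start(g), end = BiocGenerics::end(g),
      strand = as.character(BiocGenerics::strand(g)),
      gene_id = g$gene_id, amino_acid = g$amino_acid, anticodon = g$anticodon,
      introns = dec(g$introns), stringsAsFactors = FALSE
    ), dialect = "one_inclusive", contig_lengths = contig_lengths)
    l <- gr[!is_gene]
    loci <- GenomicRanges::GRanges(
      seqnames = as.character(GenomeInfoDb::seqnames(l)),
      ranges = IRanges::IRanges(BiocGenerics::start(l), BiocGenerics::end(l)),
      strand = as.character(BiocGenerics::strand(l)),
      locus_id = as.character(l$locus_id), frag_class = as.character(l$frag_class),
      parent_id = as.character(l$parent_id),
      subclass = ifelse(dec(l$subclass) == "", NA_character_, dec(l$subclass)),
      flags = dec(l$flags)
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    fields <- strsplit(gr$name, "|", fixed = TRUE)
    f <- function(i) vapply(fields, `[`, "", i)
    is_gene <- f(2) == "GENE"
    g <- gr[is_gene]
    genes <- trna_genes(data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(g)),
      start = BiocGenerics::start(g), end = BiocGenerics::end(g),
      strand = as.character(BiocGenerics::strand(g)),
      gene_id = f(1)[is_gene], amino_acid = f(3)[is_gene],
      anticodon = f(4)[is_gene], introns = dec(f(5)[is_gene]),
      stringsAsFactors = FALSE
    ), dialect = "one_inclusive", contig_lengths = contig_lengths)
    l <- gr[!is_gene]
    loci <- GenomicRanges::GRanges(
      seqnames = as.character(GenomeInfoDb::seqnames(l)),
      ranges = IRanges::IRanges(BiocGenerics::start(l), BiocGenerics::end(l)),
      strand = as.character(BiocGenerics::strand(l)),
      locus_id = f(1)[!is_gene], frag_class = f(2)[!is_gene],
      parent_id = f(3)[!is_gene],
      subclass = ifelse(dec(f(4)[!is_gene]) == "", NA_character_, dec(f(4)[!is_gene])),
      flags = dec(f(5)[!is_gene])
    )
  }
  if (!is.null(contig_lengths)) {
    GenomeInfoDb::seqlevels(loci) <- names(contig_lengths)
    GenomeInfoDb::seqlengths(loci) <- unname(contig_lengths)
  }
  names(loci) <- loci$locus_id
  annotation_set(genes, loci, genome_id)
}

empty_loci <- function() {
  GenomicRanges::GRanges(
    locus_id = character(), frag_class = character(), parent_id = character(),
    subclass = character(), flags = character()
  )
}
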
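#' Read small-RNA alignments from a BAM file
#'
#' Loads mapped alignment records with query name and the `NH` hit-count
#' tag. Multi-mapping status per record is determined from `NH` when the
#' tag is present, falling back to duplicated query names within the file
#' (documented precedence: tag first).
#'
#' @param bam_path path to a BAM file (index optional; coordinate sorting
#'   not required).
#' @return a `GAlignments` with metadata columns `qname` and `multi`
#'   (logical: the query reports >1 alignment).
#' @export
read_bam_alignments <- function(bam_path) {
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  param <- Rsamtools::ScanBamParam(
    what = "qname", tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  gal <- tryCatch(
    GenomicAlignments::readGAlignments(bam_path, param = param),
    error = function(e) stop("unreadable BAM file '", bam_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  nh <- S4Vectors::mcols(gal)$NH
  qname <- S4Vectors::mcols(gal)$qname
  multi <- if (!is.null(nh) && !all(is.na(nh))) {
    m <- !is.na(nh) & nh > 1L
    # records lacking the tag fall back to the duplicate-name rule
    if (anyNA(nh)) m[is.na(nh)] <- qname[is.na(nh)] %in% qname[duplicated(qname)]
    m
  } else qname %in% qname[duplicated(qname)]
  S4Vectors::mcols(gal)$multi <- multi
  gal
}

#' Assign aligned reads to fragment loci
#'
#' Implements conservative union-overlap assignment: a multi-mapping read
#' is `MULTIMAPPED`; otherwise the read is assigned to the single locus
#' any of its aligned blocks overlaps by at least `min_overlap` bp under
#' the chosen strandedness; reads overlapping two or more distinct loci
#' are `AMBIGUOUS`; reads overlapping none are `NONE`. Ambiguous and
#' multi-mapping reads are excluded from counts downstream ("all
#' ambiguously mapped reads removed"). Deterministic for fixed inputs;
#' reads on contigs absent from the annotation are `NONE`.
#'
#' @param alignments a `GAlignments` from [read_bam_alignments()], or any
#'   `GAlignments` carrying a logical `multi` metadata column (absent
#'   column means no multi-mappers).
#' @param ann an `AnnotationSet`.
#' @param strandedness `"same"` (default for stranded small-RNA
#'   protocols), `"opposite"`, or `"ignore"`.
#' @param min_overlap minimum overlap in bp (default 1, union semantics).
#' @return character vector along `alignments`: a locus id, or one of
#'   `"AMBIGUOUS"`, `"NONE"`, `"MULTIMAPPED"`.
#' @export
assign_reads <- function(alignments, ann,
                         strandedness = c("same", "opposite", "ignore"),
                         min_overlap = 1L) {
  strandedness <- match.arg(strandedness)
  loci <- ann$loci
  n <- length(alignments)
  out <- rep("NONE", n)
  multi <- S4Vectors::mcols(alignments)$multi %||% rep(FALSE, n)
  if (n == 0L) return(character())
  blocks <- GenomicAlignments::grglist(alignments)
  shared <- intersect(GenomeInfoDb::seqlevels(blocks), GenomeInfoDb::seqlevels(loci))
  missing_chrom <- setdiff(unique(as.character(GenomeInfoDb::seqnames(alignments))),
                           GenomeInfoDb::seqlevels(loci))
  if (length(missing_chrom))
    message("contigs absent from annotation (reads assigned NONE): ",
            paste(missing_chrom, collapse = ", "))
  hits <- GenomicRanges::findOverlaps(blocks, loci, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    rstrand <- as.character(BiocGenerics::strand(alignments))[q]
    lstrand <- as.character(BiocGenerics::strand(loci))[s]
    keep <- switch(strandedness,
      same = rstrand == lstrand,
      opposite = rstrand != lstrand,
      ignore = rep(TRUE, length(q))
    )
    q <- q[keep]; s <- s[keep]
    if (length(q)) {
      nloc <- tapply(s, q, function(i) length(unique(i)))
      first <- tapply(s, q, function(i) unique(i)[1])
      idx <- as.integer(names(nloc))
      out[idx] <- ifelse(nloc > 1L, "AMBIGUOUS", loci$locus_id[first])
    }
  }
  out[multi] <- "MULTIMAPPED"
  out
}

#' Count a BAM file against an annotation
#'
#' One pass over the mapped reads of one library: each record is assigned
#' with [assign_reads()] and tallied into per-locus counts plus
#' diagnostics. The conservation invariant holds exactly:
#' `sum(counts) + n_ambiguous_feature + n_multimapped_discarded +
#' n_unassigned == total_mapped`.
#'
#' @param bam_path path to the BAM file.
#' @param ann an `AnnotationSet`.
#' @param sample_id sample label for the column.
#' @param strandedness,min_overlap passed to [assign_reads()].
#' @return list of class `trf_count_column`: `sample_id`, `counts` (named
#'   integer over all locus ids), `diagnostics` (one-row data.frame with
#'   `total_mapped`, `n_assigned`, `n_ambiguous_feature`,
#'   `n_multimapped_discarded`, `n_unassigned`, `n_unmapped`).
#' @export
count_bam <- function(bam_path, ann, sample_id,
                      strandedness = c("same", "opposite", "ignore"),
                      min_overlap = 1L) {
  strandedness <- match.arg(strandedness)
  if (length(ann$loci) == 0L) stop("annotation has no fragment loci")
  gal <- read_bam_alignments(bam_path)
  n_unmapped <- Rsamtools::countBam(
    bam_path,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE))
  )$records
  asg <- assign_reads(gal, ann, strandedness = strandedness,
                      min_overlap = min_overlap)
  ids <- ann$loci$locus_id
  counts <- setNames(integer(length(ids)), ids)
  assigned <- asg[!asg %in% c("AMBIGUOUS", "NONE", "MULTIMAPPED")]
  tb <- table(assigned)
  counts[names(tb)] <- as.integer(tb)
  diag <- data.frame(
    sample_id = sample_id,
    total_mapped = length(gal),
    n_assigned = length(assigned),
    n_ambiguous_feature = sum(asg == "AMBIGUOUS"),
    n_multimapped_discarded = sum(asg == "MULTIMAPPED"),
    n_unassigned = sum(asg == "NONE"),
    n_unmapped = n_unmapped,
    stringsAsFactors = FALSE
  )
  stopifnot(sum(counts) + diag$n_ambiguous_feature +
              diag$n_multimapped_discarded + diag$n_unassigned == diag$total_mapped)
  structure(list(sample_id = sample_id, counts = counts, diagnostics = diag),
            class = "trf_count_column")
}

#' Merge per-sample count columns into a count matrix
#'
#' @param columns list of `trf_count_column` results from [count_bam()].
#' @return object of class `CountMatrix`: list with `counts` (integer
#'   matrix, features x samples, missing features zero-filled),
#'   `diagnostics` (data.frame, one row per sample), `feature_ids`,
#'   `sample_ids`.
#' @export
merge_counts <- function(columns) {
  if (is(columns, "trf_count_column")) columns <- list(columns)
  stopifnot(length(columns) >= 1L)
  sids <- vapply(columns, function(x) x$sample_id, "")
  if (anyDuplicated(sids)) stop("duplicate sample ids: ",
                                paste(sids[duplicated(sids)], collapse = ", "))
  feats <- unique(unlist(lapply(columns, function(x) names(x$counts))))
  m <- matrix(0L, nrow = length(feats), ncol = length(columns),
              dimnames = list(feats, sids))
  for (j in seq_along(columns)) m[names(columns[[j]]$counts), j] <- columns[[j]]$counts
  diag <- do.call(rbind, lapply(columns, function(x) x$diagnostics))
  structure(list(counts = m, diagnostics = diag,
                 feature_ids = feats, sample_ids = sids),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "features x", ncol(x$counts), "samples;",
      "total assigned reads:", sum(x$counts), "\n")
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' The counts table has features as rows and samples as columns; the
#' diagnostics table has one row per sample.
#'
#' @param cm a `CountMatrix`.
#' @param counts_path,diagnostics_path output paths (`diagnostics_path`
#'   optional).
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, diagnostics_path = NULL) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(diagnostics_path))
    write.table(cm$diagnostics, diagnostics_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts
#' @param counts_path path to a counts TSV written by [write_counts()].
#' @export
read_counts <- function(counts_path, diagnostics_path = NULL) {
  df <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$feature_id
  diag <- if (!is.null(diagnostics_path))
    read.delim(diagnostics_path, stringsAsFactors = FALSE)
  else data.frame(sample_id = colnames(m), total_mapped = colSums(m))
  structure(list(counts = m, diagnostics = diag,
                 feature_ids = rownames(m), sample_ids = colnames(m)),
            class = "CountMatrix")
}
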
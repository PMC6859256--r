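#' Default tRF length-subclass rules
#'
#' tRF-5s and tRF-3s stratify by size into tRF-5a (14-16 nt), tRF-5b
#' (22-24 nt), tRF-5c (28-30 nt), tRF-3a (about 18 nt) and tRF-3b (about
#' 22 nt). The "about" windows are implemented as +/-1 nt, i.e. tRF-3a
#' [17, 19] and tRF-3b [21, 23]; both are configurable via a custom rule
#' table.
#'
#' @return data.frame with columns `frag_class`, `subclass`, `min_len`,
#'   `max_len` (inclusive nt bounds).
#' @export
default_subclass_rules <- function() {
  data.frame(
    frag_class = c("TRF5", "TRF5", "TRF5", "TRF3", "TRF3"),
    subclass = c("tRF-5a", "tRF-5b", "tRF-5c", "tRF-3a", "tRF-3b"),
    min_len = c(14L, 22L, 28L, 17L, 21L),
    max_len = c(16L, 24L, 30L, 19L, 23L),
    stringsAsFactors = FALSE
  )
}

#' Validate a subclass rule table
#'
#' Checks `min_len <= max_len` and that rules within one fragment class
#' have non-overlapping windows; overlap is an error at rule load, not at
#' assignment time.
#'
#' @param rules data.frame as in [default_subclass_rules()].
#' @return the validated rule table.
#' @export
subclass_rules <- function(rules) {
  need <- c("frag_class", "subclass", "min_len", "max_len")
  miss <- setdiff(need, names(rules))
  if (length(miss)) stop("rule table lacks columns: ", paste(miss, collapse = ", "))
  if (any(rules$min_len > rules$max_len)) stop("rule with min_len > max_len")
  for (cl in unique(rules$frag_class)) {
    r <- rules[rules$frag_class == cl, , drop = FALSE]
    r <- r[order(r$min_len), , drop = FALSE]
    if (nrow(r) > 1 && any(r$min_len[-1] <= r$max_len[-nrow(r)]))
      stop("overlapping subclass windows for class ", cl)
  }
  rules
}

#' Assign length subclasses to fragment loci
#'
#' A pure function of (fragment class, locus length): each locus receives
#' the unique rule window containing its length, or no subclass when its
#' length falls between windows (a legitimate outcome). Under the default
#' rules LEADER5 and TSRNA loci are never subclassified.
#'
#' @param loci fragment loci (`GRanges`).
#' @param rules rule table, validated with [subclass_rules()].
#' @return `loci` with the `subclass` metadata column filled
#'   (`NA_character_` where no window matches).
#' @export
assign_subclass <- function(loci, rules = default_subclass_rules()) {
  rules <- subclass_rules(rules)
  len <- BiocGenerics::width(loci)
  sub <- rep(NA_character_, length(loci))
  for (i in seq_len(nrow(rules))) {
    hit <- loci$frag_class == rules$frag_class[i] &
      len >= rules$min_len[i] & len <= rules$max_len[i]
    sub[hit] <- rules$subclass[i]
  }
  loci$subclass <- sub
  loci
}

#' Sequence-signature flags for fragment loci
#'
#' Computes strand-aware sequence-level annotations (never filters):
#' * `TSRNA` loci get a `polyU_3prime` flag when the sense sequence
#'   contains a run of at least `polyU_min_run` consecutive T within its
#'   final `polyU_window` nt — tsRNAs characteristically end in poly-U.
#' * `TRF3` loci get a `cca_non_templated` note: the mature tRF-3 CCA is
#'   added post-transcriptionally and is absent from genomic sequence, so
#'   a genomic check cannot confirm it; the flag records this explicitly
#'   rather than faking a positive check.
#'
#' @param loci fragment loci (`GRanges`).
#' @param genome a named `DNAStringSet`, or a path to an (indexable)
#'   FASTA file.
#' @param polyU_min_run minimum T-run length (default 3).
#' @param polyU_window number of 3'-terminal nt scanned (default 6).
#' @return `loci` with updated `flags`.
#' @export
sequence_flags <- function(loci, genome, polyU_min_run = 3L, polyU_window = 6L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is(genome, "DNAStringSet"))
    names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(GenomeInfoDb::seqnames(loci))
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown)) stop("genome lacks contig(s): ", paste(unknown, collapse = ", "))
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(BiocGenerics::start(loci) < 1L) || any(BiocGenerics::end(loci) > clen))
    stop("locus outside contig bounds")
  seqs <- locus_sense_seq(loci, genome)
  is_ts <- loci$frag_class == "TSRNA"
  if (any(is_ts)) {
    tails <- substring(seqs[is_ts],
                       pmax(1L, nchar(seqs[is_ts]) - polyU_window + 1L))
    hit <- grepl(paste0("T{", polyU_min_run, ",}"), tails)
    loci$flags[is_ts] <- add_flag(loci$flags[is_ts], "polyU_3prime", hit)
  }
  is_t3 <- loci$frag_class == "TRF3"
  loci$flags[is_t3] <- add_flag(loci$flags[is_t3], "cca_non_templated")
  loci
}

## Strand-aware (sense) sequence of each locus: reverse complement of the
## plus-strand substring for minus-strand loci.
locus_sense_seq <- function(loci, genome) {
  chrom <- as.character(GenomeInfoDb::seqnames(loci))
  fw <- Biostrings::DNAStringSet(vapply(seq_along(loci), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]],
                                    BiocGenerics::start(loci)[i],
                                    BiocGenerics::end(loci)[i]))
  }, ""))
  minus <- as.character(BiocGenerics::strand(loci)) == "-"
  if (any(minus))
    fw[minus] <- Biostrings::reverseComplement(fw[minus])
  as.character(fw)
}
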
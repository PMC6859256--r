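new_normalized <- function(values, method, pseudocount = NA_real_,
                           provenance = "") {
  structure(list(values = values, method = method,
                 pseudocount_used = pseudocount, provenance = provenance,
                 feature_ids = rownames(values), sample_ids = colnames(values)),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix (", x$method, "): ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Reads-per-million normalization
#'
#' RPM(f, s) = counts(f, s) x 10^6 / total mapped reads of library s. The
#' denominator is the library-wide mapped-read total from the counting
#' diagnostics (all mapped reads in the BAM, not the within-annotation
#' sum), so per-sample RPM column sums never exceed 10^6 and reach it
#' only when every mapped read was assigned.
#'
#' @param cm a `CountMatrix`.
#' @return a `NormalizedMatrix` with `method = "RPM"`.
#' @export
rpm <- function(cm) {
  tot <- cm$diagnostics$total_mapped[match(colnames(cm$counts),
                                           cm$diagnostics$sample_id)]
  if (anyNA(tot)) stop("diagnostics lack total_mapped for some samples")
  vals <- cm$counts
  zero <- tot == 0
  if (any(zero)) {
    warning("samples with zero mapped reads emitted as all-zero: ",
            paste(colnames(cm$counts)[zero], collapse = ", "))
    tot[zero] <- 1 # denominator placeholder; numerators are necessarily 0
  }
  vals <- sweep(vals, 2, tot, "/") * 1e6
  new_normalized(vals, "RPM", provenance = "counts")
}

#' Transcripts-per-million normalization
#'
#' Per sample, each feature's count is divided by the feature length in
#' bp, and the resulting rates are rescaled to sum to 10^6:
#' TPM(f, s) = (counts(f, s) / length(f)) x 10^6 / sum_f (counts(f, s) /
#' length(f)). Columns with all-zero counts are emitted all-zero with a
#' warning.
#'
#' @param cm a `CountMatrix`.
#' @param lengths named numeric vector of feature lengths in nt, e.g.
#'   [feature_lengths()]; a missing length for a counted feature is fatal.
#' @return a `NormalizedMatrix` with `method = "TPM"`.
#' @export
tpm <- function(cm, lengths) {
  ids <- rownames(cm$counts)
  if (!all(ids %in% names(lengths)))
    stop("length missing for features: ",
         paste(setdiff(ids, names(lengths)), collapse = ", "))
  len <- lengths[ids]
  if (any(len < 1)) stop("feature lengths must be >= 1")
  rate <- cm$counts / len
  cs <- colSums(rate)
  zero <- cs == 0
  if (any(zero)) {
    warning("samples with no assigned reads emitted as all-zero: ",
            paste(colnames(cm$counts)[zero], collapse = ", "))
    cs[zero] <- 1
  }
  vals <- sweep(rate, 2, cs, "/") * 1e6
  new_normalized(vals, "TPM", provenance = "counts")
}

#' Filter features by mean log2 TPM
#'
#' Features whose mean over samples of log2(TPM + pseudocount) is below
#' `threshold` are removed ("average log2 TPM less than 1"); the boundary
#' is inclusive-keep (strict-less removal), so with the default
#' pseudocount a feature at TPM = 1 everywhere (mean log2 = 1) is kept.
#'
#' @param nm a TPM `NormalizedMatrix`.
#' @param threshold mean log2 TPM cutoff (default 1).
#' @param pseudocount added before the log2 (default 1; keeps zeros
#'   finite and makes the printed threshold meaningful at TPM = 1).
#' @return list with `kept` (filtered `NormalizedMatrix`) and `removed`
#'   (data.frame of `feature_id`, `mean_log2_tpm`).
#' @export
filter_by_mean_log2_tpm <- function(nm, threshold = 1.0, pseudocount = 1.0) {
  if (!identical(nm$method, "TPM")) stop("filter expects a TPM matrix")
  if (ncol(nm$values) == 0L) stop("zero samples")
  means <- rowMeans(log2(nm$values + pseudocount))
  keep <- means >= threshold
  kept <- new_normalized(nm$values[keep, , drop = FALSE], "TPM",
                         pseudocount = pseudocount, provenance = nm$provenance)
  list(
    kept = kept,
    removed = data.frame(feature_id = rownames(nm$values)[!keep],
                         mean_log2_tpm = unname(means[!keep]),
                         stringsAsFactors = FALSE)
  )
}

#' Write / read a normalized matrix as TSV
#'
#' A one-line `#` metadata header records the method and pseudocount.
#'
#' @param nm a `NormalizedMatrix`.
#' @param path output (input) path.
#' @return `path` invisibly; for `read_normalized`, a `NormalizedMatrix`.
#' @export
write_normalized <- function(nm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s pseudocount=%s", nm$method,
                     format(nm$pseudocount_used)), con)
  df <- data.frame(feature_id = rownames(nm$values), nm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  hdr <- readLines(path, n = 1L)
  method <- sub(".*method=(\\S+).*", "\\1", hdr)
  ps <- suppressWarnings(as.numeric(sub(".*pseudocount=(\\S+).*", "\\1", hdr)))
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  new_normalized(m, method, pseudocount = ps, provenance = path)
}
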
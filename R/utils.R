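#' @importFrom methods is
#' @importFrom stats var rbinom runif pt setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

FRAG_CLASSES <- c("TRF5", "TRF3", "TSRNA", "LEADER5")

## Normalize user-facing class labels ("tRF-1", "trf5", ...) to the
## internal enum. tRF-1 is an alias for TSRNA (3' trailer fragments).
normalize_frag_class <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  map <- c(
    TRF5 = "TRF5", TRF3 = "TRF3", TRF1 = "TSRNA", TSRNA = "TSRNA",
    LEADER5 = "LEADER5", LEADER = "LEADER5"
  )
  out <- unname(map[key])
  out
}

## Flags are stored as comma-separated strings in a GRanges mcol.
add_flag <- function(flags, flag, where = TRUE) {
  flags[is.na(flags)] <- ""
  hit <- where & !has_flag_str(flags, flag)
  flags[hit] <- ifelse(flags[hit] == "", flag, paste(flags[hit], flag, sep = ","))
  flags
}

has_flag_str <- function(flags, flag) {
  flags[is.na(flags)] <- ""
  vapply(strsplit(flags, ",", fixed = TRUE), function(f) flag %in% f, logical(1))
}

#' Test whether loci carry a validation flag
#'
#' @param loci a `GRanges` of fragment loci with a `flags` metadata column.
#' @param flag flag name, e.g. `"length_out_of_range"`.
#' @return logical vector along `loci`.
#' @export
has_flag <- function(loci, flag) {
  has_flag_str(S4Vectors::mcols(loci)$flags, flag)
}

## Convert explicit-dialect coordinates to 1-based inclusive (GRanges).
coords_to_internal <- function(start, end, dialect = c("zero_half_open", "one_inclusive")) {
  dialect <- match.arg(dialect)
  if (dialect == "zero_half_open") list(start = start + 1L, end = end)
  else list(start = start, end = end)
}

## Convert internal (1-based inclusive) to 0-based half-open.
coords_to_bed <- function(start, end) list(start = start - 1L, end = end)
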
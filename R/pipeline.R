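#' Pipeline configuration
#'
#' Aggregates every stage parameter with the field-standard defaults:
#' 20-nt leaders, TPM pseudocount 1, mean-log2-TPM filter threshold 1,
#' correlation reporting threshold |r| > 0.5.
#'
#' @param genes path to a tRNA gene table (TSV/BED/GFF3, see
#'   [read_trna_genes()]).
#' @param bams character vector of BAM paths, one per sample.
#' @param sample_ids sample labels (default: BAM basenames).
#' @param fragments optional fragment-record TSV (see
#'   [import_fragment_records()]); when `NULL` the annotation holds
#'   leader loci only.
#' @param genome optional genome FASTA for sequence flags.
#' @param genes_format,genes_dialect,fragments_dialect input conventions.
#' @param contig_lengths named contig lengths (required for leader
#'   construction unless derivable from `genome`).
#' @param leader_len leader length in nt (default 20).
#' @param strandedness read-assignment mode (default `"same"`).
#' @param pseudocount TPM log2 pseudocount (default 1).
#' @param filter_threshold mean log2 TPM cutoff (default 1).
#' @param de_groups optional named vector/list mapping sample ids to one
#'   of two group labels; enables the DE stage.
#' @param de_max_p,de_min_lfc DE reporting thresholds.
#' @param cor_covariates optional covariates TSV (covariates x samples);
#'   enables the correlation stage.
#' @param cor_method,cor_min_abs_r correlation settings (defaults
#'   `"pearson"`, 0.5).
#' @param seed integer seed recorded in the manifest.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(genes, bams, sample_ids = NULL, fragments = NULL,
                            genome = NULL, genes_format = "tsv",
                            genes_dialect = "zero_half_open",
                            fragments_dialect = "zero_half_open",
                            contig_lengths = NULL, leader_len = 20L,
                            strandedness = "same", pseudocount = 1.0,
                            filter_threshold = 1.0, de_groups = NULL,
                            de_max_p = 0.05, de_min_lfc = 1,
                            cor_covariates = NULL, cor_method = "pearson",
                            cor_min_abs_r = 0.5, seed = 1L) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.bam$", "", basename(bams))
  structure(list(
    genes = genes, bams = bams, sample_ids = sample_ids,
    fragments = fragments, genome = genome, genes_format = genes_format,
    genes_dialect = genes_dialect, fragments_dialect = fragments_dialect,
    contig_lengths = contig_lengths, leader_len = leader_len,
    strandedness = strandedness, pseudocount = pseudocount,
    filter_threshold = filter_threshold, de_groups = de_groups,
    de_max_p = de_max_p, de_min_lfc = de_min_lfc,
    cor_covariates = cor_covariates, cor_method = cor_method,
    cor_min_abs_r = cor_min_abs_r, seed = as.integer(seed)
  ), class = "PipelineConfig")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline from BAM to filtered expression tables
#'
#' Stages: annotation assembly (genes + leader loci + imported fragment
#' records), per-BAM counting with conservative ambiguity removal,
#' RPM and TPM normalization, mean-log2-TPM filtering, length
#' subclassification (plus sequence flags when a genome is supplied),
#' and optionally moderated-t DE and the correlation screen. All outputs
#' are TSV (plus the GTF annotation) in `out_dir`; a `manifest.json`
#' records package version, parameters and seed. A failing stage aborts
#' with the stage name.
#'
#' @param cfg a `PipelineConfig`.
#' @param out_dir output directory, created if needed.
#' @return named list of output paths, invisibly; also the in-memory
#'   results as attribute `results`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(is(cfg, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage("count", {
    missing <- cfg$bams[!file.exists(cfg$bams)]
    if (length(missing)) stop("BAM not found: ", paste(missing, collapse = ", "))
  })
  contig_lengths <- cfg$contig_lengths
  genome <- NULL
  if (!is.null(cfg$genome)) {
    genome <- stage("genome", Biostrings::readDNAStringSet(cfg$genome))
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (is.null(contig_lengths))
      contig_lengths <- setNames(Biostrings::width(genome), names(genome))
  }
  if (is.null(contig_lengths)) {
    # fall back to the @SQ lines of the first BAM header
    hdr <- Rsamtools::scanBamHeader(cfg$bams[1])[[1]]$targets
    contig_lengths <- hdr
  }

  ann <- stage("annotate", {
    genes <- read_trna_genes(cfg$genes, format = cfg$genes_format,
                             dialect = cfg$genes_dialect,
                             contig_lengths = contig_lengths)
    leaders <- build_leader_loci(genes, leader_len = cfg$leader_len,
                                 contig_lengths = contig_lengths)
    loci <- leaders
    if (!is.null(cfg$fragments)) {
      imp <- import_fragment_records(cfg$fragments,
                                     dialect = cfg$fragments_dialect,
                                     genes = genes)
      loci <- c(loci, imp$loci)
    }
    loci <- validate_trf_length(loci)
    annotation_set(genes, loci)
  })
  paths <- list(annotation = file.path(out_dir, "annotation.gtf"))
  write_annotation(ann, paths$annotation, "GTF")

  cm <- stage("count", {
    cols <- mapply(function(b, s)
      count_bam(b, ann, s, strandedness = cfg$strandedness),
      cfg$bams, cfg$sample_ids, SIMPLIFY = FALSE)
    merge_counts(cols)
  })
  paths$counts <- file.path(out_dir, "counts.tsv")
  paths$diagnostics <- file.path(out_dir, "diagnostics.tsv")
  write_counts(cm, paths$counts, paths$diagnostics)

  rpm_m <- stage("normalize", rpm(cm))
  tpm_m <- stage("normalize", tpm(cm, feature_lengths(ann)))
  paths$rpm <- file.path(out_dir, "rpm.tsv")
  paths$tpm <- file.path(out_dir, "tpm.tsv")
  write_normalized(rpm_m, paths$rpm)
  write_normalized(tpm_m, paths$tpm)

  filt <- stage("filter", filter_by_mean_log2_tpm(
    tpm_m, threshold = cfg$filter_threshold, pseudocount = cfg$pseudocount))
  paths$filtered <- file.path(out_dir, "filtered.tsv")
  write_normalized(filt$kept, paths$filtered)
  paths$removed <- file.path(out_dir, "removed_features.tsv")
  write.table(filt$removed, paths$removed, sep = "\t", quote = FALSE,
              row.names = FALSE)

  classes <- stage("classify", {
    loci <- assign_subclass(ann$loci)
    if (!is.null(genome)) loci <- sequence_flags(loci, genome)
    data.frame(locus_id = loci$locus_id, frag_class = loci$frag_class,
               length = BiocGenerics::width(loci), subclass = loci$subclass,
               flags = loci$flags, stringsAsFactors = FALSE)
  })
  paths$classes <- file.path(out_dir, "classes.tsv")
  write.table(classes, paths$classes, sep = "\t", quote = FALSE,
              row.names = FALSE)

  results <- list(ann = ann, counts = cm, rpm = rpm_m, tpm = tpm_m,
                  filtered = filt, classes = classes)

  if (!is.null(cfg$de_groups)) {
    de <- stage("de", {
      g <- unlist(cfg$de_groups)[colnames(filt$kept$values)]
      moderated_t_de(log2(filt$kept$values + cfg$pseudocount), factor(g))
    })
    paths$de <- file.path(out_dir, "de.tsv")
    de_out <- de
    de_out$neg_log10_fdr <- -log10(pmax(de$fdr, .Machine$double.xmin))
    write.table(de_out, paths$de, sep = "\t", quote = FALSE, row.names = FALSE)
    results$de <- de
    results$de_filtered <- filter_de(de, cfg$de_max_p, cfg$de_min_lfc)
  }

  if (!is.null(cfg$cor_covariates)) {
    co <- stage("correlate", {
      cov <- read_covariates(cfg$cor_covariates)
      correlate(filt$kept, cov, method = cfg$cor_method,
                min_abs_r = cfg$cor_min_abs_r)
    })
    paths$correlations <- file.path(out_dir, "correlations.tsv")
    write.table(co, paths$correlations, sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$correlations <- co
  }

  manifest <- list(
    package = "tRFkit", version = as.character(packageVersion("tRFkit")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    parameters = cfg[c("leader_len", "strandedness", "pseudocount",
                       "filter_threshold", "de_max_p", "de_min_lfc",
                       "cor_method", "cor_min_abs_r")],
    inputs = list(genes = cfg$genes, bams = cfg$bams,
                  fragments = cfg$fragments, genome = cfg$genome),
    outputs = paths
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  attr(paths, "results") <- results
  invisible(paths)
}

#' Read a covariates table (covariates x samples TSV)
#'
#' @param path TSV with covariate ids in the first column and one column
#'   per sample.
#' @return numeric matrix with covariate row names and sample column
#'   names.
#' @export
read_covariates <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
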
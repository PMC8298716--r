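# End-to-end driver: FASTQ libraries -> QC -> assignment -> RPM ->
# consistent-expression filter -> multiplicity / membership reports ->
# cross-tissue specificity, clustering with node extraction, and t-SNE.

#' Run the full piRNA characterization pipeline
#'
#' Chains every stage of the workflow over a cohort of FASTQ libraries. The
#' consistent-expression filter is applied within the focus tissue's
#' samples (the cohort that defines the piRNA set); all downstream reports
#' are restricted to that kept set, while detection, specificity and
#' clustering use every sample.
#'
#' @param fastq_files Named character vector of FASTQ paths (names =
#'   sample ids).
#' @param annotation A [pirna_annotation()].
#' @param metadata Sample metadata covering every sample.
#' @param config A [filter_config()].
#' @param adapter 3' adapter to trim, or `NULL` to skip trimming.
#' @param focus Focus tissue (default "placenta").
#' @param reference Reference tissue for fold-bias calls (default
#'   "testis").
#' @param region_sets List of [region_set()]s for membership reporting
#'   (e.g. piRNA clusters and an imprinted region).
#' @param imprinted_region The [region_set()] used for the node locus
#'   profile; defaults to the element of `region_sets` that is not the
#'   cluster set, else `NULL` (node profile skipped).
#' @param node_factor,node_min_rpm Parameters of
#'   [focus_enriched_predicate()].
#' @param run_tsne Compute the 3-D sample embedding (default `TRUE`).
#' @param tsne_seed Seed for the embedding (default 1).
#' @param tsne_perplexity Perplexity (default 10).
#' @return A list of class `pirna_pipeline` with elements `qc_reports`,
#'   `counts`, `rpm`, `detected`, `filter` (kept ids + diagnostics),
#'   `multiplicity`, `membership`, `detection`, `exclusivity`, `fold`,
#'   `dendrogram`, `node`, `node_profile`, `embedding` and the effective
#'   `config`.
#' @export
run_pipeline <- function(fastq_files, annotation, metadata,
                         config = filter_config(),
                         adapter = default_adapter(),
                         focus = "placenta", reference = "testis",
                         region_sets = list(),
                         imprinted_region = NULL,
                         node_factor = 20, node_min_rpm = 2000,
                         run_tsne = TRUE, tsne_seed = 1L,
                         tsne_perplexity = 10) {
  abort_if(is.null(names(fastq_files)) || any(!nzchar(names(fastq_files))),
           "fastq_files must be named by sample id")
  validate_sample_metadata(metadata)
  abort_if(!all(names(fastq_files) %in% metadata$sample_id),
           "metadata does not cover every FASTQ sample")

  qc_reports <- list()
  read_sets <- list()
  for (sid in names(fastq_files)) {
    pp <- preprocess_reads(read_fastq(fastq_files[[sid]]), adapter = adapter,
                           config = config)
    qc_reports[[sid]] <- pp$report
    read_sets[[sid]] <- pp$reads$sequence
  }

  counts <- assign_reads(read_sets, annotation, config)
  rpm <- rpm_normalize(counts)
  focus_samples <- metadata$sample_id[metadata$tissue == focus]
  abort_if(length(focus_samples) == 0L,
           "focus tissue '%s' has no samples", focus)

  detected <- detected_pirnas(counts, samples = focus_samples)
  filt <- consistent_expression_filter(counts, rpm, config,
                                       samples = focus_samples)
  kept <- filt$kept

  multiplicity <- if (length(kept) > 0L) {
    multiplicity_report(annotation, kept, config)
  } else NULL

  n_mito_known <- length(unique(
    annotation$loci$pirna_id[annotation$loci$chrom == "chrM"]))
  membership <- if (length(kept) > 0L) {
    membership_report(annotation, region_sets, kept,
                      reference_counts = c(mitochondrial = n_mito_known))
  } else NULL

  counts_kept <- counts$counts[kept, , drop = FALSE]
  rpm_kept <- rpm[kept, , drop = FALSE]
  detection <- detection_vector(counts_kept, rpm_kept, metadata, config)
  exclusivity <- exclusivity_classes(detection, focus)
  fold <- fold_bias(counts_kept, rpm_kept, metadata, focus, reference,
                    config)

  dend <- NULL
  node <- NULL
  node_profile <- NULL
  if (length(kept) >= 2L) {
    dend <- hierarchical_cluster(rpm_kept)
    pred <- focus_enriched_predicate(rpm_kept, metadata, focus,
                                     factor = node_factor,
                                     min_focus_rpm = node_min_rpm)
    node <- extract_node(dend, pred)
    if (is.null(imprinted_region) && length(region_sets) > 0L) {
      non_cluster <- Filter(function(rs) rs$name != "piRNA_clusters",
                            region_sets)
      if (length(non_cluster) > 0L) imprinted_region <- non_cluster[[1]]
    }
    if (!is.null(imprinted_region)) {
      node_profile <- node_region_report(node, annotation, imprinted_region)
    }
  }

  embedding <- NULL
  if (run_tsne && length(kept) > 0L &&
      ncol(rpm_kept) > 3 * tsne_perplexity) {
    embedding <- tsne_embed(t(log2(rpm_kept + 1)),
                            perplexity = tsne_perplexity, seed = tsne_seed)
  }

  structure(
    list(qc_reports = qc_reports, counts = counts, rpm = rpm,
         detected = detected, filter = filt, multiplicity = multiplicity,
         membership = membership, detection = detection,
         exclusivity = exclusivity, fold = fold, dendrogram = dend,
         node = node, node_profile = node_profile, embedding = embedding,
         focus = focus, reference = reference, config = config),
    class = "pirna_pipeline"
  )
}

#' @export
print.pirna_pipeline <- function(x, ...) {
  cat("piRNA characterization pipeline\n")
  cat(sprintf("  samples              : %d (focus tissue '%s')\n",
              ncol(x$counts$counts), x$focus))
  cat(sprintf("  detected in focus    : %d piRNAs (>= 1 read in >= 1 sample)\n",
              length(x$detected)))
  cat(sprintf("  consistently expressed: %d piRNAs\n", length(x$filter$kept)))
  if (!is.null(x$multiplicity)) {
    bt <- x$multiplicity$bin_totals
    cat("  multiplicity bins    :",
        paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  }
  if (!is.null(x$exclusivity)) {
    ct <- x$exclusivity$counts
    cat(sprintf("  exclusive/ubiquitous : %d / %d\n",
                ct[["exclusive_to_focus"]], ct[["ubiquitous"]]))
  }
  if (!is.null(x$node)) {
    cat(sprintf("  extracted node       : %d members\n",
                length(x$node$members)))
  }
  invisible(x)
}
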
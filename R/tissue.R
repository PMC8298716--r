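# Cross-tissue comparison of a piRNA set: per-tissue detection calls,
# exclusivity/ubiquity classes, median fold-change bias between a focus and
# a reference tissue, unsupervised hierarchical clustering of piRNAs with
# dendrogram node extraction, and region profiling of an extracted node.

tissue_groups <- function(metadata, samples) {
  abort_if(!all(samples %in% metadata$sample_id),
           "metadata does not cover every sample column")
  tis <- metadata$tissue[match(samples, metadata$sample_id)]
  split(samples, tis)
}

#' Per-tissue detection calls
#'
#' A piRNA is "detected" in a tissue iff, restricted to that tissue's
#' samples, it satisfies the consistent-expression criteria: read total
#' >= `min_total_reads` and RPM >= `min_rpm` in at least
#' [min_sample_threshold()] of the tissue's samples (which floors at one
#' sample, so a three-sample tissue requires one sample).
#'
#' @param counts A `pirna_counts` (or count matrix with `library_sizes`
#'   attached via `rpm`).
#' @param rpm RPM matrix matching `counts` (default [rpm_normalize()]).
#' @param metadata Sample metadata (`sample_id`, `tissue`) covering every
#'   sample column; every tissue must have at least one sample.
#' @param config A [filter_config()].
#' @return Logical matrix, piRNA x tissue.
#' @export
detection_vector <- function(counts, rpm = NULL, metadata,
                             config = filter_config()) {
  cm <- if (inherits(counts, "pirna_counts")) counts$counts else counts
  if (is.null(rpm)) rpm <- rpm_normalize(counts)
  groups <- tissue_groups(metadata, colnames(cm))
  abort_if(any(lengths(groups) == 0L), "tissue with zero samples")
  det <- vapply(groups, function(ss) {
    need <- min_sample_threshold(length(ss), config$min_sample_frac)
    rowSums(cm[, ss, drop = FALSE]) >= config$min_total_reads &
      rowSums(rpm[, ss, drop = FALSE] >= config$min_rpm) >= need
  }, logical(nrow(cm)))
  det <- matrix(det, nrow = nrow(cm),
                dimnames = list(rownames(cm), names(groups)))
  det
}

#' Exclusivity / ubiquity classes
#'
#' `exclusive_to_focus`: detected in the focus tissue and nowhere else;
#' `ubiquitous`: detected in every tissue; `other`: anything else. The three
#' classes partition the analysed set.
#'
#' @param detection Logical piRNA x tissue matrix from [detection_vector()].
#' @param focus Focus tissue name (must be a column of `detection`).
#' @return A list with `class` (named factor per piRNA) and `counts`.
#' @export
exclusivity_classes <- function(detection, focus) {
  abort_if(!focus %in% colnames(detection),
           "focus tissue '%s' not in detection matrix", focus)
  abort_if(ncol(detection) < 2L, "need at least two tissues")
  others <- detection[, setdiff(colnames(detection), focus), drop = FALSE]
  cls <- rep("other", nrow(detection))
  cls[detection[, focus] & rowSums(others) == 0L] <- "exclusive_to_focus"
  cls[rowSums(detection) == ncol(detection)] <- "ubiquitous"
  cls <- factor(cls, levels = c("exclusive_to_focus", "ubiquitous", "other"))
  names(cls) <- rownames(detection)
  counts <- stats::setNames(as.integer(table(cls)), levels(cls))
  stopifnot(sum(counts) == nrow(detection))
  list(class = cls, counts = counts)
}

#' Median fold-change bias between two tissues
#'
#' Computes each piRNA's median RPM in the focus and reference tissues. If
#' the reference median is zero and every reference read count is zero the
#' piRNA is classed `not_detected_in_reference`. Otherwise, with
#' `r = (focus median + pseudocount) / (reference median + pseudocount)`,
#' `r >= fold_threshold` gives `focus_biased`, `1/r >= fold_threshold` gives
#' `reference_biased`, else `neither`. Boundaries are inclusive ("five-fold
#' or higher").
#'
#' @param counts A `pirna_counts` or count matrix (used for the all-zero
#'   reference test).
#' @param rpm RPM matrix (default [rpm_normalize()] of `counts`).
#' @param metadata Sample metadata covering the samples.
#' @param focus,reference Tissue labels; both must exist with >= 1 sample.
#' @param config A [filter_config()] (`fold_threshold`, `pseudocount`).
#' @param pirna_ids Optional subset (e.g. the focus tissue's consistently
#'   expressed set) to classify.
#' @return A data.frame per piRNA: medians in each tissue, the ratio and the
#'   fold class.
#' @export
fold_bias <- function(counts, rpm = NULL, metadata, focus, reference,
                      config = filter_config(), pirna_ids = NULL) {
  cm <- if (inherits(counts, "pirna_counts")) counts$counts else counts
  if (is.null(rpm)) rpm <- rpm_normalize(counts)
  groups <- tissue_groups(metadata, colnames(cm))
  abort_if(!focus %in% names(groups), "undefined tissue label '%s'", focus)
  abort_if(!reference %in% names(groups),
           "undefined tissue label '%s'", reference)
  if (!is.null(pirna_ids)) {
    cm <- cm[pirna_ids, , drop = FALSE]
    rpm <- rpm[pirna_ids, , drop = FALSE]
  }
  fs <- groups[[focus]]
  rs <- groups[[reference]]
  med_focus <- apply(rpm[, fs, drop = FALSE], 1L, stats::median)
  med_ref <- apply(rpm[, rs, drop = FALSE], 1L, stats::median)
  ref_zero <- med_ref == 0 & rowSums(cm[, rs, drop = FALSE]) == 0L

  pc <- config$pseudocount
  ratio <- (med_focus + pc) / (med_ref + pc)
  cls <- rep("neither", nrow(rpm))
  cls[ratio >= config$fold_threshold] <- "focus_biased"
  cls[(1 / ratio) >= config$fold_threshold] <- "reference_biased"
  cls[ref_zero] <- "not_detected_in_reference"
  ratio[ref_zero] <- NA_real_

  data.frame(
    pirna_id = rownames(rpm),
    median_focus_rpm = med_focus,
    median_reference_rpm = med_ref,
    ratio = ratio,
    fold_class = factor(cls, levels = c("focus_biased", "reference_biased",
                                        "neither",
                                        "not_detected_in_reference")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Median RPM per tissue
#'
#' @param rpm RPM matrix.
#' @param metadata Sample metadata.
#' @return Numeric matrix, piRNA x tissue, of median RPM values.
#' @export
tissue_medians <- function(rpm, metadata) {
  groups <- tissue_groups(metadata, colnames(rpm))
  med <- vapply(groups, function(ss) {
    apply(rpm[, ss, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(rpm)))
  rownames(med) <- rownames(rpm)
  med
}

#' Unsupervised hierarchical clustering of piRNAs
#'
#' Clusters the rows (piRNAs) of an expression matrix after a
#' `log2(RPM + 1)` variance-stabilizing transform (optional), using
#' `stats::hclust`. The full binary dendrogram is materialized as a list of
#' nodes with member leaves and merge heights.
#'
#' @param rpm RPM matrix (piRNAs x samples), at least two rows.
#' @param method Linkage method for [stats::hclust()] (default "average").
#' @param metric Distance metric: "euclidean" (default) or "correlation"
#'   (1 - Pearson, which errors on constant rows).
#' @param log_transform Apply `log2(x + 1)` first (default `TRUE`).
#' @return An object of class `pirna_dendrogram`: the `hclust` fit plus
#'   `nodes`, a list (by merge order, heights non-decreasing) of
#'   `list(id, height, members, children)` where `children` are node ids
#'   (negative = leaf index).
#' @export
hierarchical_cluster <- function(rpm, method = "average",
                                 metric = c("euclidean", "correlation"),
                                 log_transform = TRUE) {
  metric <- match.arg(metric)
  abort_if(nrow(rpm) < 2L, "need at least two piRNAs to cluster")
  x <- if (log_transform) log2(rpm + 1) else rpm
  if (metric == "euclidean") {
    d <- stats::dist(x)
  } else {
    sds <- apply(x, 1L, stats::sd)
    abort_if(any(sds == 0),
             "constant expression row(s) make correlation distance undefined; use metric = 'euclidean'")
    d <- stats::as.dist(1 - stats::cor(t(x)))
  }
  hc <- stats::hclust(d, method = method)
  structure(list(hclust = hc, labels = rownames(x),
                 nodes = dendrogram_nodes(hc)),
            class = "pirna_dendrogram")
}

# Materialize per-node member lists from an hclust merge matrix.
dendrogram_nodes <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1L)
  nodes <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- hc$merge[i, ]
    mem <- unlist(lapply(kids, function(k) {
      if (k < 0) hc$labels[-k] else members[[k]]
    }))
    members[[i]] <- mem
    nodes[[i]] <- list(id = i, height = hc$height[i], members = mem,
                       children = kids)
  }
  nodes
}

#' @export
print.pirna_dendrogram <- function(x, ...) {
  cat(sprintf("pirna_dendrogram: %d leaves, %d internal nodes (%s linkage)\n",
              length(x$labels), length(x$nodes), x$hclust$method))
  invisible(x)
}

#' Write a dendrogram in Newick format
#' @param dendrogram A [hierarchical_cluster()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "pirna_dendrogram"))
  phy <- ape::as.phylo(dendrogram$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Predicate: focus-enriched, highly expressed clade
#'
#' Operationalizes "highly and nearly exclusively expressed in the focus
#' tissue" for [extract_node()]: a leaf qualifies when its focus-tissue
#' median RPM is at least `min_focus_rpm` and at least `factor` times the
#' largest median among all other tissues (pseudocount added to both sides'
#' denominators); a node satisfies the predicate when all its members
#' qualify and it contains every qualifying leaf of the tree.
#'
#' @param rpm RPM matrix used for the clustering.
#' @param metadata Sample metadata.
#' @param focus Focus tissue.
#' @param factor Enrichment factor over the best other tissue (default 20).
#' @param min_focus_rpm Minimum focus-tissue median RPM (default 2000).
#' @param pseudocount Added to the other-tissue median before division
#'   (default 1 RPM).
#' @return A predicate function over dendrogram nodes.
#' @export
focus_enriched_predicate <- function(rpm, metadata, focus, factor = 20,
                                     min_focus_rpm = 2000, pseudocount = 1) {
  med <- tissue_medians(rpm, metadata)
  abort_if(!focus %in% colnames(med), "undefined tissue label '%s'", focus)
  other <- med[, setdiff(colnames(med), focus), drop = FALSE]
  best_other <- apply(other, 1L, max)
  qualifies <- med[, focus] >= min_focus_rpm &
    med[, focus] >= factor * (best_other + pseudocount)
  qualifying <- rownames(med)[qualifies]
  function(node) {
    all(node$members %in% qualifying) && all(qualifying %in% node$members)
  }
}

#' Extract a dendrogram node by predicate
#'
#' Evaluates `predicate` on every internal node and returns the satisfying
#' node with the fewest members; ties are broken by the smaller node id
#' (earlier merge). Returns `NULL` when no node satisfies the predicate
#' (not an error).
#'
#' @param dendrogram A [hierarchical_cluster()] result.
#' @param predicate Function taking a node (`list(id, height, members,
#'   children)`) and returning a logical scalar, e.g.
#'   [focus_enriched_predicate()].
#' @return The selected node, or `NULL`.
#' @export
extract_node <- function(dendrogram, predicate) {
  stopifnot(inherits(dendrogram, "pirna_dendrogram"))
  ok <- vapply(dendrogram$nodes, function(nd) isTRUE(predicate(nd)),
               logical(1))
  if (!any(ok)) return(NULL)
  cand <- dendrogram$nodes[ok]
  sizes <- vapply(cand, function(nd) length(nd$members), integer(1))
  ids <- vapply(cand, function(nd) nd$id, integer(1))
  cand[[order(sizes, ids)[1]]]
}

#' Locus profile of an extracted node
#'
#' Counts, among a node's member piRNAs, how many are single-locus and how
#' many have at least one locus overlapping a named region (e.g. an
#' imprinted-gene interval).
#'
#' @param node A node from [extract_node()] (or `NULL`).
#' @param annotation A [pirna_annotation()] covering the members.
#' @param region A [region_set()].
#' @return A list with `n_members`, `n_single_locus`, `n_in_region` and
#'   `detail` (per-member data.frame).
#' @export
node_region_report <- function(node, annotation, region) {
  if (is.null(node) || length(node$members) == 0L) {
    return(list(n_members = 0L, n_single_locus = 0L, n_in_region = 0L,
                detail = data.frame(pirna_id = character(),
                                    locus_count = integer(),
                                    in_region = logical())))
  }
  members <- node$members
  counts <- locus_count(annotation, members)
  loci <- loci_granges(annotation, members)
  hit <- overlaps_region(loci, region)
  owner <- S4Vectors::mcols(loci)$pirna_id
  in_region <- members %in% unique(owner[hit])
  detail <- data.frame(pirna_id = members,
                       locus_count = as.integer(counts),
                       in_region = in_region,
                       stringsAsFactors = FALSE)
  list(n_members = length(members),
       n_single_locus = sum(counts == 1L),
       n_in_region = sum(in_region),
       detail = detail)
}
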
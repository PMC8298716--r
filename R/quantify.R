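# Assignment of QC-passed reads to annotated piRNAs and expression
# normalization. Assignment is exact-sequence: a read counts towards a piRNA
# when it equals the annotated sequence or is a contiguous subsequence of it
# of at least pirna_min_len nucleotides. A read matching k > 1 distinct
# piRNAs increments each of the k counts (piRNA-level counting; a count is
# never multiplied by the piRNA's locus number).

#' Build the exact-match index for an annotation
#'
#' Enumerates every contiguous subsequence of length >= `pirna_min_len` of
#' every annotated piRNA sequence and maps it to the (unique) set of piRNA
#' ids containing it. Lookup of a read is then a single hashed match.
#'
#' @param annotation A [pirna_annotation()].
#' @param config A [filter_config()].
#' @return A list with `keys` (substring vector), `ids` (list of piRNA id
#'   vectors, parallel to `keys`) and `pirna_ids` (all annotation ids).
#' @keywords internal
build_match_index <- function(annotation, config = filter_config()) {
  seqs <- annotation$pirnas$sequence
  ids <- annotation$pirnas$pirna_id
  min_len <- config$pirna_min_len
  subs <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    L <- nchar(s)
    pieces <- character(0)
    for (l in seq.int(min_len, L)) {
      starts <- seq_len(L - l + 1L)
      pieces <- c(pieces, substring(s, starts, starts + l - 1L))
    }
    subs[[i]] <- unique(pieces)
  }
  key <- unlist(subs, use.names = FALSE)
  owner <- rep.int(ids, lengths(subs))
  map <- split(owner, key)
  map <- lapply(map, unique)
  list(keys = names(map), ids = unname(map), pirna_ids = ids)
}

#' Assign reads to annotated piRNAs
#'
#' @param read_sets A named list, one element per sample, each either a
#'   character vector of read sequences or a read data.frame with a
#'   `sequence` column (QC-passed piRNA candidates).
#' @param annotation A [pirna_annotation()]; must be non-empty.
#' @param config A [filter_config()].
#' @return An object of class `pirna_counts`: a list with `counts` (integer
#'   matrix, piRNA x sample, rows covering every annotated piRNA),
#'   `library_sizes` (per-sample number of assigned-eligible input reads,
#'   the RPM denominator) and `unassigned` (per-sample reads matching no
#'   piRNA).
#' @export
assign_reads <- function(read_sets, annotation, config = filter_config()) {
  abort_if(!inherits(annotation, "pirna_annotation") ||
             nrow(annotation$pirnas) == 0L,
           "annotation must be a non-empty pirna_annotation")
  abort_if(is.null(names(read_sets)) || any(!nzchar(names(read_sets))),
           "read_sets must be a named list (one element per sample)")
  abort_if(anyDuplicated(names(read_sets)) > 0L, "duplicate sample names")

  idx <- build_match_index(annotation, config)
  n_pirna <- length(idx$pirna_ids)
  samples <- names(read_sets)
  counts <- matrix(0L, nrow = n_pirna, ncol = length(samples),
                   dimnames = list(idx$pirna_ids, samples))
  library_sizes <- integer(length(samples))
  names(library_sizes) <- samples
  unassigned <- integer(length(samples))
  names(unassigned) <- samples

  row_of <- seq_len(n_pirna)
  names(row_of) <- idx$pirna_ids

  for (j in seq_along(read_sets)) {
    seqs <- read_sets[[j]]
    if (is.data.frame(seqs)) seqs <- seqs$sequence
    library_sizes[j] <- length(seqs)
    if (length(seqs) == 0L) next
    u <- unique(seqs)
    cnt <- tabulate(match(seqs, u), nbins = length(u))
    hit <- match(u, idx$keys)
    matched <- which(!is.na(hit))
    unassigned[j] <- sum(cnt[is.na(hit)])
    col <- counts[, j]
    for (k in matched) {
      rows <- row_of[idx$ids[[hit[k]]]]
      col[rows] <- col[rows] + cnt[k]
    }
    counts[, j] <- col
  }

  structure(
    list(counts = counts, library_sizes = library_sizes,
         unassigned = unassigned),
    class = "pirna_counts"
  )
}

#' @export
print.pirna_counts <- function(x, ...) {
  cat(sprintf("pirna_counts: %d piRNAs x %d samples; median library size %s\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' Reads-per-million normalization
#'
#' RPM = count x 1e6 / library size, per cell. The library size is the
#' number of QC-retained piRNA-candidate reads in the sample (the reads that
#' entered assignment), a reproducible proxy for "mapped reads".
#'
#' @param counts A `pirna_counts` from [assign_reads()], or a count matrix
#'   (then `library_sizes` must be given).
#' @param library_sizes Optional named per-sample totals when `counts` is a
#'   bare matrix.
#' @return A numeric RPM matrix of the same shape.
#' @export
rpm_normalize <- function(counts, library_sizes = NULL) {
  if (inherits(counts, "pirna_counts")) {
    library_sizes <- counts$library_sizes
    counts <- counts$counts
  }
  abort_if(is.null(library_sizes), "library_sizes required for a bare matrix")
  abort_if(!all(colnames(counts) %in% names(library_sizes)),
           "library_sizes must cover every sample column")
  library_sizes <- library_sizes[colnames(counts)]
  zero <- names(library_sizes)[library_sizes == 0]
  abort_if(length(zero) > 0L,
           "zero library size for sample '%s': RPM undefined", zero[1])
  sweep(counts, 2L, library_sizes, "/") * 1e6
}

#' Minimum sample count for a prevalence fraction
#'
#' `ceiling(frac * n_samples)`, floored at 1, so a 10% rule gives 3 of 30
#' samples and still requires 1 of 3 samples in a small cohort.
#'
#' @param n_samples Number of samples (>= 1).
#' @param frac Required fraction in (0, 1].
#' @return Integer threshold.
#' @export
min_sample_threshold <- function(n_samples, frac) {
  abort_if(!is_count(n_samples) || n_samples < 1, "n_samples must be >= 1")
  abort_if(frac <= 0 || frac > 1, "frac must be in (0, 1]")
  max(1L, as.integer(ceiling(frac * n_samples)))
}

#' Two-criterion consistent-expression filter
#'
#' A piRNA is kept iff (i) its read total over all samples reaches
#' `min_total_reads` and (ii) its RPM reaches `min_rpm` in at least
#' [min_sample_threshold()] samples. Both boundaries are inclusive.
#'
#' @param counts A `pirna_counts` (or integer matrix).
#' @param rpm The matching RPM matrix (defaults to [rpm_normalize()] of
#'   `counts`).
#' @param config A [filter_config()].
#' @param samples Optional character vector restricting the filter to a
#'   subset of samples (e.g. the focus-tissue cohort).
#' @return A list with `kept` (character vector of piRNA ids, matrix order)
#'   and `diagnostics`, a data.frame per piRNA recording the totals, the
#'   per-criterion outcomes and (for dropped piRNAs) which criterion failed.
#' @export
consistent_expression_filter <- function(counts, rpm = NULL,
                                         config = filter_config(),
                                         samples = NULL) {
  cm <- if (inherits(counts, "pirna_counts")) counts$counts else counts
  if (is.null(rpm)) rpm <- rpm_normalize(counts)
  abort_if(!identical(dim(cm), dim(rpm)) ||
             !identical(dimnames(cm), dimnames(rpm)),
           "counts and rpm matrices must share shape and dimnames")
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(cm))
    abort_if(length(missing) > 0L, "unknown sample(s): %s",
             paste(utils::head(missing, 3), collapse = ", "))
    cm <- cm[, samples, drop = FALSE]
    rpm <- rpm[, samples, drop = FALSE]
  }
  n_samples <- ncol(cm)
  abort_if(n_samples == 0L, "no samples to filter on")
  need_samples <- min_sample_threshold(n_samples, config$min_sample_frac)

  total_reads <- rowSums(cm)
  n_ge_rpm <- rowSums(rpm >= config$min_rpm)
  pass_reads <- total_reads >= config$min_total_reads
  pass_rpm <- n_ge_rpm >= need_samples
  kept <- pass_reads & pass_rpm

  failed <- rep(NA_character_, nrow(cm))
  failed[!pass_reads & !pass_rpm] <- "both"
  failed[!pass_reads & pass_rpm] <- "min_total_reads"
  failed[pass_reads & !pass_rpm] <- "min_rpm_prevalence"

  diagnostics <- data.frame(
    pirna_id = rownames(cm),
    total_reads = as.integer(total_reads),
    n_samples_ge_min_rpm = as.integer(n_ge_rpm),
    required_samples = need_samples,
    pass_total_reads = pass_reads,
    pass_rpm_prevalence = pass_rpm,
    kept = kept,
    failed_criterion = failed,
    stringsAsFactors = FALSE
  )
  rownames(diagnostics) <- NULL
  list(kept = rownames(cm)[kept], diagnostics = diagnostics)
}

#' Detected piRNAs
#'
#' "Detected" is defined as at least one assigned read in at least one of
#' the given samples (the loosest read-evidence rule; reported set sizes are
#' labelled with this definition).
#'
#' @param counts A `pirna_counts` or count matrix.
#' @param samples Optional sample subset.
#' @return Character vector of detected piRNA ids.
#' @export
detected_pirnas <- function(counts, samples = NULL) {
  cm <- if (inherits(counts, "pirna_counts")) counts$counts else counts
  if (!is.null(samples)) cm <- cm[, samples, drop = FALSE]
  rownames(cm)[rowSums(cm) > 0]
}
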
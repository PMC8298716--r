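# Read-level quality control: 3' adapter trimming, the 16-40 nt length
# window, the mean-Phred >= 20 floor, and the < 23 nt miRNA-length exclusion.

#' Trim a 3' adapter from reads
#'
#' Removes the 3'-most adapter match together with everything after it.
#' A match is either a full occurrence of the adapter anywhere in the read,
#' or an exact match of an adapter *prefix* of at least `min_overlap`
#' nucleotides ending flush at the read's 3' end (a partial adapter running
#' off the read). Qualities are trimmed in lockstep; reads without a match
#' are returned unchanged. A read that is pure adapter becomes empty (and is
#' later counted as `adapter_only` by [preprocess_reads()]).
#'
#' @param reads Read data.frame (`read_id`, `sequence`, `quality`).
#' @param adapter Adapter sequence (at least 5 nt).
#' @param min_overlap Minimum exact 3'-end overlap with the adapter prefix
#'   (default 5 nt).
#' @return The reads with trimmed `sequence`/`quality`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  abort_if(!is.character(adapter) || length(adapter) != 1L || nchar(adapter) < 5L,
           "adapter must be a single sequence of length >= 5")
  adapter <- toupper(adapter)
  alen <- nchar(adapter)
  n <- nchar(reads$sequence)
  # trim position = start of the 3'-most match (0 = no trim). A shorter
  # 3'-end overlap starts further 3', so scan overlap lengths smallest-first
  # and keep the first hit per read.
  cut_at <- integer(nrow(reads))
  if (nrow(reads) > 0L) {
    for (k in seq.int(min_overlap, min(alen, max(n, min_overlap)))) {
      cand <- cut_at == 0L & n >= k
      if (!any(cand)) next
      hit <- cand &
        substr(reads$sequence, n - k + 1L, n) == substr(adapter, 1L, k)
      cut_at[hit] <- n[hit] - k + 1L
    }
    # full adapter occurring internally (bases after it are also removed)
    full <- stringi::stri_locate_last_fixed(reads$sequence, adapter)[, 1]
    better <- !is.na(full) & full > cut_at
    cut_at[better] <- full[better]
  }

  trim <- cut_at > 0L
  if (any(trim)) {
    reads$sequence[trim] <- substr(reads$sequence[trim], 1L, cut_at[trim] - 1L)
    reads$quality[trim] <- substr(reads$quality[trim], 1L, cut_at[trim] - 1L)
  }
  reads
}

#' Length-window and quality filtering
#'
#' Retains reads with `min_read_len <= length <= max_read_len` and mean
#' per-base Phred score `>= min_mean_phred` (both boundaries inclusive).
#' Removal reasons are assigned in the fixed order too_short, too_long,
#' low_quality, so every removed read has exactly one reason.
#'
#' @param reads Read data.frame (adapter-trimmed).
#' @param config A [filter_config()].
#' @return A list with `reads` (retained) and `counts`, a named integer
#'   vector over `too_short`, `too_long`, `low_quality`, `retained`.
#' @export
qc_filter <- function(reads, config = filter_config()) {
  n <- nchar(reads$sequence)
  too_short <- n < config$min_read_len
  too_long <- !too_short & n > config$max_read_len
  mq <- phred_means(reads$quality)
  low_quality <- !too_short & !too_long &
    (is.nan(mq) | mq < config$min_mean_phred)
  keep <- !(too_short | too_long | low_quality)
  list(
    reads = reads[keep, , drop = FALSE],
    counts = c(too_short = sum(too_short), too_long = sum(too_long),
               low_quality = sum(low_quality), retained = sum(keep))
  )
}

#' Exclude miRNA-length reads
#'
#' Drops reads shorter than `pirna_min_len` (default 23 nt; "below 23" is
#' strict, so 23 nt reads are retained). Applied after [qc_filter()] so the
#' remaining reads are piRNA candidates.
#'
#' @param reads Read data.frame.
#' @param config A [filter_config()].
#' @return A list with `reads` (piRNA candidates) and `n_excluded`.
#' @export
exclude_mirna_length <- function(reads, config = filter_config()) {
  short <- nchar(reads$sequence) < config$pirna_min_len
  list(reads = reads[!short, , drop = FALSE], n_excluded = sum(short))
}

#' Full read preprocessing with a QC report
#'
#' Chains [trim_adapter()] (optional), an adapter-only check (reads empty
#' after trimming), [qc_filter()] and [exclude_mirna_length()]. The report
#' partitions the input: every read is counted under exactly one of
#' adapter_only, too_short, too_long, low_quality, mirna_length, retained.
#'
#' @param reads Read data.frame from [read_fastq()].
#' @param adapter 3' adapter sequence, or `NULL` to skip trimming.
#' @param config A [filter_config()].
#' @return A list of class `qc_result` with `reads` (retained piRNA
#'   candidates) and `report` (class `qc_report`: `n_input` plus the category
#'   counts).
#' @export
preprocess_reads <- function(reads, adapter = NULL, config = filter_config()) {
  n_input <- nrow(reads)
  if (!is.null(adapter)) {
    reads <- trim_adapter(reads, adapter)
  }
  adapter_only <- nchar(reads$sequence) == 0L
  n_adapter_only <- sum(adapter_only)
  reads <- reads[!adapter_only, , drop = FALSE]
  qc <- qc_filter(reads, config)
  mi <- exclude_mirna_length(qc$reads, config)
  counts <- c(
    adapter_only = n_adapter_only,
    qc$counts[c("too_short", "too_long", "low_quality")],
    mirna_length = mi$n_excluded,
    retained = nrow(mi$reads)
  )
  names(counts) <- c("adapter_only", "too_short", "too_long", "low_quality",
                     "mirna_length", "retained")
  stopifnot(sum(counts) == n_input)  # partition property
  structure(
    list(reads = mi$reads,
         report = structure(list(n_input = n_input, counts = counts),
                            class = "qc_report")),
    class = "qc_result"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d input reads\n", x$n_input))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-13s %10d (%5.1f%%)\n", nm, x$counts[[nm]],
                if (x$n_input > 0) 100 * x$counts[[nm]] / x$n_input else 0))
  }
  invisible(x)
}
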
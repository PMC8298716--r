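#' Filtering and threshold configuration
#'
#' Collects every threshold used across the workflow in one validated object:
#' the read length window, the Phred quality floor, the miRNA-length
#' exclusion cut-off, the two-criterion consistent-expression filter
#' (total reads and RPM prevalence), the median fold-change threshold for
#' tissue bias calls, and the locus-multiplicity bin edges.
#'
#' Defaults encode the workflow's standard small RNA settings: reads are kept
#' when 16-40 nt long with mean Phred >= 20; reads shorter than 23 nt are
#' treated as miRNA-length and excluded from piRNA assignment; a piRNA is
#' "consistently expressed" when covered by >= 10 reads summed over the cohort
#' and reaching >= 1 RPM in at least 10% of samples (minimum one sample);
#' tissue bias requires a five-fold or higher median RPM ratio; multiplicity
#' bins are 1, 2-9, 10-100 and > 100 genomic loci.
#'
#' @param min_read_len Minimum retained read length (nt).
#' @param max_read_len Maximum retained read length (nt).
#' @param pirna_min_len Minimum piRNA-candidate length (nt); shorter reads are
#'   excluded as likely miRNAs.
#' @param min_mean_phred Minimum mean per-base Phred score of a retained read.
#' @param min_total_reads Minimum read total across all samples for the
#'   consistent-expression filter.
#' @param min_rpm Minimum RPM counted towards the prevalence criterion.
#' @param min_sample_frac Fraction of samples that must reach `min_rpm`.
#' @param fold_threshold Median fold-change ratio declaring tissue bias.
#' @param multiplicity_bins Upper edges of the first three multiplicity bins;
#'   `c(1, 9, 100)` gives bins 1 ("single"), 2-9 ("oligo"), 10-100 ("mid")
#'   and > 100 ("high").
#' @param pseudocount Pseudocount (RPM) added to medians in fold-change
#'   ratios. The default 0 routes all-zero reference cases to a dedicated
#'   "not detected in reference" class instead of dividing by zero.
#' @return An object of class `filter_config` (a named list).
#' @examples
#' cfg <- filter_config()
#' cfg$min_total_reads
#' @export
filter_config <- function(min_read_len = 16L,
                          max_read_len = 40L,
                          pirna_min_len = 23L,
                          min_mean_phred = 20,
                          min_total_reads = 10L,
                          min_rpm = 1.0,
                          min_sample_frac = 0.10,
                          fold_threshold = 5.0,
                          multiplicity_bins = c(1L, 9L, 100L),
                          pseudocount = 0) {
  abort_if(!is_count(min_read_len) || min_read_len < 1,
           "min_read_len must be a positive integer")
  abort_if(!is_count(max_read_len) || max_read_len < 1,
           "max_read_len must be a positive integer")
  abort_if(!is_count(pirna_min_len) || pirna_min_len < 1,
           "pirna_min_len must be a positive integer")
  abort_if(min_read_len > pirna_min_len || pirna_min_len > max_read_len,
           "need min_read_len <= pirna_min_len <= max_read_len (got %d <= %d <= %d)",
           min_read_len, pirna_min_len, max_read_len)
  abort_if(min_mean_phred < 0, "min_mean_phred must be >= 0")
  abort_if(min_total_reads < 0, "min_total_reads must be >= 0")
  abort_if(min_rpm < 0, "min_rpm must be >= 0")
  abort_if(min_sample_frac <= 0 || min_sample_frac > 1,
           "min_sample_frac must be in (0, 1]")
  abort_if(fold_threshold < 0, "fold_threshold must be >= 0")
  abort_if(length(multiplicity_bins) != 3L || any(diff(multiplicity_bins) <= 0),
           "multiplicity_bins must be three strictly increasing bin edges")
  abort_if(pseudocount < 0, "pseudocount must be >= 0")

  structure(
    list(
      min_read_len = as.integer(min_read_len),
      max_read_len = as.integer(max_read_len),
      pirna_min_len = as.integer(pirna_min_len),
      min_mean_phred = min_mean_phred,
      min_total_reads = as.integer(min_total_reads),
      min_rpm = min_rpm,
      min_sample_frac = min_sample_frac,
      fold_threshold = fold_threshold,
      multiplicity_bins = as.integer(multiplicity_bins),
      pseudocount = pseudocount
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("piRNA workflow thresholds:\n")
  cat(sprintf("  read length window   : %d-%d nt\n", x$min_read_len, x$max_read_len))
  cat(sprintf("  mean Phred floor     : %g\n", x$min_mean_phred))
  cat(sprintf("  miRNA-length cutoff  : < %d nt excluded\n", x$pirna_min_len))
  cat(sprintf("  consistent expression: >= %d reads total and >= %g RPM in >= %g%% of samples\n",
              x$min_total_reads, x$min_rpm, 100 * x$min_sample_frac))
  cat(sprintf("  fold-bias threshold  : %g-fold median RPM\n", x$fold_threshold))
  e <- x$multiplicity_bins
  cat(sprintf("  multiplicity bins    : 1 | %d-%d | %d-%d | >%d loci\n",
              e[1] + 1L, e[2], e[2] + 1L, e[3], e[3]))
  invisible(x)
}

# Canonical ordered bin labels: single = 1 locus, oligo = up to the second
# edge, mid = up to the third edge, high = beyond it.
multiplicity_bin_labels <- function(config = NULL) {
  c("single", "oligo", "mid", "high")
}
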
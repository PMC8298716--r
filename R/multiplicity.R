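# Locus multiplicity: how many genomic locations a piRNA maps to, binned as
# single (1), oligo (2-9), mid (10-100) and high (> 100) by default, plus
# membership of piRNA loci in named region sets (piRNA clusters,
# mitochondrial genome, imprinted regions).

#' Number of distinct loci of a piRNA
#'
#' @param annotation A [pirna_annotation()].
#' @param pirna_ids Ids to query (default: all).
#' @return Named integer vector of distinct-locus counts.
#' @export
locus_count <- function(annotation, pirna_ids = NULL) {
  stopifnot(inherits(annotation, "pirna_annotation"))
  counts <- stats::setNames(annotation$pirnas$n_loci, annotation$pirnas$pirna_id)
  if (is.null(pirna_ids)) return(counts)
  missing <- setdiff(pirna_ids, names(counts))
  abort_if(length(missing) > 0L, "unknown piRNA id(s): %s",
           paste(utils::head(missing, 3), collapse = ", "))
  counts[pirna_ids]
}

#' Classify locus counts into multiplicity bins
#'
#' @param count Integer vector of locus counts (all >= 1).
#' @param config A [filter_config()] supplying the bin edges.
#' @return Factor with ordered levels `single`, `oligo`, `mid`, `high`.
#' @examples
#' classify_multiplicity(c(1, 9, 10, 100, 101))
#' @export
classify_multiplicity <- function(count, config = filter_config()) {
  abort_if(any(count < 1), "locus counts must be >= 1")
  e <- config$multiplicity_bins
  labels <- multiplicity_bin_labels(config)
  idx <- findInterval(count, c(e, Inf), left.open = TRUE) + 1L
  factor(labels[idx], levels = labels)
}

#' Does a locus overlap a region set?
#'
#' True iff the interval intersects (>= 1 bp, half-open abutment excluded)
#' any region of the set on the same chromosome. Strand is ignored.
#'
#' @param loci A `GRanges` of loci (vectorized).
#' @param regions A [region_set()] or `GRanges`.
#' @return Logical vector along `loci`.
#' @export
overlaps_region <- function(loci, regions) {
  gr <- if (inherits(regions, "region_set")) regions$regions else regions
  if (length(gr) == 0L || length(loci) == 0L) {
    return(rep(FALSE, length(loci)))
  }
  # seqlevel sets may legitimately differ between query and region set
  suppressWarnings(IRanges::overlapsAny(loci, gr, ignore.strand = TRUE))
}

#' Region membership of a piRNA set
#'
#' Flags each piRNA whose loci overlap each named region set; the
#' mitochondrial flag is any locus on chromosome `"chrM"`. Totals are
#' reported per flag, optionally as a rounded percentage of a reference
#' count (e.g. expressed mitochondrial piRNAs as a percent of all annotated
#' mitochondrial piRNA loci).
#'
#' @param annotation A [pirna_annotation()].
#' @param region_sets A list of [region_set()] objects (possibly empty).
#' @param pirna_ids The analysed set (default: all annotated piRNAs).
#' @param reference_counts Optional named numeric vector; for each name
#'   matching a flag (a region-set name or `"mitochondrial"`), the total is
#'   also expressed as `round(100 * total / reference)`.
#' @return A list of class `membership_report`: `flags` (data.frame, one row
#'   per piRNA), `totals` (named integer) and `percent_of_reference`
#'   (named numeric, possibly empty).
#' @export
membership_report <- function(annotation, region_sets = list(),
                              pirna_ids = NULL, reference_counts = NULL) {
  stopifnot(inherits(annotation, "pirna_annotation"))
  if (is.null(pirna_ids)) pirna_ids <- annotation$pirnas$pirna_id
  abort_if(length(pirna_ids) == 0L, "analysed piRNA set is empty")
  loci <- loci_granges(annotation, pirna_ids)
  owner <- S4Vectors::mcols(loci)$pirna_id

  flags <- data.frame(pirna_id = pirna_ids, stringsAsFactors = FALSE)
  flags$mitochondrial <- pirna_ids %in%
    unique(owner[as.character(GenomicRanges::seqnames(loci)) == "chrM"])
  for (rs in region_sets) {
    stopifnot(inherits(rs, "region_set"))
    hit <- overlaps_region(loci, rs)
    flags[[rs$name]] <- pirna_ids %in% unique(owner[hit])
  }
  totals <- vapply(flags[-1], sum, integer(1))

  pct <- numeric(0)
  if (!is.null(reference_counts)) {
    common <- intersect(names(reference_counts), names(totals))
    pct <- stats::setNames(
      round(100 * totals[common] / reference_counts[common]),
      common
    )
  }
  structure(list(flags = flags, totals = totals,
                 percent_of_reference = pct),
            class = "membership_report")
}

#' @export
print.membership_report <- function(x, ...) {
  cat(sprintf("membership_report over %d piRNAs:\n", nrow(x$flags)))
  for (nm in names(x$totals)) {
    extra <- if (nm %in% names(x$percent_of_reference)) {
      sprintf(" (%d%% of reference)", x$percent_of_reference[[nm]])
    } else ""
    cat(sprintf("  %-16s %d%s\n", nm, x$totals[[nm]], extra))
  }
  invisible(x)
}

#' Multiplicity report for a piRNA set
#'
#' Bins each analysed piRNA by its locus count, tallies distinct loci per
#' chromosome, and counts the distinct genomic locations contributed by
#' piRNAs below a multiplicity ceiling. Distinct-locus counting
#' de-duplicates identical intervals (chromosome, start, end) across piRNAs.
#'
#' @param annotation A [pirna_annotation()].
#' @param pirna_ids The analysed set (default: all).
#' @param config A [filter_config()].
#' @param multiplicity_ceiling Distinct loci are additionally totalled over
#'   piRNAs with `locus_count < multiplicity_ceiling` (default 10, i.e. the
#'   single and oligo bins).
#' @return A list of class `multiplicity_report`: `per_pirna` (data.frame
#'   with `pirna_id`, `locus_count`, `bin`), `bin_totals` (named integer over
#'   the four bins), `chromosome_tally` (distinct loci per chromosome),
#'   `n_distinct_loci` (over the whole analysed set) and
#'   `n_distinct_loci_below_ceiling`.
#' @export
multiplicity_report <- function(annotation, pirna_ids = NULL,
                                config = filter_config(),
                                multiplicity_ceiling = 10L) {
  stopifnot(inherits(annotation, "pirna_annotation"))
  if (is.null(pirna_ids)) pirna_ids <- annotation$pirnas$pirna_id
  abort_if(length(pirna_ids) == 0L, "analysed piRNA set is empty")
  counts <- locus_count(annotation, pirna_ids)
  bins <- classify_multiplicity(counts, config)
  per_pirna <- data.frame(pirna_id = pirna_ids,
                          locus_count = as.integer(counts),
                          bin = bins, stringsAsFactors = FALSE)
  bin_totals <- stats::setNames(as.integer(table(bins)), levels(bins))
  stopifnot(sum(bin_totals) == length(pirna_ids))  # partition

  loci <- annotation$loci[annotation$loci$pirna_id %in% pirna_ids, ,
                          drop = FALSE]
  loc_key <- paste(loci$chrom, loci$start, loci$end, sep = "\r")
  distinct <- !duplicated(loc_key)
  chromosome_tally <- sort(table(loci$chrom[distinct]), decreasing = TRUE)
  chromosome_tally <- stats::setNames(as.integer(chromosome_tally),
                                      names(chromosome_tally))

  below <- pirna_ids[counts < multiplicity_ceiling]
  loci_b <- loci[loci$pirna_id %in% below, , drop = FALSE]
  n_below <- length(unique(paste(loci_b$chrom, loci_b$start, loci_b$end,
                                 sep = "\r")))

  structure(
    list(per_pirna = per_pirna,
         bin_totals = bin_totals,
         chromosome_tally = chromosome_tally,
         n_distinct_loci = sum(distinct),
         multiplicity_ceiling = as.integer(multiplicity_ceiling),
         n_distinct_loci_below_ceiling = n_below),
    class = "multiplicity_report"
  )
}

#' @export
print.multiplicity_report <- function(x, ...) {
  cat(sprintf("multiplicity_report over %d piRNAs:\n", nrow(x$per_pirna)))
  cat("  bins:", paste(sprintf("%s=%d", names(x$bin_totals), x$bin_totals),
                       collapse = ", "), "\n")
  cat(sprintf("  distinct loci: %d (%d from piRNAs with < %d loci)\n",
              x$n_distinct_loci, x$n_distinct_loci_below_ceiling,
              x$multiplicity_ceiling))
  invisible(x)
}
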
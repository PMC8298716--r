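# The piRNA annotation: one record per piRNA id carrying its mature sequence
# and the set of genomic loci it maps to. The on-disk format is a single
# merged TSV (chrom, start, end, pirna_id, sequence, strand; BED-convention
# coordinates; one row per locus), so the synthetic generator, readers and
# quantifier share one dialect.

#' Construct a piRNA annotation from a locus table
#'
#' @param loci A data.frame with columns `pirna_id`, `sequence`, `chrom`,
#'   `start`, `end`, `strand` (internal 1-based closed coordinates; one row
#'   per locus). Duplicate identical loci are collapsed; conflicting
#'   sequences for one id are an error.
#' @param config A [filter_config()]; piRNA sequence lengths must lie within
#'   `[pirna_min_len, max_read_len]`.
#' @return An object of class `pirna_annotation` with elements `pirnas`
#'   (one row per piRNA: `pirna_id`, `sequence`, `n_loci`, sorted by id) and
#'   `loci` (one row per distinct locus, sorted by id then coordinate).
#' @export
pirna_annotation <- function(loci, config = filter_config()) {
  req <- c("pirna_id", "sequence", "chrom", "start", "end", "strand")
  abort_if(!all(req %in% names(loci)),
           "annotation table must have columns: %s", paste(req, collapse = ", "))
  abort_if(nrow(loci) == 0L, "annotation must contain at least one locus")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  loci$start <- as.integer(unname(loci$start))
  loci$end <- as.integer(unname(loci$end))
  loci$pirna_id <- unname(loci$pirna_id)
  loci$sequence <- toupper(chartr("U", "T", unname(loci$sequence)))
  loci$chrom <- unname(loci$chrom)
  loci$strand <- unname(loci$strand)
  abort_if(any(!grepl("^[ACGT]+$", loci$sequence)),
           "piRNA sequences must be over the alphabet {A, C, G, T/U}")
  abort_if(any(!nzchar(loci$chrom)), "empty chromosome name in annotation")
  abort_if(any(loci$end < loci$start),
           "annotation locus with end < start for piRNA '%s'",
           loci$pirna_id[which(loci$end < loci$start)[1]])
  abort_if(any(loci$start < 1L), "annotation locus start below the origin")
  abort_if(!all(loci$strand %in% c("+", "-", "*")),
           "strand must be one of '+', '-', '*'")

  # sequence must be consistent across the rows of one id
  seq_by_id <- tapply(loci$sequence, loci$pirna_id, function(s) length(unique(s)))
  conflict <- names(seq_by_id)[seq_by_id > 1L]
  abort_if(length(conflict) > 0L,
           "conflicting sequences for piRNA id '%s'", conflict[1])

  # de-duplicate identical intervals within an id; order-invariant layout
  key <- paste(loci$pirna_id, loci$chrom, loci$start, loci$end, loci$strand,
               sep = "\r")
  loci <- loci[!duplicated(key), , drop = FALSE]
  ord <- order(loci$pirna_id, loci$chrom, loci$start, loci$end, loci$strand)
  loci <- loci[ord, req, drop = FALSE]
  rownames(loci) <- NULL

  first <- !duplicated(loci$pirna_id)
  pirnas <- data.frame(
    pirna_id = loci$pirna_id[first],
    sequence = loci$sequence[first],
    n_loci = as.integer(table(loci$pirna_id)[loci$pirna_id[first]]),
    stringsAsFactors = FALSE
  )
  rownames(pirnas) <- NULL

  len <- nchar(pirnas$sequence)
  bad <- len < config$pirna_min_len | len > config$max_read_len
  abort_if(any(bad),
           "piRNA '%s' sequence length %d outside [%d, %d]",
           pirnas$pirna_id[which(bad)[1]], len[which(bad)[1]],
           config$pirna_min_len, config$max_read_len)

  structure(list(pirnas = pirnas, loci = loci), class = "pirna_annotation")
}

#' @export
print.pirna_annotation <- function(x, ...) {
  cat(sprintf("pirna_annotation: %d piRNAs over %d loci (%d chromosomes)\n",
              nrow(x$pirnas), nrow(x$loci), length(unique(x$loci$chrom))))
  invisible(x)
}

#' Read a merged piRNA annotation TSV
#'
#' The file is tab-separated with columns `chrom`, `start`, `end`,
#' `pirna_id`, `sequence`, `strand` and BED-convention (0-based half-open)
#' coordinates; multiple rows per `pirna_id` encode multiple loci. Rows with
#' the same id are merged into one record; identical duplicate rows collapse
#' to one locus; conflicting sequences for an id are an error. The result is
#' independent of the input row order.
#'
#' @param path Path to the annotation TSV.
#' @param config A [filter_config()] used for sequence-length validation.
#' @return A [pirna_annotation()].
#' @export
read_annotation <- function(path, config = filter_config()) {
  abort_if(!file.exists(path), "annotation file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "pirna_id", "sequence", "strand")
  abort_if(!all(req %in% names(tab)),
           "annotation TSV '%s' must have columns: %s", path,
           paste(req, collapse = ", "))
  abort_if(!is.numeric(tab$start) || !is.numeric(tab$end),
           "annotation TSV '%s': non-numeric coordinates", path)
  abort_if(any(tab$end <= tab$start),
           "annotation TSV '%s': end <= start for piRNA '%s'",
           path, tab$pirna_id[which(tab$end <= tab$start)[1]])
  abort_if(any(tab$start < 0), "annotation TSV '%s': negative start", path)
  tab$start <- as.integer(tab$start) + 1L  # BED 0-based half-open -> 1-based closed
  tab$end <- as.integer(tab$end)
  pirna_annotation(tab, config = config)
}

#' Write a piRNA annotation as a merged TSV
#'
#' Emits BED-convention coordinates (0-based half-open), one row per locus.
#'
#' @param annotation A [pirna_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "pirna_annotation"))
  out <- annotation$loci[, c("chrom", "start", "end", "pirna_id", "sequence",
                             "strand")]
  out$start <- out$start - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Loci of an annotation as GRanges
#'
#' @param annotation A [pirna_annotation()].
#' @param pirna_ids Optional character vector restricting to a subset of
#'   piRNAs (e.g. the consistently expressed set).
#' @return A `GRanges` with metadata column `pirna_id`.
#' @export
loci_granges <- function(annotation, pirna_ids = NULL) {
  stopifnot(inherits(annotation, "pirna_annotation"))
  loci <- annotation$loci
  if (!is.null(pirna_ids)) {
    missing <- setdiff(pirna_ids, annotation$pirnas$pirna_id)
    abort_if(length(missing) > 0L,
             "unknown piRNA id(s): %s", paste(utils::head(missing, 3), collapse = ", "))
    loci <- loci[loci$pirna_id %in% pirna_ids, , drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = loci$strand
  )
  S4Vectors::mcols(gr)$pirna_id <- loci$pirna_id
  gr
}

#' Subset an annotation to a set of piRNA ids
#' @param annotation A [pirna_annotation()].
#' @param pirna_ids Character vector of ids to keep.
#' @param config A [filter_config()] (revalidation).
#' @return A `pirna_annotation` restricted to `pirna_ids`.
#' @export
subset_annotation <- function(annotation, pirna_ids, config = filter_config()) {
  stopifnot(inherits(annotation, "pirna_annotation"))
  missing <- setdiff(pirna_ids, annotation$pirnas$pirna_id)
  abort_if(length(missing) > 0L,
           "unknown piRNA id(s): %s", paste(utils::head(missing, 3), collapse = ", "))
  pirna_annotation(
    annotation$loci[annotation$loci$pirna_id %in% pirna_ids, , drop = FALSE],
    config = config
  )
}
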
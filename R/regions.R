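# Named genomic region sets (piRNA clusters, mitochondrial genome, imprinted
# regions). Intervals are held as GRanges (1-based, closed); BED files are
# converted at the reader/writer boundary so external coordinates stay in the
# 0-based half-open BED dialect.

#' Construct a named region set
#'
#' @param name Label for the set (e.g. `"piRNA_clusters"`, `"MEG8"`).
#' @param regions A [GenomicRanges::GRanges] of the member intervals. Widths
#'   must be at least 1 bp; strand is stored but ignored by overlap queries.
#' @return An object of class `region_set`.
#' @export
region_set <- function(name, regions) {
  abort_if(!is.character(name) || length(name) != 1L || !nzchar(name),
           "region set name must be a non-empty string")
  abort_if(!methods::is(regions, "GRanges"), "regions must be a GRanges")
  validate_intervals(regions, what = sprintf("region set '%s'", name))
  structure(list(name = name, regions = regions), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d interval(s) on %d chromosome(s)\n",
              x$name, length(x$regions),
              length(unique(as.character(GenomicRanges::seqnames(x$regions))))))
  invisible(x)
}

# Shared interval sanity checks (end > start in half-open terms means
# width >= 1 here; chromosome names non-empty).
validate_intervals <- function(gr, what = "intervals") {
  abort_if(any(GenomicRanges::width(gr) < 1L),
           "%s: zero- or negative-width interval (BED end must exceed start)", what)
  abort_if(any(GenomicRanges::start(gr) < 1L),
           "%s: interval start below the origin", what)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  abort_if(any(!nzchar(chroms)), "%s: empty chromosome name", what)
  invisible(TRUE)
}

#' Read a BED3+ file as a region set
#'
#' Comment (`#`), `track` and `browser` lines are skipped. Coordinates are
#' interpreted as 0-based half-open (BED convention) and converted to the
#' internal 1-based representation. Rows with `end <= start` are rejected.
#'
#' @param path Path to a BED file.
#' @param name Name for the resulting [region_set()].
#' @return A `region_set`.
#' @export
read_bed <- function(path, name) {
  abort_if(!file.exists(path), "BED file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^\\s*(#|track\\b|browser\\b)", lines)
  if (!any(keep)) {
    return(region_set(name, GenomicRanges::GRanges()))
  }
  tf <- tempfile(fileext = ".bed")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines[keep], tf)
  gr <- tryCatch(
    rtracklayer::import(tf, format = "BED"),
    error = function(e) {
      stop(sprintf("failed to parse BED file '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  gr <- methods::as(gr, "GRanges")
  S4Vectors::mcols(gr) <- NULL
  validate_intervals(gr, what = sprintf("BED file '%s'", path))
  region_set(name, gr)
}

#' Write a region set as BED3+
#'
#' Coordinates are emitted in BED convention (0-based half-open).
#'
#' @param regions A [region_set()] or a `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  gr <- if (inherits(regions, "region_set")) regions$regions else regions
  abort_if(!methods::is(gr, "GRanges"), "regions must be a region_set or GRanges")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
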
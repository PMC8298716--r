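# FASTQ reading/writing and Phred+33 quality helpers.
#
# Reads are carried through the workflow as a plain data.frame with columns
# read_id, sequence and quality (the Phred+33 encoded string). This keeps
# per-sample libraries of a few hundred thousand short reads cheap to
# manipulate with vectorized string operations.

#' Read a FASTQ file (Phred+33)
#'
#' Parses a four-line-per-record FASTQ file into a data.frame of reads.
#' Malformed files are rejected with an error naming the offending line;
#' records whose sequence and quality strings differ in length are rejected
#' with an error naming the record.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A data.frame with character columns `read_id`, `sequence`,
#'   `quality`, in file order. An empty file yields zero rows.
#' @seealso [write_fastq()], [phred_means()]
#' @export
read_fastq <- function(path) {
  abort_if(!file.exists(path), "FASTQ file not found: %s", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  abort_if(n %% 4L != 0L,
           "malformed FASTQ '%s': %d lines is not a multiple of 4 (truncated record near line %d)",
           path, n, 4L * (n %/% 4L) + 1L)
  hdr <- lines[seq.int(1L, n, by = 4L)]
  seqs <- lines[seq.int(2L, n, by = 4L)]
  sep <- lines[seq.int(3L, n, by = 4L)]
  qual <- lines[seq.int(4L, n, by = 4L)]

  bad <- which(!startsWith(hdr, "@"))
  abort_if(length(bad) > 0L,
           "malformed FASTQ '%s': line %d does not start with '@'",
           path, 4L * (bad[1] - 1L) + 1L)
  bad <- which(!startsWith(sep, "+"))
  abort_if(length(bad) > 0L,
           "malformed FASTQ '%s': line %d does not start with '+'",
           path, 4L * (bad[1] - 1L) + 3L)
  bad <- which(nchar(seqs) != nchar(qual))
  abort_if(length(bad) > 0L,
           "malformed FASTQ '%s': record '%s' (line %d) has %d sequence bases but %d quality characters",
           path, sub("^@", "", hdr[bad[1]]), 4L * (bad[1] - 1L) + 2L,
           nchar(seqs[bad[1]]), nchar(qual[bad[1]]))

  ids <- substring(hdr, 2L)
  ids <- sub("[ \t].*$", "", ids)
  data.frame(read_id = ids, sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads A data.frame with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  abort_if(any(nchar(reads$sequence) != nchar(reads$quality)),
           "sequence/quality length mismatch in reads to be written")
  n <- nrow(reads)
  out <- character(4L * n)
  if (n > 0L) {
    out[seq.int(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_id)
    out[seq.int(2L, by = 4L, length.out = n)] <- reads$sequence
    out[seq.int(3L, by = 4L, length.out = n)] <- "+"
    out[seq.int(4L, by = 4L, length.out = n)] <- reads$quality
  }
  writeLines(out, path)
  invisible(path)
}

#' Mean Phred score per read
#'
#' Decodes Phred+33 quality strings and returns each read's mean per-base
#' score. Vectorized over the whole library (one `charToRaw` pass).
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean scores; `NaN` for zero-length reads.
#' @export
phred_means <- function(quality) {
  n <- nchar(quality)
  out <- rep.int(NaN, length(quality))
  keep <- n > 0L
  if (!any(keep)) return(out)
  scores <- as.integer(charToRaw(paste(quality[keep], collapse = ""))) - 33L
  ends <- cumsum(n[keep])
  starts <- c(1L, ends[-length(ends)] + 1L)
  cs <- c(0, cumsum(scores))
  out[keep] <- (cs[ends + 1L] - cs[starts]) / n[keep]
  out
}

#' Decode a Phred+33 quality string to integer scores
#' @param quality A single quality string.
#' @return Integer vector of per-base Phred scores.
#' @export
phred_decode <- function(quality) {
  stopifnot(length(quality) == 1L)
  if (nchar(quality) == 0L) return(integer())
  as.integer(charToRaw(quality)) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores Integer vector of Phred scores in \[0, 60\].
#' @return A single quality string.
#' @export
phred_encode <- function(scores) {
  abort_if(any(scores < 0 | scores > 60), "Phred scores must lie in [0, 60]")
  if (length(scores) == 0L) return("")
  rawToChar(as.raw(as.integer(scores) + 33L))
}
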
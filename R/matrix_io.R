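# TSV readers/writers for expression matrices and sample metadata.

#' Write a piRNA x sample matrix as TSV
#'
#' The first column holds the piRNA ids (`pirna_id`); remaining columns are
#' samples. Values are written at full double precision so RPM matrices
#' round-trip within 1e-9 relative error and integer counts round-trip
#' exactly.
#'
#' @param m A matrix with row names (piRNA ids) and column names (samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  abort_if(is.null(rownames(m)) || is.null(colnames(m)),
           "matrix must have row and column names")
  abort_if(anyDuplicated(rownames(m)) > 0L, "duplicate row (piRNA) ids")
  abort_if(anyDuplicated(colnames(m)) > 0L, "duplicate column (sample) ids")
  df <- data.frame(pirna_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a piRNA x sample matrix from TSV
#'
#' Inverse of [write_matrix()]; expects `pirna_id` as the first column.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with piRNA row names and sample column names.
#' @export
read_matrix <- function(path) {
  abort_if(!file.exists(path), "matrix file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  abort_if(names(df)[1] != "pirna_id",
           "matrix TSV '%s' must have 'pirna_id' as its first column", path)
  abort_if(anyDuplicated(df$pirna_id) > 0L,
           "matrix TSV '%s' has duplicate piRNA ids", path)
  abort_if(anyDuplicated(names(df)[-1]) > 0L,
           "matrix TSV '%s' has duplicate sample columns", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$pirna_id
  storage.mode(m) <- "double"
  m
}

#' Read a sample metadata TSV
#'
#' @param path TSV with columns `sample_id` and `tissue` (an optional `group`
#'   column is carried through).
#' @return A data.frame with unique `sample_id` and non-empty `tissue`.
#' @export
read_sample_metadata <- function(path) {
  abort_if(!file.exists(path), "metadata file not found: %s", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_metadata(md)
  md
}

#' Write a sample metadata TSV
#' @param metadata Data.frame with `sample_id`, `tissue` (+ optional columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  validate_sample_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_sample_metadata <- function(md) {
  abort_if(!all(c("sample_id", "tissue") %in% names(md)),
           "sample metadata must have columns 'sample_id' and 'tissue'")
  abort_if(anyDuplicated(md$sample_id) > 0L, "duplicate sample ids in metadata")
  abort_if(any(!nzchar(md$tissue)), "empty tissue label in metadata")
  invisible(TRUE)
}
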
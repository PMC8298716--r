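# Readers and writers: FASTQ, BED, merged annotation TSV, matrix TSV,
# sample metadata. Round-trip identity and order-invariance.

test_that("read_fastq parses minimal records and preserves order", {
  tf <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2 extra comment", "ACGTA", "+", "IIIIJ"), tf)
  reads <- read_fastq(tf)
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$read_id, c("r1", "r2"))
  expect_equal(reads$sequence[1], "ACGT")
  expect_equal(phred_decode(reads$quality[1]), rep(40L, 4))
  expect_equal(phred_means(reads$quality), c(40, 40.2))
})

test_that("read_fastq of an empty file yields zero reads", {
  tf <- tempfile(fileext = ".fastq")
  file.create(tf)
  expect_equal(nrow(read_fastq(tf)), 0L)
})

test_that("malformed FASTQ errors name the offending line or record", {
  tf <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), tf)
  expect_error(read_fastq(tf), "line 5")
  writeLines(c("@r1", "ACGT", "+", "III"), tf)
  expect_error(read_fastq(tf), "r1")
  writeLines(c("r1", "ACGT", "+", "IIII"), tf)
  expect_error(read_fastq(tf), "line 1")
})

test_that("FASTQ writer/reader round-trips random libraries", {
  for (i in 1:5) {
    reads <- with_seed(i, {
      n <- sample(1:40, 1)
      seqs <- vapply(sample(16:40, n, replace = TRUE), function(l) {
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
              collapse = "")
      }, character(1))
      data.frame(read_id = paste0("read", seq_len(n)), sequence = seqs,
                 quality = vapply(nchar(seqs), function(l) {
                   phred_encode(sample(0:40, l, replace = TRUE))
                 }, character(1)),
                 stringsAsFactors = FALSE)
    })
    tf <- tempfile(fileext = ".fastq")
    write_fastq(reads, tf)
    expect_equal(read_fastq(tf), reads)
  }
})

test_that("read_bed applies BED half-open convention and skips comments", {
  tf <- tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=clusters",
               "chr14\t1000\t2000", "chr2\t0\t30"), tf)
  rs <- read_bed(tf, "clusters")
  expect_s3_class(rs, "region_set")
  expect_equal(length(rs$regions), 2L)
  expect_equal(GenomicRanges::width(rs$regions), c(1000L, 30L))
  expect_equal(GenomicRanges::start(rs$regions), c(1001L, 1L))
})

test_that("read_bed rejects empty intervals and non-numeric coordinates", {
  tf <- tempfile(fileext = ".bed")
  writeLines("chr1\t500\t500", tf)
  expect_error(read_bed(tf, "x"), "width")
  writeLines("chr1\tabc\t500", tf)
  expect_error(read_bed(tf, "x"), "parse")
})

test_that("empty BED yields an empty region set", {
  tf <- tempfile(fileext = ".bed")
  file.create(tf)
  expect_equal(length(read_bed(tf, "x")$regions), 0L)
})

test_that("BED writer/reader round-trips a region set", {
  rs <- region_set("clusters", GenomicRanges::GRanges(
    c("chr1", "chr14", "chrM"),
    IRanges::IRanges(start = c(11L, 5001L, 2L), width = c(30L, 1000L, 25L))))
  tf <- tempfile(fileext = ".bed")
  write_bed(rs, tf)
  back <- read_bed(tf, "clusters")
  expect_equal(GenomicRanges::start(back$regions),
               GenomicRanges::start(rs$regions))
  expect_equal(GenomicRanges::width(back$regions),
               GenomicRanges::width(rs$regions))
})

test_that("annotation rows with one id merge into one multi-locus record", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tpirna_id\tsequence\tstrand",
               "chr1\t100\t130\tpiR-x\tACGTACGTACGTACGTACGTACGTACGTAC\t+",
               "chr5\t200\t230\tpiR-x\tACGTACGTACGTACGTACGTACGTACGTAC\t+"), tf)
  ann <- read_annotation(tf)
  expect_equal(nrow(ann$pirnas), 1L)
  expect_equal(ann$pirnas$n_loci, 2L)
  # 0-based half-open input becomes 1-based closed internally
  expect_equal(ann$loci$start, c(101L, 201L))
  expect_equal(ann$loci$end, c(130L, 230L))
})

test_that("duplicate identical annotation rows collapse to one locus", {
  row <- "chr1\t100\t130\tpiR-x\tACGTACGTACGTACGTACGTACGTACGTAC\t+"
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tpirna_id\tsequence\tstrand", row, row), tf)
  expect_equal(read_annotation(tf)$pirnas$n_loci, 1L)
})

test_that("annotation reader rejects conflicting sequences and bad intervals", {
  hdr <- "chrom\tstart\tend\tpirna_id\tsequence\tstrand"
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(hdr,
               "chr1\t100\t130\tpiR-x\tACGTACGTACGTACGTACGTACGTACGTAC\t+",
               "chr2\t100\t130\tpiR-x\tTTTTACGTACGTACGTACGTACGTACGTAC\t+"), tf)
  expect_error(read_annotation(tf), "conflicting")
  writeLines(c(hdr,
               "chr1\t130\t100\tpiR-x\tACGTACGTACGTACGTACGTACGTACGTAC\t+"), tf)
  expect_error(read_annotation(tf), "end <= start")
})

test_that("annotation is invariant to input row order", {
  sim <- generate_annotation(
    n_pirnas = 10L,
    multiplicity_mix = c(single = 6L, oligo = 3L, mid = 1L, high = 0L),
    n_node_members = 2L, n_imprinted_single_locus = 1L, n_mito = 1L,
    n_in_clusters = 0L, n_exclusive = 1L, n_ubiquitous = 1L,
    n_reference_biased = 1L, n_focus_biased = 1L, n_background = 0L,
    n_background_mito = 0L, n_background_in_clusters = 0L,
    oligo_loci_total = 12L, seed = 3L
  )
  tf1 <- tempfile(fileext = ".tsv")
  write_annotation(sim$annotation, tf1)
  tab <- utils::read.delim(tf1, stringsAsFactors = FALSE)
  for (i in 1:3) {
    tf2 <- tempfile(fileext = ".tsv")
    perm <- tab[with_seed(i, sample(nrow(tab))), ]
    utils::write.table(perm, tf2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_equal(read_annotation(tf2), read_annotation(tf1))
  }
})

test_that("matrix TSV round-trips integers exactly and doubles to 1e-9", {
  m_int <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
                  dimnames = list(c("piR-a", "piR-b"), c("s1", "s2")))
  tf <- tempfile(fileext = ".tsv")
  write_matrix(m_int, tf)
  expect_equal(read_matrix(tf), m_int + 0)  # storage mode double

  m_dbl <- with_seed(1, matrix(runif(12) * 1e4, 3, 4,
                               dimnames = list(paste0("p", 1:3),
                                               paste0("s", 1:4))))
  write_matrix(m_dbl, tf)
  expect_equal(read_matrix(tf), m_dbl, tolerance = 1e-9)
})

test_that("duplicate matrix ids are rejected", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(write_matrix(m, tempfile()), "duplicate row")
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s1")))
  expect_error(write_matrix(m2, tempfile()), "duplicate column")
})

test_that("sample metadata round-trips and is validated", {
  md <- cohort_metadata(n_focus = 3L, n_reference = 2L,
                        other_tissues = "liver", n_per_other = 1L)
  tf <- tempfile(fileext = ".tsv")
  write_sample_metadata(md, tf)
  expect_equal(read_sample_metadata(tf), md)
  bad <- rbind(md, md[1, ])
  expect_error(write_sample_metadata(bad, tf), "duplicate")
})
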
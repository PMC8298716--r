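# The synthetic cohort generator: determinism, conservation, planted
# composition, Poisson count behaviour and degenerate inputs.

test_that("same seed gives byte-identical annotation and FASTQ output", {
  s1 <- tiny_sim(depth = 800, seed = 77L, out_dir = tempfile())
  s2 <- tiny_sim(depth = 800, seed = 77L, out_dir = tempfile())
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth$counts, s2$truth$counts)
  for (sid in s1$metadata$sample_id) {
    expect_identical(readLines(s1$truth$fastq_paths[[sid]]),
                     readLines(s2$truth$fastq_paths[[sid]]))
  }
})

test_that("per-sample read totals equal the sum of planted class counts", {
  sim <- tiny_sim(depth = 2000, seed = 15L)
  cc <- sim$truth$class_counts
  expect_equal(cc$total,
               cc$pirna + cc$mirna_length + cc$low_quality + cc$fragment +
                 cc$adapter_only)
  expect_equal(colSums(sim$truth$counts), stats::setNames(cc$pirna,
                                                          cc$sample_id))
  for (j in c(1L, nrow(cc))) {
    n_lines <- length(readLines(sim$truth$fastq_paths[[cc$sample_id[j]]]))
    expect_equal(n_lines, 4L * cc$total[j])
  }
})

test_that("planted multiplicity, designations and classes are exact", {
  sim <- generate_annotation(
    n_pirnas = 30L,
    multiplicity_mix = c(single = 18L, oligo = 8L, mid = 2L, high = 2L),
    n_node_members = 4L, n_imprinted_single_locus = 3L, n_mito = 3L,
    n_in_clusters = 2L, n_exclusive = 2L, n_ubiquitous = 3L,
    n_reference_biased = 3L, n_focus_biased = 2L,
    n_background = 8L, n_background_mito = 3L,
    n_background_in_clusters = 1L, oligo_loci_total = 30L, seed = 4L
  )
  tr <- sim$truth
  fg <- tr[!tr$is_background, ]
  expect_equal(as.integer(table(fg$bin)[c("single", "oligo", "mid", "high")]),
               c(18L, 8L, 2L, 2L))
  expect_equal(sum(fg$mitochondrial), 3L)
  expect_equal(sum(tr$mitochondrial), 6L)
  expect_equal(sum(fg$imprinted), 3L)
  expect_equal(sum(fg$in_cluster), 2L)
  expect_equal(as.integer(table(fg$expr_class)[c("node", "exclusive",
                                                 "ubiquitous",
                                                 "reference_biased",
                                                 "focus_biased", "other")]),
               c(4L, 2L, 3L, 3L, 2L, 16L))
  # truth n_loci agrees with the annotation
  ann_counts <- locus_count(sim$annotation, tr$pirna_id)
  expect_equal(unname(ann_counts), tr$n_loci)
  # imprinted designates are single-locus with the locus inside the region
  gm <- genome_model()
  imp_ids <- tr$pirna_id[tr$imprinted]
  expect_true(all(tr$n_loci[tr$imprinted] == 1L))
  expect_true(all(overlaps_region(loci_granges(sim$annotation, imp_ids),
                                  gm$imprinted_region)))
  # oligo bin loci sum to the requested total
  expect_equal(sum(fg$n_loci[fg$bin == "oligo"]), 30L)
})

test_that("sequences are unique, adapter-clean and containment-free", {
  sim <- generate_annotation(
    n_pirnas = 25L,
    multiplicity_mix = c(single = 20L, oligo = 5L, mid = 0L, high = 0L),
    n_node_members = 2L, n_imprinted_single_locus = 1L, n_mito = 2L,
    n_in_clusters = 0L, n_exclusive = 2L, n_ubiquitous = 2L,
    n_reference_biased = 2L, n_focus_biased = 2L,
    n_background = 5L, n_background_mito = 0L,
    n_background_in_clusters = 0L, oligo_loci_total = 20L, seed = 8L
  )
  seqs <- sim$annotation$pirnas$sequence
  expect_false(anyDuplicated(seqs) > 0L)
  expect_true(all(nchar(seqs) >= 23L & nchar(seqs) <= 32L))
  expect_false(any(grepl(default_adapter(), seqs, fixed = TRUE)))
  for (i in seq_along(seqs)) {
    expect_false(any(grepl(seqs[i], seqs[-i], fixed = TRUE)))
  }
})

test_that("a too-small region refuses to host the requested loci", {
  gm <- genome_model()
  small <- GenomicRanges::GRanges("chr14",
                                  IRanges::IRanges(6000001L, 6000100L))
  gm$imprinted_region <- region_set("MEG8", small)
  expect_error(
    generate_annotation(
      n_pirnas = 10L,
      multiplicity_mix = c(single = 10L, oligo = 0L, mid = 0L, high = 0L),
      genome = gm, n_node_members = 6L, n_imprinted_single_locus = 6L,
      n_mito = 0L, n_in_clusters = 0L, n_exclusive = 1L, n_ubiquitous = 1L,
      n_reference_biased = 1L, n_focus_biased = 1L, n_background = 0L,
      n_background_mito = 0L, n_background_in_clusters = 0L, seed = 1L
    ),
    "too small"
  )
})

test_that("empty sample lists and zero depth degenerate gracefully", {
  sim <- generate_annotation(
    n_pirnas = 4L,
    multiplicity_mix = c(single = 4L, oligo = 0L, mid = 0L, high = 0L),
    n_node_members = 1L, n_imprinted_single_locus = 1L, n_mito = 1L,
    n_in_clusters = 0L, n_exclusive = 1L, n_ubiquitous = 1L,
    n_reference_biased = 1L, n_focus_biased = 0L, n_background = 0L,
    n_background_mito = 0L, n_background_in_clusters = 0L, seed = 2L
  )
  md <- cohort_metadata(n_focus = 2L, n_reference = 1L,
                        other_tissues = "adrenal_gland", n_per_other = 1L)
  expect_error(
    generate_reads(sim$annotation, sim$truth, md[0, ], depth = 100),
    "empty"
  )
  tr <- generate_reads(sim$annotation, sim$truth, md, depth = 0, seed = 1L)
  expect_true(all(tr$counts == 0L))
  expect_true(all(tr$class_counts$total == 0L))
  expect_equal(length(readLines(tr$fastq_paths[[1]])), 0L)
})

test_that("realized counts follow the Poisson model around a planted mean", {
  # one ubiquitously expressed piRNA, no contaminants: the scaling makes the
  # expected per-sample count equal the depth, here 100.
  sim <- generate_annotation(
    n_pirnas = 1L,
    multiplicity_mix = c(single = 1L, oligo = 0L, mid = 0L, high = 0L),
    n_node_members = 0L, n_imprinted_single_locus = 0L, n_mito = 0L,
    n_in_clusters = 0L, n_exclusive = 0L, n_ubiquitous = 1L,
    n_reference_biased = 0L, n_focus_biased = 0L, n_background = 0L,
    n_background_mito = 0L, n_background_in_clusters = 0L, seed = 3L
  )
  md <- cohort_metadata(n_focus = 1L, n_reference = 1L,
                        other_tissues = "adrenal_gland", n_per_other = 1L)
  noise <- sim_noise()
  noise[c("mirna_frac", "low_qual_frac", "fragment_frac",
          "adapter_only_frac", "adapter_read_frac")] <- 0
  hits <- vapply(1:100, function(s) {
    tr <- generate_reads(sim$annotation, sim$truth, md, depth = 100,
                         noise = noise, seed = s)
    expect_equal(unname(tr$expected_means[1, 1]), 100)
    abs(tr$counts[1, 1] - 100) <= 4 * sqrt(100)
  }, logical(1))
  # Poisson tail bound: |N - 100| > 40 has probability ~6e-5 per draw
  expect_gte(mean(hits), 0.99)
})

test_that("simulate_cohort writes a coherent, re-readable bundle", {
  dir <- tempfile("bundle")
  sim <- simulate_cohort(out_dir = dir, depth = 1500, seed = 5L,
                         n_pirnas = 20L,
                         multiplicity_mix = c(single = 12L, oligo = 6L,
                                              mid = 1L, high = 1L),
                         n_node_members = 4L, n_imprinted_single_locus = 3L,
                         n_mito = 2L, n_in_clusters = 1L, n_exclusive = 2L,
                         n_ubiquitous = 3L, n_reference_biased = 3L,
                         n_focus_biased = 2L, n_background = 6L,
                         n_background_mito = 2L,
                         n_background_in_clusters = 2L,
                         oligo_loci_total = 24L)
  ann <- read_annotation(sim$paths$annotation)
  expect_identical(ann, sim$annotation)
  md <- read_sample_metadata(sim$paths$metadata)
  expect_equal(md, sim$metadata)
  clusters <- read_bed(sim$paths$clusters_bed, "piRNA_clusters")
  expect_equal(length(clusters$regions),
               length(sim$genome$cluster_regions$regions))
  counts <- read_matrix(sim$paths$truth_counts)
  expect_equal(counts, sim$truth$counts + 0)
  manifest <- jsonlite::read_json(sim$paths$manifest)
  expect_equal(manifest$seed, 5L)
  expect_equal(manifest$n_pirnas, 20L)
})
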
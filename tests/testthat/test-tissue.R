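# Cross-tissue comparison: detection vectors, exclusivity classes, fold
# bias, hierarchical clustering and node extraction.

# A hand-built cohort: 4 placenta + 3 testis + 2 liver samples.
toy_tissue_data <- function() {
  md <- data.frame(
    sample_id = c(paste0("pl", 1:4), paste0("te", 1:3), paste0("li", 1:2)),
    tissue = c(rep("placenta", 4), rep("testis", 3), rep("liver", 2)),
    stringsAsFactors = FALSE
  )
  counts <- rbind(
    everywhere = c(50, 60, 55, 45, 40, 50, 45, 30, 35),
    placenta_only = c(20, 25, 30, 15, 0, 0, 0, 0, 0),
    testis_high = c(10, 12, 8, 10, 400, 500, 450, 10, 12),
    silent = rep(0, 9)
  )
  colnames(counts) <- md$sample_id
  libs <- stats::setNames(rep(1e5, 9), md$sample_id)
  list(md = md, counts = counts, rpm = rpm_normalize(counts, libs))
}

test_that("detection applies the consistency criteria within each tissue", {
  d <- toy_tissue_data()
  det <- detection_vector(d$counts, d$rpm, d$md)
  expect_true(all(det["everywhere", ]))
  expect_equal(unname(det["placenta_only", c("placenta", "testis", "liver")]),
               c(TRUE, FALSE, FALSE))
  expect_true(all(det["testis_high", ]))
  expect_false(any(det["silent", ]))
})

test_that("a piRNA with enough reads in 1 of 3 testis samples is detected", {
  md <- data.frame(sample_id = paste0("te", 1:3), tissue = "testis",
                   stringsAsFactors = FALSE)
  counts <- matrix(c(12L, 0L, 0L), 1, 3,
                   dimnames = list("p1", md$sample_id))
  rpm <- rpm_normalize(counts, stats::setNames(rep(1e5, 3), md$sample_id))
  det <- detection_vector(counts, rpm, md)
  expect_true(det["p1", "testis"])  # min_sample_threshold(3, 0.10) == 1
})

test_that("exclusivity classes partition the analysed set", {
  d <- toy_tissue_data()
  det <- detection_vector(d$counts, d$rpm, d$md)
  cls <- exclusivity_classes(det, "placenta")
  expect_equal(as.character(cls$class[c("everywhere", "placenta_only",
                                        "testis_high", "silent")]),
               c("ubiquitous", "exclusive_to_focus", "ubiquitous", "other"))
  expect_equal(sum(cls$counts), nrow(det))
})

test_that("fold bias honours the inclusive five-fold boundary", {
  md <- data.frame(sample_id = c("p1", "p2", "p3", "t1", "t2", "t3"),
                   tissue = rep(c("placenta", "testis"), each = 3),
                   stringsAsFactors = FALSE)
  libs <- stats::setNames(rep(1e6, 6), md$sample_id)
  counts <- rbind(
    exactly5 = c(10, 10, 10, 2, 2, 2),     # ratio exactly 5 -> focus_biased
    equal = c(7, 7, 7, 7, 7, 7),           # ratio 1 -> neither
    ref_hi = c(2, 2, 2, 11, 10, 12),       # 1/r >= 5 -> reference_biased
    ref_zero = c(5, 6, 4, 0, 0, 0)         # -> not_detected_in_reference
  )
  colnames(counts) <- md$sample_id
  rpm <- rpm_normalize(counts, libs)
  fb <- fold_bias(counts, rpm, md, "placenta", "testis")
  expect_equal(as.character(fb$fold_class),
               c("focus_biased", "neither", "reference_biased",
                 "not_detected_in_reference"))
  expect_true(is.na(fb$ratio[4]))
})

test_that("swapping focus and reference swaps the bias calls", {
  for (i in 1:10) {
    dat <- with_seed(i * 11L, {
      md <- data.frame(sample_id = paste0("s", 1:9),
                       tissue = rep(c("A", "B", "C"), each = 3),
                       stringsAsFactors = FALSE)
      counts <- matrix(rpois(90, 20) + 1L, 10, 9,
                       dimnames = list(paste0("p", 1:10), md$sample_id))
      list(md = md, counts = counts,
           rpm = rpm_normalize(counts,
                               stats::setNames(rep(1e5, 9), md$sample_id)))
    })
    ab <- fold_bias(dat$counts, dat$rpm, dat$md, "A", "B")
    ba <- fold_bias(dat$counts, dat$rpm, dat$md, "B", "A")
    expect_equal(ab$fold_class == "focus_biased",
                 ba$fold_class == "reference_biased")
    expect_equal(ab$fold_class == "reference_biased",
                 ba$fold_class == "focus_biased")
  }
})

test_that("identical expression rows merge at height zero", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 9, 9, 9))
  colnames(m) <- paste0("s", 1:4)
  dend <- hierarchical_cluster(m, log_transform = FALSE)
  first <- dend$nodes[[1]]
  expect_equal(sort(first$members), c("a", "b"))
  expect_equal(first$height, 0)
})

test_that("single linkage on three points reproduces the hand dendrogram", {
  # 1-D points at 0, 1, 3: pairwise distances 1, 2, 3.
  m <- matrix(c(0, 1, 3), 3, 1, dimnames = list(c("x", "y", "z"), "s1"))
  dend <- hierarchical_cluster(m, method = "single", log_transform = FALSE)
  expect_equal(sort(dend$nodes[[1]]$members), c("x", "y"))
  expect_equal(dend$nodes[[1]]$height, 1)
  expect_equal(dend$nodes[[2]]$height, 2)  # z joins at d(y, z) = 2
})

test_that("dendrogram heights are monotone for standard linkages", {
  for (method in c("single", "complete", "average")) {
    m <- with_seed(99L, matrix(rnorm(60), 10, 6,
                               dimnames = list(paste0("p", 1:10),
                                               paste0("s", 1:6))))
    dend <- hierarchical_cluster(m, method = method, log_transform = FALSE)
    heights <- vapply(dend$nodes, function(nd) nd$height, numeric(1))
    expect_true(all(diff(heights) >= -1e-12))
    # child memberships partition the parent's
    for (nd in dend$nodes) {
      kid_members <- unlist(lapply(nd$children, function(k) {
        if (k < 0) dend$labels[-k] else dend$nodes[[k]]$members
      }))
      expect_equal(sort(kid_members), sort(nd$members))
    }
  }
})

test_that("constant rows with correlation distance suggest euclidean", {
  m <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  colnames(m) <- paste0("s", 1:3)
  expect_error(hierarchical_cluster(m, metric = "correlation",
                                    log_transform = FALSE),
               "euclidean")
})

test_that("extract_node returns the smallest satisfying node, never root", {
  m <- with_seed(7L, matrix(rnorm(48), 8, 6,
                            dimnames = list(paste0("p", 1:8),
                                            paste0("s", 1:6))))
  dend <- hierarchical_cluster(m, log_transform = FALSE)
  everything <- extract_node(dend, function(nd) TRUE)
  expect_equal(length(everything$members), 2L)  # first merge, not root
  expect_null(extract_node(dend, function(nd) FALSE))
})

test_that("a planted focus-high block is extracted with its locus profile", {
  sim <- tiny_sim(depth = 30000, seed = 31L)
  # RPM magnitudes scale inversely with the number of expressed piRNAs, so
  # the "highly expressed" floor is raised for this 20-piRNA toy cohort.
  res <- run_pipeline(sim$truth$fastq_paths, sim$annotation, sim$metadata,
                      region_sets = list(sim$genome$cluster_regions,
                                         sim$genome$imprinted_region),
                      imprinted_region = sim$genome$imprinted_region,
                      node_min_rpm = 2e4, run_tsne = FALSE)
  planted <- sim$truth_pirnas$pirna_id[sim$truth_pirnas$expr_class == "node"]
  expect_setequal(res$node$members, planted)
  expect_equal(res$node_profile$n_members, 4L)
  expect_equal(res$node_profile$n_single_locus, 3L)
  expect_equal(res$node_profile$n_in_region, 3L)
})

test_that("node profile counts multi-locus in-region members correctly", {
  ann <- toy_annotation()
  node <- list(id = 1L, height = 0,
               members = c("piR-b", "piR-r"), children = c(-1L, -2L))
  # piR-b has 2 loci (none in region); piR-r is single-locus in region
  rep1 <- node_region_report(node, ann, toy_region())
  expect_equal(rep1$n_members, 2L)
  expect_equal(rep1$n_single_locus, 1L)
  expect_equal(rep1$n_in_region, 1L)
  empty <- node_region_report(NULL, ann, toy_region())
  expect_equal(empty$n_members, 0L)
})
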
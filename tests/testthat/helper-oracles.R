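# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately avoid the package's own index/overlap machinery.

# Brute-force read assignment: a read counts for a piRNA when it equals the
# annotated sequence or is a contiguous substring of it with length >=
# min_len. All-pairs scan with grepl(fixed = TRUE).
brute_force_assign <- function(read_sets, annotation, min_len = 23L) {
  ids <- annotation$pirnas$pirna_id
  seqs <- annotation$pirnas$sequence
  counts <- matrix(0L, nrow = length(ids), ncol = length(read_sets),
                   dimnames = list(ids, names(read_sets)))
  for (j in seq_along(read_sets)) {
    reads <- read_sets[[j]]
    if (is.data.frame(reads)) reads <- reads$sequence
    for (r in reads) {
      hit <- (r == seqs) |
        (nchar(r) >= min_len & grepl(r, seqs, fixed = TRUE))
      counts[hit, j] <- counts[hit, j] + 1L
    }
  }
  counts
}

# Brute-force interval overlap: O(n * m) scan over plain coordinate tables
# (1-based closed), ignoring strand.
brute_force_overlap <- function(loci_df, regions_df) {
  vapply(seq_len(nrow(loci_df)), function(i) {
    any(regions_df$chrom == loci_df$chrom[i] &
          regions_df$start <= loci_df$end[i] &
          regions_df$end >= loci_df$start[i])
  }, logical(1))
}

# A small hand-built annotation covering the interesting cases: a
# single-locus piRNA, a two-locus piRNA, a mitochondrial piRNA, and a piRNA
# inside a named region.
toy_annotation <- function() {
  loci <- data.frame(
    pirna_id = c("piR-a", "piR-b", "piR-b", "piR-m", "piR-r"),
    sequence = c("ACGTACGTACGTACGTACGTACGTA",     # 25 nt
                 "TTGCAATTGCAATTGCAATTGCAATTGG",  # 28 nt
                 "TTGCAATTGCAATTGCAATTGCAATTGG",
                 "GGGCCCGGGCCCGGGCCCGGGCCCG",     # 25 nt
                 "CATCATCATCATCATCATCATCATCAT"),  # 27 nt
    chrom = c("chr1", "chr2", "chr5", "chrM", "chr14"),
    start = c(101L, 201L, 501L, 11L, 1001L),
    end = c(125L, 228L, 528L, 35L, 1027L),
    strand = c("+", "+", "-", "+", "+"),
    stringsAsFactors = FALSE
  )
  pirna_annotation(loci)
}

toy_region <- function() {
  region_set("target", GenomicRanges::GRanges(
    "chr14", IRanges::IRanges(start = 1010L, end = 1100L)))
}

# Read data.frame maker with uniform high quality.
make_reads <- function(seqs, phred = 40L) {
  data.frame(read_id = paste0("r", seq_along(seqs), recycle0 = TRUE),
             sequence = seqs,
             quality = strrep(rawToChar(as.raw(phred + 33L)), nchar(seqs)),
             stringsAsFactors = FALSE)
}

# A small planted cohort used by invariant tests (fast: ~20 piRNAs, 19
# samples, shallow depth).
tiny_sim <- function(depth = 8000, seed = 42L, noise = sim_noise(),
                     out_dir = tempfile("tinysim")) {
  ann <- generate_annotation(
    n_pirnas = 20L,
    multiplicity_mix = c(single = 12L, oligo = 6L, mid = 1L, high = 1L),
    n_node_members = 4L, n_imprinted_single_locus = 3L,
    n_mito = 2L, n_in_clusters = 1L,
    n_exclusive = 2L, n_ubiquitous = 3L,
    n_reference_biased = 3L, n_focus_biased = 2L,
    n_background = 6L, n_background_mito = 2L,
    n_background_in_clusters = 2L,
    oligo_loci_total = 24L,
    seed = seed
  )
  md <- cohort_metadata(n_focus = 6L, n_reference = 3L,
                        other_tissues = c("adrenal_gland", "brain", "liver"),
                        n_per_other = 2L)
  truth <- generate_reads(ann$annotation, ann$truth, md, depth = depth,
                          noise = noise, out_dir = out_dir, seed = seed + 1L)
  list(annotation = ann$annotation, truth_pirnas = ann$truth, truth = truth,
       metadata = md, genome = genome_model())
}

# Random count/RPM instance generator for property suites.
random_counts_instance <- function(n_pirna = 20L, n_sample = 8L) {
  counts <- matrix(rpois(n_pirna * n_sample, lambda = 5), n_pirna, n_sample,
                   dimnames = list(paste0("p", seq_len(n_pirna)),
                                   paste0("s", seq_len(n_sample))))
  libs <- colSums(counts) + sample(0:50, n_sample, replace = TRUE)
  libs[libs == 0] <- 1L
  names(libs) <- colnames(counts)
  list(counts = counts, library_sizes = libs)
}
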
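# Synthetic cohort generator with a planted truth table.
#
# The generator emulates a small RNA sequencing study of one focus tissue
# (default "placenta", 30 samples) against a reference germline tissue
# (default "testis", 3 samples) and five further somatic tissues (3 samples
# each): multi-sample libraries of 16-40 nt reads with adapter remnants,
# low-quality reads, miRNA-length contaminants and sample-private random
# fragments; piRNAs transcribed from 1, 2-9, 10-100 and > 100 loci; a block
# of single-locus piRNAs planted inside a named imprinted region that is
# high in the focus tissue and low elsewhere; mitochondrial-locus piRNAs;
# and planted exclusive / ubiquitous / fold-biased expression classes.
# Every planted fact is recorded so downstream stages can be scored exactly.

#' Default 3' adapter used by the generator
#'
#' A fixed, documented 10-nt sequence appended to a configurable fraction of
#' simulated reads (the start of the common Illumina small RNA 3' adapter).
#' @return The adapter sequence.
#' @export
default_adapter <- function() "AGATCGGAAG"

#' Synthetic genome model
#'
#' A compact genome layout for the simulator: 22 autosomes plus chrX, chrY
#' and a short mitochondrial chromosome, one named imprinted region (an
#' MEG8-like interval on chr14) and a set of piRNA cluster regions. Cluster
#' regions never overlap the imprinted region.
#'
#' @param imprinted_name Name of the imprinted region set (default "MEG8").
#' @return An object of class `genome_model` with `chromosomes` (named
#'   lengths), `imprinted_region` and `cluster_regions` ([region_set()]s).
#' @export
genome_model <- function(imprinted_name = "MEG8") {
  auto <- stats::setNames(as.integer(seq(25e6, 4e6, length.out = 22)),
                          paste0("chr", 1:22))
  chromosomes <- c(auto, chrX = 15000000L, chrY = 6000000L, chrM = 16571L)

  imprinted <- region_set(
    imprinted_name,
    GenomicRanges::GRanges("chr14",
                           IRanges::IRanges(start = 6000001L, end = 6040000L))
  )
  cluster_chroms <- paste0("chr", c(1:10, 12, 15:22, "X"))
  clusters <- region_set(
    "piRNA_clusters",
    GenomicRanges::GRanges(
      cluster_chroms,
      IRanges::IRanges(start = 2000001L, width = 50000L)
    )
  )
  gm <- structure(list(chromosomes = chromosomes,
                       imprinted_region = imprinted,
                       cluster_regions = clusters),
                  class = "genome_model")
  validate_genome_model(gm)
  gm
}

validate_genome_model <- function(gm) {
  within_bounds <- function(gr) {
    chr <- as.character(GenomicRanges::seqnames(gr))
    abort_if(!all(chr %in% names(gm$chromosomes)),
             "genome model region on undeclared chromosome")
    abort_if(any(GenomicRanges::end(gr) > gm$chromosomes[chr]),
             "genome model region exceeds chromosome bounds")
  }
  within_bounds(gm$imprinted_region$regions)
  within_bounds(gm$cluster_regions$regions)
  abort_if(any(overlaps_region(gm$cluster_regions$regions,
                               gm$imprinted_region)),
           "cluster regions must not overlap the imprinted region")
  abort_if(!"chrM" %in% names(gm$chromosomes),
           "genome model must declare chrM")
  invisible(TRUE)
}

#' Sample sheet for the default cohort design
#'
#' @param n_focus Number of focus-tissue samples (default 30).
#' @param focus Focus tissue label (default "placenta").
#' @param n_reference Reference-tissue samples (default 3).
#' @param reference Reference tissue label (default "testis").
#' @param other_tissues Further somatic tissue labels.
#' @param n_per_other Samples per further tissue (default 3).
#' @return Sample metadata data.frame (`sample_id`, `tissue`).
#' @export
cohort_metadata <- function(n_focus = 30L, focus = "placenta",
                            n_reference = 3L, reference = "testis",
                            other_tissues = c("adrenal_gland", "brain",
                                              "liver", "kidney", "lung"),
                            n_per_other = 3L) {
  tissues <- c(rep(focus, n_focus), rep(reference, n_reference),
               rep(other_tissues, each = n_per_other))
  within <- stats::ave(seq_along(tissues), tissues, FUN = seq_along)
  md <- data.frame(
    sample_id = paste0(tissues, "_", formatC(within, width = 2, flag = "0")),
    tissue = tissues,
    stringsAsFactors = FALSE
  )
  validate_sample_metadata(md)
  md
}

# --- random sequence helpers -------------------------------------------------

random_dna <- function(n, len_min, len_max) {
  if (n == 0L) return(character(0))
  lens <- if (len_min == len_max) rep.int(len_min, n) else
    sample(seq.int(len_min, len_max), n, replace = TRUE)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * len_max, replace = TRUE),
                nrow = n)
  full <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  substr(full, 1L, lens)
}

# TRUE where a sequence would interact with adapter trimming: contains the
# full adapter, or ends in an adapter prefix of >= min_overlap nt.
adapter_confusable <- function(seqs, adapter, min_overlap = 5L) {
  if (length(seqs) == 0L) return(logical(0))
  bad <- stringi::stri_detect_fixed(seqs, adapter)
  n <- nchar(seqs)
  for (k in seq.int(min_overlap, nchar(adapter))) {
    bad <- bad | (n >= k &
                    substr(seqs, n - k + 1L, n) == substr(adapter, 1L, k))
  }
  bad
}

# Draw n sequences that are unique, adapter-clean and substring-free (no
# sequence contained in another), so exact-match assignment is unambiguous.
random_pirna_sequences <- function(n, len_min, len_max, adapter) {
  seqs <- character(0)
  while (length(seqs) < n) {
    cand <- random_dna(2L * (n - length(seqs)) + 10L, len_min, len_max)
    cand <- cand[!adapter_confusable(cand, adapter)]
    seqs <- unique(c(seqs, cand))
    if (length(seqs) > n) seqs <- seqs[seq_len(n)]
    # drop sequences contained in a longer one
    ord <- order(nchar(seqs))
    contained <- rep(FALSE, length(seqs))
    for (i in seq_along(ord)) {
      s <- seqs[ord[i]]
      longer <- ord[-seq_len(i)]
      if (length(longer) > 0L &&
          any(stringi::stri_detect_fixed(seqs[longer], s))) {
        contained[ord[i]] <- TRUE
      }
    }
    seqs <- seqs[!contained]
  }
  seqs
}

# Non-overlapping placements inside a single region: one slot per locus.
place_in_region <- function(region_gr, widths, label) {
  n <- length(widths)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  W <- GenomicRanges::width(region_gr)
  slot <- W %/% n
  abort_if(slot < max(widths),
           "region '%s' too small to place %d loci without overlap",
           label, n)
  offs <- vapply(seq_len(n), function(i) {
    sample.int(slot - widths[i] + 1L, 1L) - 1L
  }, integer(1))
  start <- GenomicRanges::start(region_gr) + (seq_len(n) - 1L) * slot + offs
  data.frame(chrom = as.character(GenomicRanges::seqnames(region_gr)),
             start = start, end = start + widths - 1L,
             stringsAsFactors = FALSE)
}

# Random placements on the nuclear genome avoiding forbidden regions and
# previously used intervals.
place_random <- function(n, genome, widths, forbidden, used_keys) {
  out_chrom <- character(n)
  out_start <- integer(n)
  todo <- seq_len(n)
  chroms <- setdiff(names(genome$chromosomes), "chrM")
  lens <- genome$chromosomes[chroms]
  while (length(todo) > 0L) {
    m <- length(todo)
    chr <- sample(chroms, m, replace = TRUE, prob = as.numeric(lens))
    start <- as.integer(floor(stats::runif(m) *
                                unname(lens[chr] - widths[todo] - 1L))) + 1L
    end <- start + widths[todo] - 1L
    gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(start, end))
    bad <- overlaps_region(gr, forbidden)
    key <- paste(chr, start, end, sep = "\r")
    bad <- bad | key %in% used_keys | duplicated(key)
    ok <- !bad
    idx <- todo[ok]
    out_chrom[idx] <- chr[ok]
    out_start[idx] <- start[ok]
    used_keys <- c(used_keys, key[ok])
    todo <- todo[!ok]
  }
  data.frame(chrom = out_chrom, start = out_start,
             end = out_start + widths - 1L, stringsAsFactors = FALSE)
}

#' Generate a piRNA annotation with planted truth
#'
#' Builds an annotation whose locus-multiplicity bins, region memberships
#' and expression classes are exactly specified, plus a matching truth
#' table. Foreground piRNAs (the planted "consistently expressed" set) are
#' split into expression classes: a `node` block that is high in the focus
#' tissue and low elsewhere (mostly single-locus inside the imprinted
#' region), `exclusive` (focus only), `ubiquitous` (all tissues),
#' `reference_biased` and `focus_biased` (five-fold-plus median
#' differences), and `other` (focus plus a strict subset of tissues).
#' Background piRNAs are expressed outside the focus tissue (and only
#' sporadically within it), so they are detectable but fail the
#' consistent-expression filter; they include additional mitochondrial and
#' cluster-resident piRNAs.
#'
#' @param n_pirnas Number of foreground piRNAs (default 297).
#' @param multiplicity_mix Named integer vector over bins
#'   `single`/`oligo`/`mid`/`high` summing to `n_pirnas`
#'   (default 151/116/0/30).
#' @param genome A [genome_model()].
#' @param n_node_members Size of the planted focus-high node (default 16).
#' @param n_imprinted_single_locus Node members that are single-locus inside
#'   the imprinted region (default 15); the remaining node members are
#'   multi-locus outside it.
#' @param n_mito Foreground single-locus piRNAs on chrM (default 19).
#' @param n_in_clusters Foreground piRNAs with a locus inside a piRNA
#'   cluster (default 0, matching a somatic tissue whose consistent piRNAs
#'   avoid clusters).
#' @param n_exclusive,n_ubiquitous,n_reference_biased,n_focus_biased Planted
#'   expression-class sizes (defaults 11 / 53 / 95 / 22); the remainder is
#'   class `other`.
#' @param n_background Background piRNAs (default 223).
#' @param n_background_mito Background piRNAs on chrM (default 23, so 42
#'   annotated mitochondrial piRNAs in total under the defaults).
#' @param n_background_in_clusters Background piRNAs inside clusters
#'   (default 30).
#' @param oligo_loci_total Total loci across the oligo bin (default 485, so
#'   the sub-10-multiplicity piRNAs span 636 distinct loci).
#' @param config A [filter_config()].
#' @param adapter Adapter the read generator will use; annotated sequences
#'   are screened against it.
#' @param seed RNG seed (same seed, byte-identical annotation).
#' @return A list with `annotation` (a [pirna_annotation()]) and `truth`
#'   (data.frame per piRNA: `pirna_id`, `expr_class`, `bin`, `n_loci`,
#'   `mitochondrial`, `imprinted`, `in_cluster`, `is_background`).
#' @export
generate_annotation <- function(n_pirnas = 297L,
                                multiplicity_mix = c(single = 151L,
                                                     oligo = 116L,
                                                     mid = 0L,
                                                     high = 30L),
                                genome = genome_model(),
                                n_node_members = 16L,
                                n_imprinted_single_locus = 15L,
                                n_mito = 19L,
                                n_in_clusters = 0L,
                                n_exclusive = 11L,
                                n_ubiquitous = 53L,
                                n_reference_biased = 95L,
                                n_focus_biased = 22L,
                                n_background = 223L,
                                n_background_mito = 23L,
                                n_background_in_clusters = 30L,
                                oligo_loci_total = 485L,
                                config = filter_config(),
                                adapter = default_adapter(),
                                seed = 1L) {
  abort_if(sum(multiplicity_mix) != n_pirnas,
           "multiplicity_mix must sum to n_pirnas (%d != %d)",
           sum(multiplicity_mix), n_pirnas)
  abort_if(!all(names(multiplicity_mix) == c("single", "oligo", "mid", "high")),
           "multiplicity_mix must be named single/oligo/mid/high")
  n_node_multi <- n_node_members - n_imprinted_single_locus
  abort_if(n_node_multi < 0, "n_imprinted_single_locus cannot exceed n_node_members")
  abort_if(multiplicity_mix[["single"]] < n_imprinted_single_locus + n_mito,
           "single bin too small for the imprinted + mitochondrial piRNAs")
  abort_if(multiplicity_mix[["oligo"]] < n_node_multi,
           "oligo bin too small for the multi-locus node members")
  n_classed <- n_node_members + n_exclusive + n_ubiquitous +
    n_reference_biased + n_focus_biased
  abort_if(n_classed > n_pirnas,
           "expression classes exceed n_pirnas (%d > %d)", n_classed, n_pirnas)
  abort_if(n_in_clusters + n_mito + n_imprinted_single_locus > n_pirnas,
           "designated piRNAs exceed n_pirnas")
  abort_if(n_background_mito + n_background_in_clusters > n_background,
           "designated background piRNAs exceed n_background")

  with_seed(seed, {
    n_total <- n_pirnas + n_background
    ids <- c(sprintf("piR-sim-%04d", seq_len(n_pirnas)),
             if (n_background > 0)
               sprintf("piR-bg-%04d", seq_len(n_background)))
    seqs <- random_pirna_sequences(n_total, config$pirna_min_len, 32L,
                                   adapter)
    widths <- nchar(seqs)

    fg <- seq_len(n_pirnas)

    # --- multiplicity bins -------------------------------------------------
    bin <- rep(NA_character_, n_total)
    node_idx <- seq_len(n_node_members)
    imprinted_idx <- node_idx[seq_len(n_imprinted_single_locus)]
    node_multi_idx <- setdiff(node_idx, imprinted_idx)
    bin[imprinted_idx] <- "single"
    bin[node_multi_idx] <- "oligo"

    rest <- setdiff(fg, node_idx)
    n_single_left <- multiplicity_mix[["single"]] - n_imprinted_single_locus
    mito_idx <- if (n_mito > 0) sample(rest, n_mito) else integer(0)
    bin[mito_idx] <- "single"
    rest2 <- setdiff(rest, mito_idx)
    pool <- sample(rest2)
    take <- function(pool, n) {
      abort_if(n > length(pool), "internal: pool exhausted")
      if (n == 0L) return(list(got = integer(0), left = pool))
      list(got = pool[seq_len(n)], left = pool[-seq_len(n)])
    }
    t1 <- take(pool, n_single_left - n_mito)
    bin[t1$got] <- "single"
    t2 <- take(t1$left, multiplicity_mix[["oligo"]] - n_node_multi)
    bin[t2$got] <- "oligo"
    t3 <- take(t2$left, multiplicity_mix[["mid"]])
    bin[t3$got] <- "mid"
    bin[t3$left] <- "high"
    if (n_background > 0) bin[n_pirnas + seq_len(n_background)] <- "single"

    # --- loci per piRNA ----------------------------------------------------
    n_loci <- integer(n_total)
    n_loci[bin == "single"] <- 1L
    oligo_idx <- which(bin == "oligo")
    if (length(oligo_idx) > 0L) {
      k <- length(oligo_idx)
      base_cnt <- oligo_loci_total %/% k
      extra <- oligo_loci_total - base_cnt * k
      cnt <- rep.int(base_cnt, k)
      if (extra > 0) cnt[sample.int(k, extra)] <- base_cnt + 1L
      e <- config$multiplicity_bins
      abort_if(any(cnt < 2L | cnt > e[2]),
               "oligo_loci_total %d not realizable with %d piRNAs in [2, %d]",
               oligo_loci_total, k, e[2])
      n_loci[oligo_idx] <- cnt
    }
    mid_idx <- which(bin == "mid")
    if (length(mid_idx) > 0L) {
      e <- config$multiplicity_bins
      n_loci[mid_idx] <- sample(seq.int(e[2] + 1L, e[3]), length(mid_idx),
                                replace = TRUE)
    }
    high_idx <- which(bin == "high")
    if (length(high_idx) > 0L) {
      e <- config$multiplicity_bins
      n_loci[high_idx] <- sample(seq.int(e[3] + 1L, e[3] + 60L),
                                 length(high_idx), replace = TRUE)
    }

    # --- region designations ----------------------------------------------
    cluster_idx <- if (n_in_clusters > 0)
      sample(setdiff(fg, c(node_idx, mito_idx)), n_in_clusters) else integer(0)
    bg_all <- n_pirnas + seq_len(n_background)
    bg_mito_idx <- if (n_background_mito > 0)
      bg_all[seq_len(n_background_mito)] else integer(0)
    bg_cluster_idx <- if (n_background_in_clusters > 0)
      bg_all[n_background_mito + seq_len(n_background_in_clusters)] else integer(0)

    # --- place loci --------------------------------------------------------
    forbidden <- region_set(
      "forbidden",
      suppressWarnings(c(genome$imprinted_region$regions,
                         genome$cluster_regions$regions))
    )
    used <- character(0)
    loci_list <- vector("list", n_total)

    imp <- place_in_region(genome$imprinted_region$regions,
                           widths[imprinted_idx],
                           genome$imprinted_region$name)
    for (i in seq_along(imprinted_idx)) {
      loci_list[[imprinted_idx[i]]] <- imp[i, , drop = FALSE]
    }

    all_mito_idx <- c(mito_idx, bg_mito_idx)
    if (length(all_mito_idx) > 0L) {
      mito_gr <- GenomicRanges::GRanges(
        "chrM", IRanges::IRanges(1L, genome$chromosomes[["chrM"]]))
      mito <- place_in_region(mito_gr, widths[all_mito_idx], "chrM")
      for (i in seq_along(all_mito_idx)) {
        loci_list[[all_mito_idx[i]]] <- mito[i, , drop = FALSE]
      }
    }

    all_cluster_idx <- c(cluster_idx, bg_cluster_idx)
    cluster_homes <- if (length(all_cluster_idx) > 0L) {
      sample.int(length(genome$cluster_regions$regions),
                 length(all_cluster_idx), replace = TRUE)
    } else integer(0)
    for (i in seq_along(all_cluster_idx)) {
      reg <- genome$cluster_regions$regions[cluster_homes[i]]
      w <- widths[all_cluster_idx[i]]
      start <- GenomicRanges::start(reg) +
        sample.int(GenomicRanges::width(reg) - w, 1L) - 1L
      loci_list[[all_cluster_idx[i]]] <-
        data.frame(chrom = as.character(GenomicRanges::seqnames(reg)),
                   start = start, end = start + w - 1L,
                   stringsAsFactors = FALSE)
    }

    # remaining loci: random placements outside the special regions
    need_random <- n_loci
    placed <- vapply(loci_list, function(x) if (is.null(x)) 0L else nrow(x),
                     integer(1))
    need_random <- need_random - placed
    owners <- rep.int(seq_len(n_total), need_random)
    if (length(owners) > 0L) {
      rnd <- place_random(length(owners), genome, widths[owners],
                          forbidden, used)
      rnd_split <- split(rnd, owners)
      for (nm in names(rnd_split)) {
        i <- as.integer(nm)
        loci_list[[i]] <- rbind(loci_list[[i]], rnd_split[[nm]])
      }
    }

    loci <- do.call(rbind, loci_list)
    loci$pirna_id <- rep.int(ids, vapply(loci_list, nrow, integer(1)))
    loci$sequence <- seqs[match(loci$pirna_id, ids)]
    loci$strand <- sample(c("+", "-"), nrow(loci), replace = TRUE)

    annotation <- pirna_annotation(loci, config = config)

    truth <- data.frame(
      pirna_id = ids,
      expr_class = NA_character_,
      bin = bin,
      n_loci = n_loci,
      mitochondrial = seq_len(n_total) %in% all_mito_idx,
      imprinted = seq_len(n_total) %in% imprinted_idx,
      in_cluster = seq_len(n_total) %in% all_cluster_idx,
      is_background = seq_len(n_total) > n_pirnas,
      stringsAsFactors = FALSE
    )

    # --- expression classes ------------------------------------------------
    truth$expr_class[node_idx] <- "node"
    pool <- sample(setdiff(fg, node_idx))
    t1 <- take(pool, n_exclusive)
    truth$expr_class[t1$got] <- "exclusive"
    t2 <- take(t1$left, n_ubiquitous)
    truth$expr_class[t2$got] <- "ubiquitous"
    t3 <- take(t2$left, n_reference_biased)
    truth$expr_class[t3$got] <- "reference_biased"
    t4 <- take(t3$left, n_focus_biased)
    truth$expr_class[t4$got] <- "focus_biased"
    truth$expr_class[t4$left] <- "other"
    truth$expr_class[truth$is_background] <- "background"

    list(annotation = annotation, truth = truth)
  })
}

#' Default expression profile for the read generator
#'
#' Expected read counts per sample, by expression class and tissue role,
#' before depth scaling. The focus tissue is where the planted consistent
#' set is expressed; the `node` class is high in the focus tissue, clearly
#' detectable in one secondary tissue, low in the remaining somatic tissues
#' and absent from the reference tissue. Biased classes differ ten-fold in
#' expected counts between focus and reference (comfortably beyond the
#' five-fold median call) and are expressed in `n_biased_other_tissues`
#' further tissues so they are neither exclusive nor ubiquitous. `other`
#' piRNAs are expressed in the focus tissue and a non-empty strict subset of
#' the remaining tissues. Background piRNAs are nearly silent in the focus
#' tissue (sporadic single reads) and fill the other tissues' libraries so
#' all samples have comparable sequencing depth.
#'
#' @param focus,reference,secondary Tissue labels.
#' @return A named list of profile parameters.
#' @export
expression_profile <- function(focus = "placenta", reference = "testis",
                               secondary = "adrenal_gland") {
  list(
    focus = focus, reference = reference, secondary = secondary,
    node_focus = 4000, node_secondary = 60, node_other = 15,
    node_reference = 0,
    exclusive_focus = 50,
    ubiquitous = 400,
    biased_high = 800, biased_low = 80,
    n_biased_other_tissues = 2L,
    other_expressed = 150,
    other_min_tissues = 1L,
    background_focus = 0.05
  )
}

#' Default contamination fractions for the read generator
#'
#' Fractions of the per-sample depth: miRNA-length reads (< 23 nt),
#' low-quality reads (mean Phred < 20), sample-private random fragments
#' (matching no annotated piRNA) and adapter-only reads;
#' `adapter_read_frac` is the fraction of piRNA-derived reads that carry a
#' 3' adapter remnant, and `end_trim_rate` optionally shortens piRNA reads
#' by one 3' nucleotide.
#'
#' @return Named list of fractions.
#' @export
sim_noise <- function() {
  list(mirna_frac = 0.15, low_qual_frac = 0.05, fragment_frac = 0.03,
       adapter_only_frac = 0.02, adapter_read_frac = 0.20,
       end_trim_rate = 0)
}

# Expected mean read counts per (piRNA, tissue) for a planted truth.
expected_mean_matrix <- function(truth, tissues, profile, depth, noise) {
  focus <- profile$focus
  reference <- profile$reference
  abort_if(!focus %in% tissues, "focus tissue '%s' not in metadata", focus)
  abort_if(!reference %in% tissues,
           "reference tissue '%s' not in metadata", reference)
  somatic <- setdiff(tissues, c(focus, reference))
  n <- nrow(truth)
  mu <- matrix(0, nrow = n, ncol = length(tissues),
               dimnames = list(truth$pirna_id, tissues))

  cls <- truth$expr_class
  # node
  mu[cls == "node", focus] <- profile$node_focus
  if (profile$secondary %in% somatic) {
    mu[cls == "node", profile$secondary] <- profile$node_secondary
  }
  for (t in setdiff(somatic, profile$secondary)) {
    mu[cls == "node", t] <- profile$node_other
  }
  mu[cls == "node", reference] <- profile$node_reference
  # exclusive
  mu[cls == "exclusive", focus] <- profile$exclusive_focus
  # ubiquitous
  mu[cls == "ubiquitous", ] <- profile$ubiquitous
  # biased classes: focus + reference + a fixed-size subset of other tissues
  for (i in which(cls %in% c("reference_biased", "focus_biased"))) {
    hi <- if (cls[i] == "reference_biased") reference else focus
    lo <- if (cls[i] == "reference_biased") focus else reference
    mu[i, hi] <- profile$biased_high
    mu[i, lo] <- profile$biased_low
    pick <- sample(somatic, min(profile$n_biased_other_tissues,
                                length(somatic)))
    mu[i, pick] <- profile$biased_low
  }
  # other: focus + a non-empty strict subset of the non-focus tissues
  non_focus <- setdiff(tissues, focus)
  for (i in which(cls == "other")) {
    mu[i, focus] <- profile$other_expressed
    k <- sample(seq.int(profile$other_min_tissues,
                        length(non_focus) - 1L), 1L)
    mu[i, sample(non_focus, k)] <- profile$other_expressed
  }
  # background: sporadic in focus, library-balancing filler elsewhere
  bg <- which(cls == "background")
  mu[bg, focus] <- profile$background_focus
  if (length(bg) > 0L) {
    focus_total <- sum(mu[, focus])
    for (t in setdiff(tissues, focus)) {
      filler <- max(0, (focus_total - sum(mu[, t])) / length(bg))
      mu[bg, t] <- filler
    }
  }

  # scale so the focus tissue's expected piRNA yield matches the depth and
  # contamination fractions
  pirna_frac <- 1 - noise$mirna_frac - noise$low_qual_frac -
    noise$fragment_frac - noise$adapter_only_frac
  abort_if(pirna_frac <= 0, "contamination fractions must sum to < 1")
  mu * (pirna_frac * depth / sum(mu[, focus]))
}

good_quality_strings <- function(lens) {
  chars <- strsplit(rawToChar(as.raw(30:40 + 33L)), "")[[1]]
  strrep(sample(chars, length(lens), replace = TRUE), lens)
}

low_quality_strings <- function(lens) {
  chars <- strsplit(rawToChar(as.raw(8:15 + 33L)), "")[[1]]
  strrep(sample(chars, length(lens), replace = TRUE), lens)
}

# Random contaminant sequences that cannot collide with adapter trimming.
random_clean_dna <- function(n, len_min, len_max, adapter) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(n - length(out) + 5L, len_min, len_max)
    cand <- cand[!adapter_confusable(cand, adapter)]
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Generate per-sample FASTQ libraries from a planted truth
#'
#' Draws each (piRNA, sample) read count from a Poisson distribution around
#' the planted tissue mean, emits piRNA-derived reads as exact copies of the
#' annotated sequences (a configurable fraction carrying a 3' adapter
#' remnant, truncated at the read-length ceiling), adds the contaminant
#' classes, shuffles, and writes one FASTQ per sample. Deterministic for a
#' fixed seed.
#'
#' @param annotation A [pirna_annotation()] from [generate_annotation()].
#' @param truth The matching truth data.frame.
#' @param metadata Sample metadata ([cohort_metadata()]).
#' @param depth Expected total reads per sample (default 2e5).
#' @param noise Contamination fractions ([sim_noise()]).
#' @param profile Expression profile ([expression_profile()]).
#' @param adapter 3' adapter sequence appended to `adapter_read_frac` of
#'   piRNA reads.
#' @param config A [filter_config()].
#' @param out_dir Directory for the FASTQ files (created if needed).
#' @param seed RNG seed.
#' @return A list of class `sim_truth`: `fastq_paths` (named by sample),
#'   `expected_means` (piRNA x sample), `counts` (realized piRNA x sample
#'   read counts), `class_counts` (per-sample planted read-class totals),
#'   `pirnas` (the truth table), `metadata`, `adapter`, `noise`, `depth`,
#'   `seed`.
#' @export
generate_reads <- function(annotation, truth, metadata, depth = 2e5,
                           noise = sim_noise(),
                           profile = expression_profile(),
                           adapter = default_adapter(),
                           config = filter_config(),
                           out_dir = tempfile("simreads"), seed = 1L) {
  abort_if(nrow(metadata) == 0L, "sample list must not be empty")
  abort_if(depth < 0, "depth must be >= 0")
  fr <- unlist(noise[c("mirna_frac", "low_qual_frac", "fragment_frac",
                       "adapter_only_frac", "adapter_read_frac",
                       "end_trim_rate")])
  abort_if(any(fr < 0 | fr > 1), "noise fractions must lie in [0, 1]")
  stopifnot(identical(annotation$pirnas$pirna_id, sort(truth$pirna_id)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  with_seed(seed, {
    tissues <- unique(metadata$tissue)
    mu_tissue <- expected_mean_matrix(truth, tissues, profile, depth, noise)
    mu <- mu_tissue[, metadata$tissue, drop = FALSE]
    colnames(mu) <- metadata$sample_id
    seq_of <- stats::setNames(annotation$pirnas$sequence,
                              annotation$pirnas$pirna_id)[truth$pirna_id]

    n_pirna <- nrow(truth)
    counts <- matrix(0L, n_pirna, nrow(metadata),
                     dimnames = list(truth$pirna_id, metadata$sample_id))
    class_counts <- data.frame(
      sample_id = metadata$sample_id, pirna = 0L, mirna_length = 0L,
      low_quality = 0L, fragment = 0L, adapter_only = 0L, total = 0L,
      stringsAsFactors = FALSE
    )
    fastq_paths <- stats::setNames(
      file.path(out_dir, paste0(metadata$sample_id, ".fastq")),
      metadata$sample_id
    )

    for (j in seq_len(nrow(metadata))) {
      cnt <- stats::rpois(n_pirna, mu[, j])
      counts[, j] <- cnt
      pir_seq <- rep.int(unname(seq_of), cnt)
      if (noise$end_trim_rate > 0 && length(pir_seq) > 0L) {
        eligible <- nchar(pir_seq) > config$pirna_min_len
        trim <- eligible & stats::runif(length(pir_seq)) < noise$end_trim_rate
        pir_seq[trim] <- substr(pir_seq[trim], 1L, nchar(pir_seq[trim]) - 1L)
      }
      if (noise$adapter_read_frac > 0 && length(pir_seq) > 0L) {
        with_ad <- stats::runif(length(pir_seq)) < noise$adapter_read_frac
        pir_seq[with_ad] <- substr(paste0(pir_seq[with_ad], adapter), 1L,
                                   config$max_read_len)
      }
      n_mirna <- stats::rpois(1L, noise$mirna_frac * depth)
      n_lowq <- stats::rpois(1L, noise$low_qual_frac * depth)
      n_frag <- stats::rpois(1L, noise$fragment_frac * depth)
      n_adonly <- stats::rpois(1L, noise$adapter_only_frac * depth)

      mirna_seqs <- random_clean_dna(n_mirna, config$min_read_len,
                                     config$pirna_min_len - 1L, adapter)
      lowq_seqs <- random_clean_dna(n_lowq, config$pirna_min_len, 32L,
                                    adapter)
      frag_seqs <- random_clean_dna(n_frag, config$pirna_min_len, 35L,
                                    adapter)
      adonly_seqs <- rep.int(adapter, n_adonly)

      seqs <- c(pir_seq, mirna_seqs, lowq_seqs, frag_seqs, adonly_seqs)
      quals <- c(
        good_quality_strings(nchar(pir_seq)),
        good_quality_strings(nchar(mirna_seqs)),
        low_quality_strings(nchar(lowq_seqs)),
        good_quality_strings(nchar(frag_seqs)),
        good_quality_strings(nchar(adonly_seqs))
      )
      ord <- sample.int(length(seqs))
      reads <- data.frame(
        read_id = sprintf("%s_r%07d", metadata$sample_id[j],
                          seq_along(seqs)),
        sequence = seqs[ord],
        quality = quals[ord],
        stringsAsFactors = FALSE
      )
      write_fastq(reads, fastq_paths[j])
      class_counts[j, c("pirna", "mirna_length", "low_quality", "fragment",
                        "adapter_only", "total")] <-
        c(length(pir_seq), n_mirna, n_lowq, n_frag, n_adonly, length(seqs))
    }

    structure(
      list(fastq_paths = fastq_paths, expected_means = mu, counts = counts,
           class_counts = class_counts, pirnas = truth, metadata = metadata,
           adapter = adapter, noise = noise, depth = depth, seed = seed),
      class = "sim_truth"
    )
  })
}

#' Simulate a full cohort to disk
#'
#' Convenience wrapper: builds the genome model, sample sheet, annotation
#' and per-sample FASTQ libraries, and writes every artefact (annotation
#' TSV, cluster/imprinted/chrM BEDs, metadata TSV, truth tables, manifest
#' JSON) under one directory.
#'
#' @param out_dir Output directory.
#' @param depth Expected reads per sample (default 2e5).
#' @param seed Master seed; the annotation and read generators derive their
#'   seeds from it.
#' @param config A [filter_config()].
#' @param ... Passed through to [generate_annotation()].
#' @return A list of class `sim_cohort` with `dir`, `genome`, `metadata`,
#'   `annotation`, `truth` (the `sim_truth`), `paths` (named files) and the
#'   effective parameters.
#' @export
simulate_cohort <- function(out_dir = tempfile("simcohort"), depth = 2e5,
                            seed = 1L, config = filter_config(), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- genome_model()
  metadata <- cohort_metadata()
  ann <- generate_annotation(genome = genome, config = config,
                             seed = seed, ...)
  truth <- generate_reads(ann$annotation, ann$truth, metadata,
                          depth = depth, config = config,
                          out_dir = file.path(out_dir, "fastq"),
                          seed = seed + 1L)

  paths <- list(
    annotation = file.path(out_dir, "annotation.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    clusters_bed = file.path(out_dir, "pirna_clusters.bed"),
    imprinted_bed = file.path(out_dir, "imprinted_region.bed"),
    truth_pirnas = file.path(out_dir, "truth_pirnas.tsv"),
    truth_counts = file.path(out_dir, "truth_counts.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_annotation(ann$annotation, paths$annotation)
  write_sample_metadata(metadata, paths$metadata)
  write_bed(genome$cluster_regions, paths$clusters_bed)
  write_bed(genome$imprinted_region, paths$imprinted_bed)
  utils::write.table(ann$truth, paths$truth_pirnas, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(truth$counts, paths$truth_counts)
  manifest <- list(
    seed = seed, depth = depth, adapter = truth$adapter,
    noise = truth$noise,
    n_samples = nrow(metadata),
    tissues = as.list(table(metadata$tissue)),
    n_pirnas = sum(!ann$truth$is_background),
    n_background = sum(ann$truth$is_background),
    files = c(paths[names(paths) != "manifest"],
              list(fastq = as.list(truth$fastq_paths)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  structure(
    list(dir = out_dir, genome = genome, metadata = metadata,
         annotation = ann$annotation, truth = truth, paths = paths,
         seed = seed, depth = depth),
    class = "sim_cohort"
  )
}
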
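#!/usr/bin/env Rscript
# Step 5: cross-tissue specificity of the consistent piRNA set.
#
# Per-tissue detection calls (the same consistency criteria applied within
# each tissue's samples), exclusivity/ubiquity classes, placenta-vs-testis
# median fold-bias calls, unsupervised hierarchical clustering with
# extraction of the placenta-high node and its locus profile, and the 3-D
# t-SNE sample embedding.

suppressPackageStartupMessages(library(placentapiR))

metadata <- read_sample_metadata("scratch/sim/metadata.tsv")
annotation <- read_annotation("scratch/sim/annotation.tsv")
counts <- read_matrix("scratch/sim/counts.tsv")
rpm <- read_matrix("scratch/sim/rpm.tsv")
kept <- readLines("scratch/sim/kept_pirnas.txt")
imprinted <- read_bed("scratch/sim/imprinted_region.bed", "MEG8")

counts_kept <- counts[kept, , drop = FALSE]
rpm_kept <- rpm[kept, , drop = FALSE]

det <- detection_vector(counts_kept, rpm_kept, metadata)
excl <- exclusivity_classes(det, "placenta")
fold <- fold_bias(counts_kept, rpm_kept, metadata, "placenta", "testis")

dend <- hierarchical_cluster(rpm_kept)
node <- extract_node(dend, focus_enriched_predicate(rpm_kept, metadata,
                                                    "placenta"))
profile <- node_region_report(node, annotation, imprinted)
emb <- tsne_embed(t(log2(rpm_kept + 1)), seed = 1L)

spec <- data.frame(pirna_id = kept,
                   exclusivity = as.character(excl$class[kept]),
                   fold_class = as.character(fold$fold_class),
                   median_placenta_rpm = fold$median_focus_rpm,
                   median_testis_rpm = fold$median_reference_rpm)
write.table(spec, "results/05_specificity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(profile$detail, "results/05_node_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(emb$coords), emb$coords),
            "results/05_tsne_coords.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_dendrogram_newick(dend, "results/05_dendrogram.nwk")

cat(sprintf("Exclusive to placenta: %d; ubiquitous: %d (of %d piRNAs)\n",
            excl$counts[["exclusive_to_focus"]],
            excl$counts[["ubiquitous"]], length(kept)))
tab <- table(fold$fold_class)
cat(sprintf(">= 5-fold median bias: %d towards testis, %d towards placenta; %d not detected in testis\n",
            tab[["reference_biased"]], tab[["focus_biased"]],
            tab[["not_detected_in_reference"]]))
cat(sprintf("Placenta-high node: %d members, %d single-locus, %d inside %s\n",
            profile$n_members, profile$n_single_locus, profile$n_in_region,
            imprinted$name))
cat("Tables -> results/05_*.tsv; dendrogram -> results/05_dendrogram.nwk\n")
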
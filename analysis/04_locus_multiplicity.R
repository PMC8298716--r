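#!/usr/bin/env Rscript
# Step 4: locus multiplicity and region membership of the consistent set.
#
# Bins each kept piRNA by its number of annotated genomic loci, tallies
# distinct loci per chromosome, and reports membership against the piRNA
# cluster regions, the mitochondrial genome and the imprinted region.

suppressPackageStartupMessages(library(placentapiR))

annotation <- read_annotation("scratch/sim/annotation.tsv")
kept <- readLines("scratch/sim/kept_pirnas.txt")
clusters <- read_bed("scratch/sim/pirna_clusters.bed", "piRNA_clusters")
imprinted <- read_bed("scratch/sim/imprinted_region.bed", "MEG8")

mult <- multiplicity_report(annotation, kept)
n_mito_known <- length(unique(
  annotation$loci$pirna_id[annotation$loci$chrom == "chrM"]))
memb <- membership_report(annotation, list(clusters, imprinted), kept,
                          reference_counts = c(mitochondrial = n_mito_known))

write.table(mult$per_pirna, "results/04_multiplicity_per_pirna.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(chrom = names(mult$chromosome_tally),
                       distinct_loci = mult$chromosome_tally),
            "results/04_chromosome_tally.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(memb$flags, "results/04_membership_flags.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(mult)
cat(sprintf("piRNAs below 10 loci: %d (%.1f%%), spanning %d distinct loci\n",
            mult$bin_totals[["single"]] + mult$bin_totals[["oligo"]],
            100 * (mult$bin_totals[["single"]] + mult$bin_totals[["oligo"]]) /
              nrow(mult$per_pirna),
            mult$n_distinct_loci_below_ceiling))
print(memb)
cat("Tables -> results/04_*.tsv\n")
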
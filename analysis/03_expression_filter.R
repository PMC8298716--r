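#!/usr/bin/env Rscript
# Step 3: the consistent-expression filter on the placenta cohort.
#
# "Detected" piRNAs have at least one assigned read in at least one
# placenta sample. The consistent set additionally satisfies both filter
# criteria within the placenta samples: >= 10 reads in total and >= 1 RPM
# in >= 10% of samples (3 of 30). The kept-id list goes to scratch/sim; a
# funnel summary and the per-criterion drop-out table go to results/.

suppressPackageStartupMessages(library(placentapiR))

metadata <- read_sample_metadata("scratch/sim/metadata.tsv")
counts <- read_matrix("scratch/sim/counts.tsv")
rpm <- read_matrix("scratch/sim/rpm.tsv")
focus_samples <- metadata$sample_id[metadata$tissue == "placenta"]

detected <- detected_pirnas(counts, samples = focus_samples)
filt <- consistent_expression_filter(counts, rpm,
                                     samples = focus_samples)

writeLines(filt$kept, "scratch/sim/kept_pirnas.txt")
write.table(filt$diagnostics, "results/03_filter_diagnostics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

drop_tab <- table(filt$diagnostics$failed_criterion, useNA = "no")
cat(sprintf("Detected in placenta (>= 1 read, >= 1 sample): %d piRNAs\n",
            length(detected)))
cat(sprintf("Consistently expressed (>= 10 reads and >= 1 RPM in >= %d/%d samples): %d piRNAs\n",
            min_sample_threshold(length(focus_samples), 0.10),
            length(focus_samples), length(filt$kept)))
for (nm in names(drop_tab)) {
  cat(sprintf("  dropped by %s: %d\n", nm, drop_tab[[nm]]))
}
cat("Kept ids -> scratch/sim/kept_pirnas.txt; diagnostics -> results/03_filter_diagnostics.tsv\n")
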
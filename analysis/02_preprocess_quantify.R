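#!/usr/bin/env Rscript
# Step 2: read-level QC and piRNA quantification.
#
# For every sample: trim the 3' adapter, drop reads outside the 16-40 nt
# window or below mean Phred 20, exclude miRNA-length (< 23 nt) reads, then
# assign the surviving reads to annotated piRNAs by exact sequence match
# and normalize to reads per million (RPM). Count matrices go to
# scratch/sim; the per-sample QC summary goes to results/.

suppressPackageStartupMessages(library(placentapiR))

manifest <- jsonlite::read_json("scratch/sim/manifest.json")
metadata <- read_sample_metadata("scratch/sim/metadata.tsv")
annotation <- read_annotation("scratch/sim/annotation.tsv")
adapter <- manifest$adapter

qc_rows <- list()
read_sets <- list()
for (sid in metadata$sample_id) {
  pp <- preprocess_reads(read_fastq(file.path("scratch/sim/fastq",
                                              paste0(sid, ".fastq"))),
                         adapter = adapter)
  qc_rows[[sid]] <- data.frame(sample_id = sid,
                               n_input = pp$report$n_input,
                               t(pp$report$counts))
  read_sets[[sid]] <- pp$reads$sequence
}
qc <- do.call(rbind, qc_rows)

counts <- assign_reads(read_sets, annotation)
rpm <- rpm_normalize(counts)

write_matrix(counts$counts, "scratch/sim/counts.tsv")
write_matrix(rpm, "scratch/sim/rpm.tsv")
write.table(data.frame(sample_id = names(counts$library_sizes),
                       library_size = counts$library_sizes,
                       unassigned = counts$unassigned),
            "scratch/sim/library_sizes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(qc, "results/02_qc_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("QC over %d samples: mean %.1f%% of reads retained\n",
            nrow(qc), 100 * mean(qc$retained / qc$n_input)))
cat(sprintf("  mean removal: adapter-only %.1f%%, low-quality %.1f%%, miRNA-length %.1f%%\n",
            100 * mean(qc$adapter_only / qc$n_input),
            100 * mean(qc$low_quality / qc$n_input),
            100 * mean(qc$mirna_length / qc$n_input)))
cat(sprintf("Assigned reads: median library %s; %d annotated piRNAs quantified\n",
            format(median(counts$library_sizes), big.mark = ","),
            nrow(counts$counts)))
cat("Counts/RPM -> scratch/sim; QC summary -> results/02_qc_summary.tsv\n")
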
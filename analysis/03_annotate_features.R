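#!/usr/bin/env Rscript
# Stage 3: partition peaks across the six genomic feature categories,
# rescue intergenic peaks by distance to the nearest CDS stop/start codon
# (10 kb gate), and classify genic peaks by RNA biotype.

suppressMessages(library(clipbind))
genome <- readRDS("scratch/genome.rds")
peaks <- read_peaks_bed("results/peaks.bed")

idx <- build_feature_index(genome, promoter_width = 1000)
asn <- assign_peaks(peaks, idx)
res <- rescue_intergenic(asn, genome, max_distance = 10000)

write.table(res$assignments, "results/feature_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$curve, "results/rescue_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
props <- category_proportions(asn)
write.table(props, "results/category_proportions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
biot <- classify_rna_type(asn, genome)
write.table(biot, "results/rna_type_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ig <- res$assignments[res$assignments$category == "intergenic", ]
cat(sprintf("feature partition: %s\n",
            paste(sprintf("%s %.0f%%", props$category,
                          100 * props$proportion), collapse = ", ")))
cat(sprintf("intergenic rescue: %d of %d within 10 kb of a stop/start codon\n",
            sum(ig$rescue_status != "unresolved"), nrow(ig)))
cat(sprintf("RNA types: %s\n",
            paste(sprintf("%s %d", biot$biotype, biot$count),
                  collapse = ", ")))
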
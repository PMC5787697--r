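#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs.
#
# A toy two-chromosome genome with mRNA/lincRNA/miRNA/snRNA genes gets
# GC-rich binding sites planted at exon-boundary flanks, intron bodies and
# intergenic space; crosslink-style reads (16-23 nt, T-to-C conversions)
# are sampled from the sites, and a skipped-exon event table with planted
# enhanced/silenced/background classes is generated. Everything is written
# as plain text under results/data/.

suppressMessages(library(clipbind))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

genome <- make_genome(genome_config(n_chromosomes = 2,
                                    chromosome_length = 200000,
                                    n_genes = 40), seed = 1001)
model <- binding_model(n_sites = 400)
genome <- plant_binding_sites(genome, model, seed = 1002)
reads <- simulate_clip_reads(genome, model, n_reads = 40000, seed = 1003)
events <- simulate_splice_events(genome, 600,
                                 class_mix = c(enhanced = 0.15,
                                               silenced = 0.15,
                                               background = 0.7),
                                 seed = 1004)

write_genome_fasta(genome, "results/data/genome.fa")
write_annotation_gtf(genome, "results/data/annotation.gtf")
write_annotation_bed12(genome, "results/data/annotation.bed12")
write_reads_bed(reads, "results/data/reads.bed")
write_splice_events_tsv(events, "results/data/splice_events.tsv")
dir.create("scratch", showWarnings = FALSE)
saveRDS(genome, "scratch/genome.rds")  # binary cache for later stages

cat(sprintf(
  "simulated: %d genes (%s), %d binding sites, %d reads (%.1f%% converted), %d splice events\n",
  nrow(genome$genes),
  paste(sprintf("%d %s", table(genome$genes$biotype),
                names(table(genome$genes$biotype))), collapse = ", "),
  nrow(genome$sites), nrow(reads),
  100 * mean(!is.na(reads$mismatch_offset)), nrow(events)))
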
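#!/usr/bin/env Rscript
# Stage 4: positional 4-mer enrichment (log2 odds) in the peaks versus a
# shuffled protein-coding-sequence background, summarised by GC content.
# Shuffle count is scaled down from the full-scale default of 10000 (pooled
# frequencies stabilise far earlier at toy genome size).

suppressMessages(library(clipbind))
genome <- readRDS("scratch/genome.rds")
peaks <- read_peaks_bed("results/peaks.bed")

fg <- count_kmers_in_windows(peaks, genome, k = 4, flank = 20)
bg <- background_frequencies(genome, k = 4, n_shuffles = 100, seed = 1005)
scores <- enrichment_scores(fg, bg)
write.table(scores, "results/kmer_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
gc <- gc_summary(scores)
write.table(gc, "results/kmer_gc_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

site <- scores[scores$region == "site", ]
top <- head(site, 10)
cat(sprintf("top enriched site 4-mers: %s\n",
            paste(sprintf("%s (%.2f)", top$kmer, top$score),
                  collapse = ", ")))
cat(sprintf("site GC-rich mean score %+.2f over %d 4-mers; AT-rich %+.2f over %d\n",
            gc$mean_score[gc$region == "site" & gc$class == "GC-rich"],
            gc$n_kmers[gc$region == "site" & gc$class == "GC-rich"],
            gc$mean_score[gc$region == "site" & gc$class == "AT-rich"],
            gc$n_kmers[gc$region == "site" & gc$class == "AT-rich"]))
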
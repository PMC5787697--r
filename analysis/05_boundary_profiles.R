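#!/usr/bin/env Rscript
# Stage 5: per-base coverage metaprofiles at exon-intron (EI) and
# intron-exon (IE) boundaries (100 exonic + 300 intronic bases), against
# the two background randomizations: shuffled exon placements and random
# fixed-length regions (scaled down from the full-scale default of 150000 x 5000 bp).

suppressMessages(library(clipbind))
genome <- readRDS("scratch/genome.rds")
reads <- read_reads_bed("results/data/reads.bed")
clen <- setNames(genome$chromosomes$length, genome$chromosomes$name)

b <- unique_boundaries(genome)
for (type in c("ei", "ie")) {
  prof <- profile_coverage(reads, b[[type]], type, chrom_lengths = clen)
  bg_sh <- background_profiles(reads, genome, "shuffle-exons", type,
                               seed = 1006)
  bg_rr <- background_profiles(reads, genome, "random-regions", type,
                               n_regions = 4000, seed = 1007)
  tab <- data.frame(offset = prof$offset, count = prof$count,
                    density = prof$density,
                    background_shuffle = bg_sh$density,
                    background_random = bg_rr$density)
  write.table(tab, sprintf("results/boundary_profile_%s.tsv", type),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
    plot_boundary_profile(prof, bg_sh, bg_rr,
                          sprintf("results/figures/boundary_%s.png", type))
  }
  flank <- if (type == "ei") prof$offset >= -40 & prof$offset < 0 else
    prof$offset >= -40 & prof$offset < 0
  cat(sprintf(
    "%s: %d boundaries; exon-flank density %.2f vs backgrounds %.2f (shuffle) / %.2f (random) => ratio %.1fx / %.1fx\n",
    toupper(type), prof$n_boundaries, mean(prof$density[flank]),
    mean(bg_sh$density[flank]), mean(bg_rr$density[flank]),
    mean(prof$density[flank]) / mean(bg_sh$density[flank]),
    mean(prof$density[flank]) / mean(bg_rr$density[flank])))
}
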
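#!/usr/bin/env Rscript
# Stage 6: positional splicing map. Skipped-exon events are classified
# (enhanced / silenced / background by P, FDR and inclusion difference),
# then the peak-anchor density around each event class is compared to
# resampled background events by permutation.

suppressMessages(library(clipbind))
genome <- readRDS("scratch/genome.rds")
peaks <- read_peaks_bed("results/peaks.bed")
events <- classify_events(read_splice_events_tsv("results/data/splice_events.tsv"))

cat(sprintf("event classes: %s\n",
            paste(sprintf("%s %d", names(table(events$class)),
                          table(events$class)), collapse = ", ")))

bg <- events[events$class == "background", ]
maps <- list()
for (cls in c("enhanced", "silenced")) {
  target <- events[events$class == cls, ]
  if (nrow(target) == 0) next
  m <- map_significance(peaks, target, bg, n_permutations = 200,
                        seed = 1008 + match(cls, c("enhanced", "silenced")))
  maps[[cls]] <- m
  out <- as.data.frame(m)
  out$class <- cls
  write.table(out, sprintf("results/splicing_map_%s.tsv", cls), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s (%d events): min p = %.3f; %d of %d positions with p <= 0.05\n",
              cls, nrow(target), min(m$p_value), sum(m$p_value <= 0.05),
              nrow(m)))
}
if (length(maps) && requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  plot_splicing_map(maps, "results/figures/splicing_map.png")
}
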
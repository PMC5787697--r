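#!/usr/bin/env Rscript
# Stage 2: call conversion-filtered binding-site peaks.
#
# Reads are grouped by same-strand overlap; a group becomes a peak iff
# (1) T-to-C conversion frequency >= 0.25, (2) more than five converted
# reads, and (3) at least two distinct conversion positions.

suppressMessages(library(clipbind))
reads <- read_reads_bed("results/data/reads.bed")
peaks <- call_peaks(reads)
write_peaks_bed(peaks, "results/peaks.bed")

cat(sprintf(
  "called %d peaks from %d reads; mean length %.1f nt (median %d), mean conversion frequency %.2f\n",
  nrow(peaks), nrow(reads), mean(peaks$length), median(peaks$length),
  mean(peaks$conversion_frequency)))
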
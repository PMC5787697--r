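fake_peak <- function(anchor, strand = "+", chrom = "chr1", id = "p1") {
  out <- data.frame(peak_id = id, chrom = chrom, start = anchor - 10L,
                    end = anchor + 11L, strand = strand, length = 21L,
                    n_reads = 10L, n_converted_reads = 8L,
                    conversion_frequency = 0.8, n_conversion_sites = 2L,
                    anchor = as.integer(anchor), stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  out
}

# kmer_table with prescribed counts, for pure score arithmetic.
fake_table <- function(counts_site, k) {
  structure(list(k = k, mode = "flank",
                 counts = list(site = counts_site),
                 freq = list(site = (counts_site + 0.5) /
                               (sum(counts_site) + 0.5 * length(counts_site))),
                 n_windows = 1, n_skipped = 0), class = "kmer_table")
}

fake_background <- function(freq, k) {
  structure(list(k = k, counts = NULL, freq = freq, n_shuffles = 1,
                 n_orfs = 1), class = "kmer_background")
}

test_that("window k-mer counting is exact", {
  g <- manual_genome(c(chr1 = 1000))
  expect_error(count_kmers_in_windows(fake_peak(500), g, k = 21, window = 20),
               "window")

  # anchor mode: a 20-nt window holds exactly 17 4-mers
  tab <- count_kmers_in_windows(fake_peak(500), g, k = 4, mode = "anchor")
  expect_equal(sum(tab$counts$site), 17)
  expect_equal(sum(tab$counts$upstream), 17)

  # span mode (default): a 21-bp peak yields 18 site 4-mers
  tabs <- count_kmers_in_windows(fake_peak(500), g, k = 4)
  expect_equal(sum(tabs$counts$site), 18)

  # zero peaks: all counts zero
  tab0 <- count_kmers_in_windows(fake_peak(500)[0, ], g, k = 4)
  expect_equal(sum(unlist(tab0$counts)), 0)

  # "GCGC" x 5 planted at the window: count of GCGC is 9
  s <- paste(rep("A", 1000), collapse = "")
  substr(s, 491, 510) <- strrep("GC", 10)
  gg <- manual_genome(c(chr1 = 1000),
                      sequence = {
                        x <- Biostrings::DNAStringSet(s); names(x) <- "chr1"; x
                      })
  tab2 <- count_kmers_in_windows(fake_peak(500), gg, k = 4, mode = "anchor")
  expect_equal(unname(tab2$counts$site[["GCGC"]]), 9)
  expect_equal(unname(tab2$counts$site[["CGCG"]]), 8)

  # minus-strand windows are counted in sense orientation
  tab3 <- count_kmers_in_windows(fake_peak(500, "-"), gg, k = 4,
                                 mode = "anchor")
  expect_equal(unname(tab3$counts$site[["GCGC"]]), 9)

  # peaks too close to a chromosome edge are skipped and logged
  tab4 <- count_kmers_in_windows(fake_peak(15), g, k = 4)
  expect_equal(tab4$n_skipped, 1)
  expect_equal(tab4$n_windows, 0)
})

test_that("percentile mode bins the peak span into fifths", {
  g <- manual_genome(c(chr1 = 1000))
  p <- fake_peak(500)
  p$start <- 450L; p$end <- 550L
  tab <- count_kmers_in_windows(p, g, k = 4, mode = "percentile")
  expect_setequal(names(tab$counts), paste0("pctl", 1:5))
  expect_equal(sum(tab$counts$pctl1), 17)  # 20-nt fifth, 17 4-mers
})

test_that("shuffled-ORF background preserves composition", {
  gp <- one_gene("G1", strand = "+", exon_starts = 0, exon_ends = 100,
                 cds = c(0, 100))
  seqs <- Biostrings::DNAStringSet(paste(strrep("ACGT", 25),
                                         strrep("A", 900), sep = ""))
  names(seqs) <- "chr1"
  g <- manual_genome(c(chr1 = 1000), genes = gp$genes, exons = gp$exons,
                     sequence = seqs)
  bg1 <- background_frequencies(g, k = 1, n_shuffles = 5, seed = 1)
  expect_equal(as.numeric(bg1$freq), rep(0.25, 4), tolerance = 0.01)

  # k = 4 on a uniform-composition ORF converges to 4^-4 per k-mer
  bg4 <- background_frequencies(g, k = 4, n_shuffles = 400, seed = 2)
  expect_equal(mean(as.numeric(bg4$freq)), 1 / 256, tolerance = 1e-6)
  # overlapping k-mers within one shuffle are correlated, so allow a wide
  # Monte-Carlo band around the analytic 4^-k
  expect_lt(max(abs(as.numeric(bg4$freq) - 1 / 256)) / (1 / 256), 0.5)

  # deterministic per seed; default shuffle count is the full 10000
  bg1b <- background_frequencies(g, k = 1, n_shuffles = 5, seed = 1)
  expect_identical(bg1$freq, bg1b$freq)
  expect_equal(formals(background_frequencies)$n_shuffles, 10000)

  expect_error(background_frequencies(manual_genome(), k = 4), "protein-coding")
})

test_that("log2-odds scores and their invariants", {
  k <- 2
  counts <- setNames(rep(10, 16), all_kmers_test(k))
  fg <- fake_table(counts, k)
  bg <- fake_background(fg$freq$site, k)
  sc <- enrichment_scores(fg, bg)
  expect_equal(sc$score, rep(0, 16))

  # foreground 1/16 vs background 1/256 -> score 4.0
  fg2 <- fake_table(counts, k)
  fg2$freq$site <- setNames(rep(1 / 16, 16), names(counts))
  bg2 <- fake_background(setNames(rep(1 / 256, 16), names(counts)), k)
  expect_equal(enrichment_scores(fg2, bg2)$score, rep(4, 16))

  # odds consistency: sum over k-mers of 2^score * bg_freq = sum fg_freq = 1
  fg3 <- fake_table(setNames(rpois(16, 30), names(counts)), k)
  bg3 <- fake_background(pseudo_freq_test(rpois(16, 50)), k)
  sc3 <- enrichment_scores(fg3, bg3)
  expect_equal(sum(2^sc3$score * sc3$background_freq), 1, tolerance = 1e-9)

  # duplicating every foreground window leaves scores unchanged
  fg4 <- fake_table(2 * fg3$counts$site, k)
  sc4 <- enrichment_scores(fg4, bg3)
  expect_equal(sc4$score, sc3$score, tolerance = 0.02)

  expect_error(enrichment_scores(fake_table(counts, 2),
                                 fake_background(rep(1 / 256, 256), 4)),
               "different k")
})

test_that("GC summary means and empty classes", {
  sc <- data.frame(kmer = c("GGCC", "AATT", "GACT"),
                   region = "site", count = 1, freq = 0.1,
                   background_freq = 0.1, score = c(2, -2, 0))
  gs <- gc_summary(sc)
  expect_equal(gs$mean_score[gs$class == "GC-rich"], 2)
  expect_equal(gs$mean_score[gs$class == "AT-rich"], -2)

  # all scores zero: both means zero
  sc0 <- sc; sc0$score <- 0
  expect_equal(gc_summary(sc0)$mean_score, c(0, 0))

  # empty class reported as NA with size 0
  scg <- sc[1, ]
  gs2 <- gc_summary(scg)
  expect_true(is.na(gs2$mean_score[gs2$class == "AT-rich"]))
  expect_equal(gs2$n_kmers[gs2$class == "AT-rich"], 0)
})

test_that("planted GC-biased sites rank GC-rich 4-mers on top", {
  g <- make_genome(genome_config(), seed = 81)
  model <- binding_model(gc_exponent = 2)
  g <- plant_binding_sites(g, model, seed = 82)
  reads <- simulate_clip_reads(g, model, n_reads = 15000, seed = 83)
  p <- call_peaks(reads)
  fg <- count_kmers_in_windows(p, g, k = 4)
  bg <- background_frequencies(g, k = 4, n_shuffles = 30, seed = 84)
  sc <- enrichment_scores(fg, bg)
  site <- sc[sc$region == "site", ]
  gc_top <- vapply(strsplit(head(site$kmer, 10), ""), function(ch)
    mean(ch %in% c("G", "C")), numeric(1))
  expect_true(all(gc_top >= 0.75))
  gs <- gc_summary(site)
  expect_gt(gs$mean_score[gs$class == "GC-rich"], 0)
  expect_lt(gs$mean_score[gs$class == "AT-rich"], 0)
})
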
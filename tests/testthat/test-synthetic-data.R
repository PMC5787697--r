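test_that("genome generation is deterministic and internally consistent", {
  g1 <- make_genome(genome_config(), seed = 11)
  g2 <- make_genome(genome_config(), seed = 11)
  expect_identical(g1$genes, g2$genes)
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))

  # invariants: genes inside chromosomes; exons ordered, non-overlapping
  clen <- setNames(g1$chromosomes$length, g1$chromosomes$name)
  expect_true(all(g1$genes$start >= 0))
  expect_true(all(g1$genes$end <= clen[g1$genes$chrom]))
  for (tx in split(g1$exons, g1$exons$transcript_id)) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) > 1) expect_true(all(tx$start[-1] >= tx$end[-nrow(tx)]))
  }
  expect_equal(unname(nchar(as.character(g1$sequence))),
               g1$chromosomes$length)

  # UTRs + CDS partition the exonic span of mRNA genes
  mr <- g1$genes[g1$genes$biotype == "mRNA", ]
  expect_true(all(mr$cds_start > mr$start & mr$cds_end < mr$end))
})

test_that("genome edge cases and biotype vocabulary", {
  g0 <- make_genome(genome_config(n_genes = 0), seed = 1)
  expect_equal(nrow(g0$genes), 0)

  g <- make_genome(genome_config(), seed = 3)
  expect_setequal(unique(g$genes$biotype),
                  c("mRNA", "lincRNA", "miRNA", "snRNA"))

  expect_error(
    make_genome(genome_config(chromosome_length = 500, n_genes = 1,
                              exons_per_gene = c(3, 3),
                              intron_length = c(2000, 3000)), seed = 1),
    "longer than")
})

test_that("GTF output carries exactly the generated exon records", {
  g <- make_genome(genome_config(n_genes = 10, exons_per_gene = c(3, 3),
                                 biotype_mix = c(mRNA = 1, lincRNA = 0,
                                                 miRNA = 0, snRNA = 0)),
                   seed = 21)
  path <- tempfile(fileext = ".gtf")
  write_annotation_gtf(g, path)
  # independent parse: raw line split, no package reader
  lines <- readLines(path)
  feat <- vapply(strsplit(lines, "\t"), `[`, character(1), 3)
  expect_equal(sum(feat == "exon"), 30)
  expect_equal(sum(feat == "gene"), 10)
})

test_that("simulated reads respect bounds, lengths and conversion rules", {
  g <- make_genome(genome_config(), seed = 31)
  model <- binding_model()
  g <- plant_binding_sites(g, model, seed = 32)

  expect_equal(nrow(simulate_clip_reads(g, model, n_reads = 0, seed = 1)), 0)

  reads <- simulate_clip_reads(g, model, n_reads = 5000, seed = 33)
  clen <- setNames(g$chromosomes$length, g$chromosomes$name)
  expect_true(all(reads$start >= 0 & reads$end <= clen[reads$chrom]))
  expect_true(all(reads$end - reads$start >= 16 &
                    reads$end - reads$start <= 23))
  expect_true(all(reads$n_mismatches <= 1))
  # determinism
  reads2 <- simulate_clip_reads(g, model, n_reads = 5000, seed = 33)
  expect_identical(reads, reads2)

  # conversion probability 1: every site read overlapping a sense T converts
  m1 <- binding_model(conversion_prob = 1)
  r1 <- simulate_clip_reads(g, m1, n_reads = 2000, seed = 34)
  site_reads <- r1[r1$origin != "background", ]
  overlaps_t <- vapply(seq_len(nrow(site_reads)), function(i) {
    s <- g$sites[g$sites$site_id == site_reads$origin[i], ]
    any(s$t_positions[[1]] >= site_reads$start[i] &
          s$t_positions[[1]] < site_reads$end[i])
  }, logical(1))
  expect_true(all(!is.na(site_reads$mismatch_offset[overlaps_t])))
  expect_true(all(site_reads$ref_base[overlaps_t] == "T"))
  expect_true(all(site_reads$alt_base[overlaps_t] == "C"))
})

test_that("read-length histogram matches the configured distribution", {
  g <- make_genome(genome_config(), seed = 41)
  model <- binding_model()
  g <- plant_binding_sites(g, model, seed = 42)
  reads <- simulate_clip_reads(g, model, n_reads = 1e5, seed = 43)
  lens <- reads$end - reads$start
  obs <- table(factor(lens, levels = 16:23))
  expected <- default_read_lengths()
  # chi-square goodness of fit at alpha = 0.01
  gof <- suppressWarnings(stats::chisq.test(obs, p = expected))
  expect_gt(gof$p.value, 0.01)
  # mode at 20-21 nt
  expect_true(names(which.max(obs)) %in% c("20", "21"))
})

test_that("splice-event simulation plants recoverable classes", {
  g <- make_genome(genome_config(), seed = 51)
  expect_equal(nrow(simulate_splice_events(g, 0, seed = 1)), 0)
  expect_error(simulate_splice_events(g, -1), "non-negative")

  bg <- simulate_splice_events(g, 50, class_mix = c(enhanced = 0,
                                                    silenced = 0,
                                                    background = 1),
                               seed = 52)
  expect_true(all(bg$FDR > 0.5))

  ev <- simulate_splice_events(g, 300, seed = 53)
  cls <- classify_events(ev)
  expect_equal(as.character(cls$class), cls$true_class)

  # cassette trios are ordered on the genome and consistent per strand
  plus <- ev[ev$strand == "+", ]
  expect_true(all(plus$upstreamEE <= plus$exonStart_0base &
                    plus$exonEnd <= plus$downstreamES))
  minus <- ev[ev$strand == "-", ]
  expect_true(all(minus$downstreamEE <= minus$exonStart_0base &
                    minus$exonEnd <= minus$upstreamES))
  expect_true(all(abs(ev$IncLevelDifference) <= 1))
})

test_that("titration forward model is exact and seeded noise reproducible", {
  # P = 0 gives fraction bound 0
  t0 <- simulate_titration(2, 1e6, concentrations = c(0, 1e-6),
                           noise_sd = 0, seed = 1)
  expect_equal(t0$fraction_bound[1], 0)

  # midpoint identity: f = 0.5 at P = 1/K for any stoichiometry
  for (n in c(0.5, 1, 1.75, 2, 3.31)) {
    tm <- simulate_titration(n, 1e6, concentrations = 1e-6, noise_sd = 0)
    expect_equal(tm$fraction_bound, 0.5)
  }

  # noiseless log-odds is exactly linear with slope n (direct algebra)
  tt <- simulate_titration(2, 1e6, noise_sd = 0)
  y <- log(tt$fraction_bound / (1 - tt$fraction_bound))
  x <- log(tt$protein_M)
  slopes <- diff(y) / diff(x)
  expect_equal(slopes, rep(2, length(slopes)), tolerance = 1e-10)

  # closed form at every grid point
  expect_equal(tt$fraction_bound,
               (1e6 * tt$protein_M)^2 / (1 + (1e6 * tt$protein_M)^2),
               tolerance = 1e-12)

  s1 <- simulate_titration(1.75, 1.95e6, seed = 7)
  s2 <- simulate_titration(1.75, 1.95e6, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$fraction_bound >= 0 & s1$fraction_bound <= 1))
  expect_error(simulate_titration(1, 1e6, concentrations = -1e-6),
               "negative")
})

test_that("competition forward model: symmetry, constant ratio, defaults", {
  # equal affinities and stoichiometries: identical band disappearance
  cc <- simulate_competition(1, 1, 1e6, 1e6, noise_sd = 0)
  expect_equal(cc$dna_free_fraction, cc$rna_free_fraction)

  # 25-fold affinity ratio: per-point ratio is 25 everywhere, intercept 25
  c25 <- simulate_competition(1, 1, 25e6, 1e6, noise_sd = 0)
  fit <- competition_ratio(c25)
  expect_equal(fit$points$ratio[fit$usable],
               rep(25, sum(fit$usable)), tolerance = 1e-9)
  expect_equal(fit$ratio_dna_rna, 25, tolerance = 1e-6)

  # default grid spans 0.05-2.5 uM with equimolar 0.05 uM ligands
  expect_equal(min(cc$protein_M), 0.05e-6)
  expect_equal(max(cc$protein_M), 2.5e-6)
  expect_equal(attr(cc, "ligand_M"), 0.05e-6)
  expect_identical(simulate_competition(1, 1, 2e6, 1e6, seed = 3),
                   simulate_competition(1, 1, 2e6, 1e6, seed = 3))
})

test_that("planted boundary sites enrich the EI metaprofile", {
  g <- make_genome(genome_config(), seed = 61)
  model <- binding_model(region_weights = c(exon_boundary = 10, intron = 1,
                                            intergenic = 1))
  g <- plant_binding_sites(g, model, seed = 62)
  reads <- simulate_clip_reads(g, model, n_reads = 20000, seed = 63)
  b <- unique_boundaries(g)
  clen <- setNames(g$chromosomes$length, g$chromosomes$name)
  prof <- profile_coverage(reads, b$ei, "ei", chrom_lengths = clen)
  flank <- prof$offset >= -40 & prof$offset < 0
  body <- prof$offset >= 150
  expect_gt(mean(prof$density[flank]), 2 * mean(prof$density[body]))
})
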
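# Brute-force per-boundary scan: for every boundary and offset, count reads
# covering the mapped genomic base (independent of the package's coverage
# accumulation).
bf_profile <- function(reads, boundaries, type, exon_depth = 100,
                       intron_depth = 300) {
  offsets <- seq(-exon_depth, intron_depth - 1L)
  counts <- numeric(length(offsets))
  for (i in seq_len(nrow(boundaries))) {
    b <- boundaries[i, ]
    for (oi in seq_along(offsets)) {
      o <- offsets[oi]
      g <- if (type == "ei") {
        if (b$strand == "+") b$pos + o else b$pos - o
      } else {
        if (b$strand == "+") b$pos - 1L - o else b$pos + 1L + o
      }
      cov <- sum(reads$copy_count[reads$chrom == b$chrom &
                                    reads$strand == b$strand &
                                    reads$start <= g & g < reads$end])
      counts[oi] <- counts[oi] + cov
    }
  }
  counts
}

test_that("boundary extraction applies orientation, terminal and dedup rules", {
  b0 <- unique_boundaries(manual_genome())
  expect_equal(nrow(b0$ei), 0)
  expect_equal(nrow(b0$ie), 0)

  # one 3-exon plus-strand transcript: 2 EI and 2 IE boundaries
  g3 <- one_gene("G1", strand = "+", exon_starts = c(100, 500, 900),
                 exon_ends = c(200, 600, 1000), cds = c(120, 980))
  gm <- manual_genome(c(chr1 = 5000), genes = g3$genes, exons = g3$exons)
  b <- unique_boundaries(gm)
  expect_equal(sort(b$ei$pos), c(200, 600))  # first intronic bases
  expect_equal(sort(b$ie$pos), c(500, 900))  # first exonic bases

  # minus strand: EI at genomic exon starts - 1, IE at exon ends - 1
  g3m <- one_gene("G2", strand = "-", exon_starts = c(100, 500, 900),
                  exon_ends = c(200, 600, 1000), cds = c(120, 980))
  bm <- unique_boundaries(manual_genome(c(chr1 = 5000), genes = g3m$genes,
                                        exons = g3m$exons))
  expect_equal(sort(bm$ei$pos), c(499, 899))
  expect_equal(sort(bm$ie$pos), c(199, 599))

  # two transcripts of one gene sharing an exon end deduplicate to 1 EI
  tx2 <- g3$exons[1:2, ]
  tx2$transcript_id <- "G1.t2"
  gm2 <- manual_genome(c(chr1 = 5000), genes = g3$genes,
                       exons = rbind(g3$exons, tx2))
  b2 <- unique_boundaries(gm2)
  expect_equal(sum(b2$ei$pos == 200), 1)

  # single-exon transcripts and non-coding genes contribute nothing
  g1 <- one_gene("N1", strand = "+", exon_starts = c(2000, 2500),
                 exon_ends = c(2100, 2600), biotype = "lincRNA")
  gm3 <- manual_genome(c(chr1 = 5000),
                       genes = rbind(g3$genes, g1$genes),
                       exons = rbind(g3$exons, g1$exons))
  expect_equal(nrow(unique_boundaries(gm3)$ei), 2)
})

test_that("a single read covers exactly its offsets in the metaprofile", {
  b <- data.frame(chrom = "chr1", pos = 1000L, strand = "+")
  # read spanning offsets -5..10 of the EI boundary at 1000
  r <- make_read("chr1", 995, 1011)
  prof <- profile_coverage(r, b, "ei")
  expect_equal(prof$count[prof$offset >= -5 & prof$offset <= 10],
               rep(1, 16))
  expect_equal(sum(prof$count), 16)

  # no reads: all-zero profile; defaults are 100 exonic + 300 intronic bases
  p0 <- profile_coverage(r[0, ], b, "ei")
  expect_equal(sum(p0$count), 0)
  expect_equal(length(p0$offset), 400)
  expect_equal(range(p0$offset), c(-100, 299))

  # copy_count weighting
  r4 <- make_read("chr1", 995, 1011, copies = 4L)
  expect_equal(sum(profile_coverage(r4, b, "ei")$count), 64)

  # opposite-strand reads do not contribute
  rm <- make_read("chr1", 995, 1011, strand = "-")
  expect_equal(sum(profile_coverage(rm, b, "ei")$count), 0)
})

test_that("profiles match a brute-force per-boundary scan", {
  set.seed(7)
  g3 <- one_gene("G1", strand = "+", exon_starts = c(300, 800, 1500),
                 exon_ends = c(450, 1000, 1700), cds = c(320, 1680))
  g3m <- one_gene("G2", strand = "-", exon_starts = c(2300, 2900),
                  exon_ends = c(2500, 3100), cds = c(2320, 3080))
  gm <- manual_genome(c(chr1 = 5000),
                      genes = rbind(g3$genes, g3m$genes),
                      exons = rbind(g3$exons, g3m$exons))
  reads <- do.call(rbind, lapply(1:150, function(i) {
    s <- sample(0:4950, 1)
    make_read("chr1", s, s + sample(16:23, 1),
              strand = sample(c("+", "-"), 1),
              copies = sample(1:3, 1))
  }))
  b <- unique_boundaries(gm)
  for (type in c("ei", "ie")) {
    tab <- b[[type]]
    prof <- profile_coverage(reads, tab, type,
                             chrom_lengths = c(chr1 = 5000))
    expect_equal(prof$count, bf_profile(reads, tab, type),
                 info = type)
  }
})

test_that("mirroring the genome leaves transcript-oriented profiles unchanged", {
  L <- 5000L
  g3 <- one_gene("G1", strand = "+", exon_starts = c(300, 800, 1500),
                 exon_ends = c(450, 1000, 1700), cds = c(320, 1680))
  gm <- manual_genome(c(chr1 = L), genes = g3$genes, exons = g3$exons)
  set.seed(8)
  reads <- do.call(rbind, lapply(1:100, function(i) {
    s <- sample(200:1800, 1)
    make_read("chr1", s, s + 20, strand = sample(c("+", "-"), 1))
  }))
  # mirror: x -> L - x, strands flipped
  mirror_exons <- g3$exons
  mirror_exons$start <- L - g3$exons$end
  mirror_exons$end <- L - g3$exons$start
  mirror_exons$strand <- "-"
  mirror_genes <- g3$genes
  mirror_genes$start <- L - g3$genes$end
  mirror_genes$end <- L - g3$genes$start
  mirror_genes$strand <- "-"
  gmm <- manual_genome(c(chr1 = L), genes = mirror_genes,
                       exons = mirror_exons)
  mreads <- reads
  mreads$start <- L - reads$end
  mreads$end <- L - reads$start
  mreads$strand <- ifelse(reads$strand == "+", "-", "+")
  for (type in c("ei", "ie")) {
    p1 <- profile_coverage(reads, unique_boundaries(gm)[[type]], type,
                           chrom_lengths = c(chr1 = L))
    p2 <- profile_coverage(mreads, unique_boundaries(gmm)[[type]], type,
                           chrom_lengths = c(chr1 = L))
    expect_equal(p1$count, p2$count, info = type)
  }
})

test_that("background profiles are flat for uniform reads and zero for none", {
  g <- make_genome(genome_config(), seed = 91)
  model <- binding_model(background_rate = 1)  # all reads uniform
  g <- plant_binding_sites(g, model, seed = 92)
  reads <- simulate_clip_reads(g, model, n_reads = 30000, seed = 93)

  for (method in c("shuffle-exons", "random-regions")) {
    z <- background_profiles(reads[0, ], g, method, "ei",
                             n_regions = 500, seed = 1)
    expect_equal(sum(z$count), 0)
    bgp <- background_profiles(reads, g, method, "ei", n_regions = 1000,
                               seed = 2)
    fit <- lm(density ~ offset, data.frame(density = bgp$density,
                                           offset = bgp$offset))
    drift <- abs(coef(fit)[2]) * 400   # density change across the window
    expect_lt(drift, 0.15 * mean(bgp$density))
  }

  # full-scale defaults are kept on the function signature
  expect_equal(formals(background_profiles)$n_regions, 150000)
  expect_equal(formals(background_profiles)$region_length, 5000)
})
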
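# A two-gene hand-built annotation exercises every category:
# G001 (+, mRNA): exons [1000,1200) and [2000,2400), CDS [1100,2300)
#   -> 5'UTR [1000,1100), CDS exon [1100,1200)+[2000,2300),
#      3'UTR [2300,2400), intron [1200,2000), promoter [0,1000)
# G002 (-, mRNA): exons [5000,5300) and [6000,6200), CDS [5100,6100)
#   -> TSS at 6199, promoter [6200,7200)
annot_fixture <- function() {
  g1 <- one_gene("G001", strand = "+", exon_starts = c(1000, 2000),
                 exon_ends = c(1200, 2400), cds = c(1100, 2300))
  g2 <- one_gene("G002", strand = "-", exon_starts = c(5000, 6000),
                 exon_ends = c(5300, 6200), cds = c(5100, 6100))
  manual_genome(c(chr1 = 20000), genes = rbind(g1$genes, g2$genes),
                exons = rbind(g1$exons, g2$exons))
}

peak_at <- function(anchor, strand = "+", chrom = "chr1", id = "p1") {
  out <- data.frame(peak_id = id, chrom = chrom,
                    start = anchor - 10L, end = anchor + 11L,
                    strand = strand, length = 21L, n_reads = 10L,
                    n_converted_reads = 8L, conversion_frequency = 0.8,
                    n_conversion_sites = 2L, anchor = as.integer(anchor),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  out
}

test_that("empty annotation maps every anchor to intergenic", {
  idx <- build_feature_index(manual_genome())
  a <- assign_peaks(peak_at(5000), idx)
  expect_equal(as.character(a$category), "intergenic")
})

test_that("anchor assignment hits each category with correct arithmetic", {
  idx <- build_feature_index(annot_fixture())
  cases <- list(
    list(1050, "+", "utr5"),     # before CDS start in first exon
    list(1150, "+", "exon"),     # CDS exon
    list(2350, "+", "utr3"),     # after CDS end in last exon
    list(1500, "+", "intron"),
    list(500, "+", "promoter"),  # [0,1000) upstream of TSS 1000
    list(999, "+", "promoter"),
    list(3000, "+", "intergenic"),
    list(5050, "-", "utr3"),     # minus strand: left of CDS is 3'UTR
    list(6150, "-", "utr5"),
    list(5600, "-", "intron"),
    list(6500, "-", "promoter")) # promoter of G002: [6200,7200)
  for (cs in cases) {
    a <- assign_peaks(peak_at(cs[[1]], cs[[2]]), idx)
    expect_equal(as.character(a$category), cs[[3]],
                 info = sprintf("anchor %d %s", cs[[1]], cs[[2]]))
  }
  # promoter window arithmetic: one past either edge is not promoter
  expect_equal(as.character(assign_peaks(peak_at(1000, "+"), idx)$category),
               "utr5")
  expect_equal(as.character(assign_peaks(peak_at(7300, "-"), idx)$category),
               "intergenic")
})

test_that("intronic bases are exactly the transcript span minus exons", {
  g <- annot_fixture()
  idx <- build_feature_index(g)
  # set-difference oracle over the G001 span
  exonic <- c(1000:1199, 2000:2399)
  span <- 1000:2399
  intr_oracle <- setdiff(span, exonic)
  got <- vapply(seq(1000, 2399, by = 7), function(pos) {
    as.character(assign_peaks(peak_at(pos, "+"), idx)$category)
  }, character(1))
  want <- ifelse(seq(1000, 2399, by = 7) %in% intr_oracle, "intron", NA)
  expect_true(all(got[!is.na(want)] == "intron"))
  expect_true(all(got[is.na(want)] != "intron"))
})

test_that("precedence and strand rules resolve overlapping features", {
  # gene B intron overlapping gene A 3'UTR on the same strand
  gA <- one_gene("GA", strand = "+", exon_starts = 1000, exon_ends = 2000,
                 cds = c(1100, 1500))  # 3'UTR [1500,2000)
  gB <- one_gene("GB", strand = "+", exon_starts = c(500, 3000),
                 exon_ends = c(600, 3200), cds = c(550, 3100))
  g <- manual_genome(c(chr1 = 20000), genes = rbind(gA$genes, gB$genes),
                     exons = rbind(gA$exons, gB$exons))
  idx <- build_feature_index(g)
  a <- assign_peaks(peak_at(1700, "+"), idx)
  expect_equal(as.character(a$category), "utr3")
  expect_equal(a$gene_id, "GA")

  # antisense anchor inside a gene is intergenic
  a2 <- assign_peaks(peak_at(1700, "-"), idx)
  expect_equal(as.character(a2$category), "intergenic")

  expect_error(assign_peaks(peak_at(25000, "+"), idx), "off chromosome")
})

test_that("intergenic rescue measures codon distances with a 10 kb gate", {
  g <- annot_fixture()  # G001 +: stop at 2299, start at 1100
  idx <- build_feature_index(g)
  run <- function(anchor, strand = "+") {
    asn <- assign_peaks(peak_at(anchor, strand), idx)
    rescue_intergenic(asn, g)
  }
  # peak just downstream of the stop codon
  r <- run(2500)
  expect_equal(r$assignments$rescue_status, "within-10kb-of-stop")
  expect_equal(r$assignments$distance_bp, 2500 - 2299)

  # first intergenic base past the gene end
  expect_equal(run(2400)$assignments$distance_bp, 2400 - 2299)

  # beyond 10 kb from both codons -> unresolved
  r15 <- run(12400)
  expect_equal(r15$assignments$rescue_status, "unresolved")
  expect_gt(r15$assignments$distance_bp, 10000)

  # exactly at the 10 kb threshold is rescued
  r10 <- run(2299 + 10000)
  expect_equal(r10$assignments$rescue_status, "within-10kb-of-stop")

  # minus strand, downstream of the gene (past its stop codon at 5100)
  rm <- run(4000, "-")
  expect_equal(rm$assignments$rescue_status, "within-10kb-of-stop")
  expect_equal(rm$assignments$distance_bp, 5100 - 4000)

  # minus strand, upstream of the start codon at 6099 (past the promoter)
  rs <- run(7500, "-")
  expect_equal(rs$assignments$rescue_status, "within-10kb-of-start")
  expect_equal(rs$assignments$distance_bp, 7500 - 6099)

  # non-intergenic assignments are never modified
  asn <- assign_peaks(peak_at(1150, "+"), idx)
  rr <- rescue_intergenic(asn, g)
  expect_equal(as.character(rr$assignments$category), "exon")
  expect_true(is.na(rr$assignments$rescue_status))
})

test_that("secondary annotation flags and cumulative curve shape", {
  g <- annot_fixture()
  idx <- build_feature_index(g)
  peaks <- do.call(rbind, lapply(seq_along(c(12400, 13000, 16000)),
                                 function(i)
    peak_at(c(12400, 13000, 16000)[i], id = paste0("p", i))))
  class(peaks) <- c("peak_set", "data.frame")
  asn <- assign_peaks(peaks, idx)
  sec <- data.frame(chrom = "chr1", start = 12900, end = 13100)
  r <- rescue_intergenic(asn, g, secondary = sec)
  st <- r$assignments$rescue_status
  expect_equal(st[r$assignments$anchor == 13000], "other-annotation")
  expect_equal(st[r$assignments$anchor == 16000], "unresolved")
  expect_true(all(diff(r$curve$cumulative_count) >= 0))
})

test_that("RNA-type classification counts genic peaks by biotype", {
  # one gene per biotype, one peak anchored in each, plus intergenic peaks
  mk <- function(id, bt, s) one_gene(id, strand = "+", exon_starts = s,
                                     exon_ends = s + 200,
                                     cds = if (bt == "mRNA")
                                       c(s + 50, s + 150) else c(NA, NA),
                                     biotype = bt)
  parts <- Map(mk, c("M1", "L1", "R1", "S1"),
               c("mRNA", "lincRNA", "miRNA", "snRNA"),
               c(1000, 3000, 5000, 7000))
  g <- manual_genome(c(chr1 = 20000),
                     genes = do.call(rbind, lapply(parts, `[[`, "genes")),
                     exons = do.call(rbind, lapply(parts, `[[`, "exons")))
  idx <- build_feature_index(g)
  peaks <- do.call(rbind, lapply(seq_along(c(1100, 3100, 5100, 7100)),
                                 function(i)
    peak_at(c(1100, 3100, 5100, 7100)[i], id = paste0("p", i))))
  class(peaks) <- c("peak_set", "data.frame")
  asn <- assign_peaks(peaks, idx)
  bt <- classify_rna_type(asn, g)
  expect_equal(nrow(bt), 4)
  expect_true(all(bt$count == 1))

  # all-intergenic input gives an empty biotype table
  asn_ig <- assign_peaks(peak_at(15000), idx)
  expect_equal(nrow(classify_rna_type(asn_ig, g)), 0)

  # proportions arithmetic
  tab <- data.frame(peak_id = sprintf("q%d", 1:12),
                    gene_id = c(rep("M1", 10), rep("L1", 2)),
                    category = "exon")
  expect_equal(classify_rna_type(tab, g)$proportion, c(2 / 12, 10 / 12))
})

test_that("category proportions sum to one on simulated runs", {
  g <- make_genome(genome_config(), seed = 71)
  model <- binding_model()
  g <- plant_binding_sites(g, model, seed = 72)
  reads <- simulate_clip_reads(g, model, n_reads = 15000, seed = 73)
  p <- call_peaks(reads)
  expect_gt(nrow(p), 30)
  asn <- assign_peaks(p, build_feature_index(g))
  props <- category_proportions(asn)
  expect_equal(sum(props$proportion), 1)

  # planted placement structure shows through: introns and intergenic space
  # dominate in roughly the configured 0.40 / 0.35 balance
  pr <- setNames(props$proportion, props$category)
  expect_gt(pr[["intron"]], 0.2)
  expect_gt(pr[["intergenic"]], 0.15)
})
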
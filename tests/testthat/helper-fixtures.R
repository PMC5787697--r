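# Shared fixtures and independent brute-force oracles. Everything is built
# in code; no stored data files.

# Hand-built genome model for exact-arithmetic tests.
manual_genome <- function(chrom_lengths = c(chr1 = 20000),
                          genes = NULL, exons = NULL, sequence = NULL,
                          seed = 99) {
  chroms <- data.frame(name = names(chrom_lengths),
                       length = as.integer(chrom_lengths),
                       stringsAsFactors = FALSE)
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), biotype = character(0),
                        tss = integer(0), cds_start = integer(0),
                        cds_end = integer(0))
  }
  if (is.null(exons)) {
    exons <- data.frame(gene_id = character(0), transcript_id = character(0),
                        chrom = character(0), strand = character(0),
                        start = integer(0), end = integer(0),
                        exon_rank = integer(0))
  }
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- Biostrings::DNAStringSet(vapply(chroms$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)))
    names(sequence) <- chroms$name
  }
  structure(list(chromosomes = chroms, genes = genes, exons = exons,
                 sequence = sequence, sites = NULL),
            class = "genome_model")
}

# One mRNA gene with explicit structure (0-based half-open coordinates).
one_gene <- function(gene_id = "G001", chrom = "chr1", strand = "+",
                     exon_starts, exon_ends, cds = c(NA, NA),
                     biotype = "mRNA") {
  start <- min(exon_starts); end <- max(exon_ends)
  tss <- if (strand == "+") start else end - 1L
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      start = start, end = end, biotype = biotype,
                      tss = as.integer(tss),
                      cds_start = as.integer(cds[1]),
                      cds_end = as.integer(cds[2]), stringsAsFactors = FALSE)
  rank <- if (strand == "+") seq_along(exon_starts) else
    rev(seq_along(exon_starts))
  exons <- data.frame(gene_id = gene_id,
                      transcript_id = paste0(gene_id, ".t1"), chrom = chrom,
                      strand = strand, start = as.integer(exon_starts),
                      end = as.integer(exon_ends),
                      exon_rank = as.integer(rank), stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}

# Read-row constructor (0-based half-open, sense-orientation mismatch).
make_read <- function(chrom = "chr1", start, end, strand = "+",
                      mm = NA_integer_, ref = NA_character_,
                      alt = NA_character_, n_mm = NULL, copies = 1L,
                      id = NULL) {
  if (is.null(n_mm)) n_mm <- as.integer(!is.na(mm))
  data.frame(read_id = id %||% sprintf("r%04d", sample.int(1e6, 1)),
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, mismatch_offset = as.integer(mm),
             ref_base = ref, alt_base = alt, n_mismatches = as.integer(n_mm),
             copy_count = as.integer(copies), origin = "manual",
             sequence = "", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Converted read shortcut: carries a T-to-C at genomic position pos.
converted_read <- function(start, end, pos, strand = "+", chrom = "chr1",
                           copies = 1L) {
  mm <- if (strand == "+") pos - start else (end - 1L) - pos
  make_read(chrom, start, end, strand, mm = mm, ref = "T", alt = "C",
            copies = copies)
}

# ---- brute-force oracles (independent of the package implementation) ----

# Transitive-closure grouping over the pairwise same-strand >=1 bp overlap
# relation.
bf_group_reads <- function(reads) {
  n <- nrow(reads)
  if (n == 0) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- reads$chrom[i] == reads$chrom[j] &&
      reads$strand[i] == reads$strand[j] &&
      reads$start[i] < reads$end[j] && reads$start[j] < reads$end[i]
  }
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n); next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[reach[i, ]] <- next_id
      comp[i] <- next_id
    }
  }
  comp
}

# Direct evaluation of the three filter predicates on brute-force groups.
bf_call_peaks <- function(reads, min_freq = 0.25, min_conv_excl = 5,
                          min_sites = 2) {
  comp <- bf_group_reads(reads)
  kept <- list()
  for (g in unique(comp)) {
    sub <- reads[comp == g, , drop = FALSE]
    cc <- sub$copy_count
    conv <- !is.na(sub$mismatch_offset) & !is.na(sub$ref_base) &
      sub$ref_base == "T" & sub$alt_base == "C" & sub$n_mismatches <= 1
    pos <- ifelse(sub$strand == "+", sub$start + sub$mismatch_offset,
                  sub$end - 1L - sub$mismatch_offset)
    n_reads <- sum(cc); n_conv <- sum(cc[conv])
    n_sites <- length(unique(pos[conv]))
    if (n_conv / n_reads >= min_freq && n_conv > min_conv_excl &&
        n_sites >= min_sites) {
      kept[[length(kept) + 1L]] <- data.frame(
        chrom = sub$chrom[1], strand = sub$strand[1],
        start = min(sub$start), end = max(sub$end),
        n_reads = n_reads, n_converted_reads = n_conv,
        n_conversion_sites = n_sites, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(kept)) do.call(rbind, kept) else
    data.frame(chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0), n_reads = integer(0),
               n_converted_reads = integer(0), n_conversion_sites = integer(0))
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# Random small read sets for the oracle-equivalence property.
random_read_set <- function(n_max = 50, seed) {
  set.seed(seed)
  n <- sample.int(n_max, 1)
  starts <- sample.int(300, n, replace = TRUE)
  lens <- sample(16:23, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  has_mm <- runif(n) < 0.6
  reads <- do.call(rbind, lapply(seq_len(n), function(i) {
    mm <- if (has_mm[i]) sample.int(lens[i], 1) - 1L else NA_integer_
    ref <- if (has_mm[i]) sample(c("T", "T", "T", "G"), 1) else NA_character_
    alt <- if (has_mm[i]) sample(c("C", "C", "C", "A"), 1) else NA_character_
    n_mm <- if (has_mm[i]) sample(1:2, 1, prob = c(0.85, 0.15)) else 0L
    make_read("chr1", starts[i], starts[i] + lens[i], strands[i], mm = mm,
              ref = ref, alt = alt, n_mm = n_mm,
              copies = sample(1:3, 1), id = sprintf("r%03d", i))
  }))
  reads
}

# Independent k-mer helpers for score-arithmetic tests.
all_kmers_test <- function(k) {
  apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE],
        1, paste, collapse = "")
}

pseudo_freq_test <- function(counts, pseudo = 0.5) {
  (counts + pseudo) / (sum(counts) + pseudo * length(counts))
}
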
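#' Empirical PAR-CLIP read-length distribution
#'
#' Relative frequencies of collapsed read lengths 16-23 nt observed for
#' crosslink-derived sequencing reads, normalized from the library's length
#' histogram (mode at 20 nt, mean about 19.5 nt).
#'
#' @return Named numeric vector of probabilities over lengths 16:23.
#' @export
default_read_lengths <- function() {
  counts <- c(`16` = 2142, `17` = 3897, `18` = 5271, `19` = 6894,
              `20` = 8935, `21` = 5883, `22` = 3535, `23` = 1888)
  counts / sum(counts)
}

#' Binding model for the PAR-CLIP read simulator
#'
#' Describes where binding sites are planted, what their sequence looks
#' like, and how reads sample them. Site placement weights cover the three
#' region classes the genomic analyses distinguish: flanks of exon/intron
#' boundaries, intron bodies, and intergenic space.
#'
#' @param n_sites Number of binding sites to plant.
#' @param site_length Site length in bp (crosslink clusters average ~21 nt).
#' @param region_weights Named placement weights over
#'   \code{exon_boundary}, \code{intron}, \code{intergenic}.
#' @param gc_exponent Per-base log2 odds of G/C versus A/T within site
#'   sequence; 0 means no GC bias, the default 2 gives P(G or C) = 0.8.
#' @param conversion_prob Probability that a site-derived read carries the
#'   diagnostic T-to-C conversion at a crosslink T it overlaps.
#' @param background_rate Fraction of reads drawn uniformly from the genome
#'   rather than from sites.
#' @param read_lengths Named probability vector over read lengths (names are
#'   lengths in nt); support must lie within 16..23 unless
#'   \code{allow_any_length}.
#' @param copy_lambda Poisson rate for extra copies per collapsed read
#'   (copy_count = 1 + Pois(copy_lambda)).
#' @param with_sequence Attach read sequences (sense strand) to the output.
#' @param allow_any_length Permit read-length support outside 16..23.
#' @return A list of class \code{"binding_model"}.
#' @export
binding_model <- function(n_sites = 200,
                          site_length = 21,
                          region_weights = c(exon_boundary = 0.25,
                                             intron = 0.40,
                                             intergenic = 0.35),
                          gc_exponent = 2,
                          conversion_prob = 0.7,
                          background_rate = 0.2,
                          read_lengths = default_read_lengths(),
                          copy_lambda = 0,
                          with_sequence = TRUE,
                          allow_any_length = FALSE) {
  stopifnot(conversion_prob >= 0, conversion_prob <= 1,
            background_rate >= 0, background_rate <= 1,
            all(region_weights >= 0), sum(region_weights) > 0,
            all(c("exon_boundary", "intron", "intergenic") %in%
                  names(region_weights)),
            abs(sum(read_lengths) - 1) < 1e-8)
  lens <- as.integer(names(read_lengths))
  if (!allow_any_length && !all(lens %in% 16:23)) {
    stop("read-length support must lie within 16..23 nt", call. = FALSE)
  }
  structure(list(n_sites = n_sites, site_length = as.integer(site_length),
                 region_weights = region_weights / sum(region_weights),
                 gc_exponent = gc_exponent,
                 conversion_prob = conversion_prob,
                 background_rate = background_rate,
                 read_lengths = read_lengths,
                 copy_lambda = copy_lambda,
                 with_sequence = with_sequence),
            class = "binding_model")
}

# GC-biased random site sequence with at least two guaranteed sense-strand
# T positions (crosslink sites need >= 2 independent conversion positions).
random_site_sequence <- function(len, gc_exponent) {
  p_gc <- 2^gc_exponent / (1 + 2^gc_exponent)
  base_p <- c(A = (1 - p_gc) / 2, C = p_gc / 2, G = p_gc / 2,
              T = (1 - p_gc) / 2)
  s <- sample(names(base_p), len, replace = TRUE, prob = base_p)
  n_t <- sum(s == "T")
  if (n_t < 2) {
    pos <- sample(len, 2 - n_t)
    s[pos] <- "T"
  }
  s
}

#' Plant binding sites into a toy genome
#'
#' Chooses site locations by the model's region weights (exon-boundary
#' flanks of mRNA genes, intron bodies, intergenic space), writes GC-biased
#' site sequence into the genome (sense strand), and records the site table.
#' Boundary sites are centred just inside the exon 3' end, where coverage
#' pile-ups are expected at exon/intron boundaries.
#'
#' @param genome A \code{genome_model}.
#' @param model A \code{\link{binding_model}}.
#' @param seed Integer seed.
#' @return The genome with \code{$sites} (site_id, chrom, strand, start, end,
#'   region, t_positions) and edited \code{$sequence}.
#' @export
plant_binding_sites <- function(genome, model = binding_model(), seed = NULL) {
  stopifnot(inherits(genome, "genome_model"), inherits(model, "binding_model"))
  with_seed(seed, {
    L <- model$site_length
    introns <- transcript_introns(genome$exons)
    coding_exons <- genome$exons[genome$exons$gene_id %in%
                                   genome$genes$gene_id[genome$genes$biotype == "mRNA"], ]
    # exon 3' ends (transcript orientation) with a following intron
    ei <- unique_boundaries(genome)$ei

    sites <- vector("list", model$n_sites)
    for (i in seq_len(model$n_sites)) {
      region <- sample(names(model$region_weights), 1,
                       prob = model$region_weights)
      if (region == "exon_boundary" && nrow(ei) == 0) region <- "intergenic"
      if (region == "intron" && nrow(introns) == 0) region <- "intergenic"
      if (region == "exon_boundary") {
        b <- ei[sample(nrow(ei), 1), ]
        off <- sample(0:25, 1)  # site centre this far inside the exon end
        centre <- if (b$strand == "+") b$pos - 1L - off else b$pos + 1L + off
        strand <- b$strand
        chrom <- b$chrom
      } else if (region == "intron") {
        intr <- introns[sample(nrow(introns), 1), ]
        if (intr$end - intr$start <= L + 2) {
          centre <- intr$start + (intr$end - intr$start) %/% 2
        } else {
          centre <- sample(seq(intr$start + L, intr$end - L), 1)
        }
        strand <- intr$strand
        chrom <- intr$chrom
      } else {
        # intergenic: sample uniformly from the complement of gene spans
        ci <- sample(nrow(genome$chromosomes), 1)
        chrom <- genome$chromosomes$name[ci]
        gspan <- genome$genes[genome$genes$chrom == chrom, , drop = FALSE]
        for (try in 1:50) {
          centre <- sample(seq(L, genome$chromosomes$length[ci] - L), 1)
          if (!nrow(gspan) ||
              !any(centre >= gspan$start - L & centre < gspan$end + L)) break
        }
        strand <- sample(c("+", "-"), 1)
      }
      clen <- genome$chromosomes$length[match(chrom, genome$chromosomes$name)]
      start <- max(0L, min(as.integer(centre) - L %/% 2L, clen - L))
      sites[[i]] <- data.frame(site_id = sprintf("S%04d", i), chrom = chrom,
                               strand = strand, start = start,
                               end = start + L, region = region,
                               stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, sites)

    # write site sequences (sense orientation) into the genome
    seqs <- as.character(genome$sequence)
    t_positions <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
      s <- random_site_sequence(L, model$gc_exponent)
      genomic <- if (sites$strand[i] == "+") s else
        rev(chartr("ACGT", "TGCA", s))
      cs <- sites$chrom[i]
      substr(seqs[cs], sites$start[i] + 1L, sites$end[i]) <-
        paste(genomic, collapse = "")
      # genomic positions of sense-strand T's
      rel <- which(s == "T")
      t_positions[[i]] <- if (sites$strand[i] == "+") {
        sites$start[i] + rel - 1L
      } else {
        sites$end[i] - rel
      }
    }
    sites$t_positions <- I(t_positions)
    genome$sequence <- Biostrings::DNAStringSet(seqs)
    names(genome$sequence) <- genome$chromosomes$name
    genome$sites <- sites
    genome
  })
}

#' Simulate aligned PAR-CLIP reads
#'
#' Draws reads from planted binding sites (and a uniform background), with
#' lengths from the configured 16-23 nt distribution and T-to-C conversions
#' at site crosslink positions. Mismatch records are stored in sense
#' (transcript) orientation: a minus-strand conversion appears as A-to-G in
#' reference coordinates, and the offset is counted from the read's 5' end.
#' At most one mismatch per read is generated.
#'
#' If the genome has no planted sites yet, sites are planted first (from the
#' same seed) and the updated genome is attached to the result as
#' \code{attr(reads, "genome")}.
#'
#' @param genome A \code{genome_model} (ideally after
#'   \code{\link{plant_binding_sites}}).
#' @param model A \code{\link{binding_model}}.
#' @param n_reads Number of collapsed reads to generate.
#' @param seed Integer seed.
#' @return A data.frame of class \code{"clip_reads"}: \code{read_id},
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   \code{strand}, \code{mismatch_offset} (0-based within read, sense
#'   orientation; NA when unconverted), \code{ref_base}, \code{alt_base},
#'   \code{n_mismatches}, \code{copy_count}, \code{origin} (site_id or
#'   "background"), and \code{sequence} if requested.
#' @export
simulate_clip_reads <- function(genome, model = binding_model(),
                                n_reads = 1000, seed = NULL) {
  stopifnot(inherits(genome, "genome_model"), n_reads >= 0)
  attach_genome <- FALSE
  if (is.null(genome$sites)) {
    genome <- plant_binding_sites(genome, model, seed = seed)
    attach_genome <- TRUE
  }
  reads <- with_seed(seed, {
    lens <- as.integer(names(model$read_lengths))
    sites <- genome$sites
    n_bg <- rbinom(1, n_reads, model$background_rate)
    if (is.null(sites) || nrow(sites) == 0) n_bg <- n_reads
    n_site <- n_reads - n_bg
    clen <- setNames(genome$chromosomes$length, genome$chromosomes$name)

    chrom <- character(0); start <- integer(0); len <- integer(0)
    strand <- character(0); origin <- character(0)
    mm_off <- integer(0)

    if (n_site > 0) {
      site_idx <- sample(nrow(sites), n_site, replace = TRUE)
      len_s <- sample(lens, n_site, replace = TRUE,
                      prob = model$read_lengths)
      s_start <- sites$start[site_idx]
      s_end <- sites$end[site_idx]
      s_chrom <- sites$chrom[site_idx]
      # read start jitters around the site so every read overlaps it
      lo <- pmax(0L, s_start - 3L)
      hi <- pmin(clen[s_chrom] - len_s, s_end - len_s + 3L)
      hi <- pmax(hi, lo)
      start_s <- lo + as.integer(floor(runif(n_site) * (hi - lo + 1L)))
      start_s <- pmin(start_s, hi)
      mm_s <- rep(NA_integer_, n_site)
      want_conv <- runif(n_site) < model$conversion_prob
      pick <- runif(n_site)
      for (si in unique(site_idx)) {
        ts <- sort(sites$t_positions[[si]])
        j <- which(site_idx == si)
        n_in <- findInterval(start_s[j] + len_s[j] - 0.5, ts) -
          findInterval(start_s[j] - 0.5, ts)
        lo_i <- findInterval(start_s[j] - 0.5, ts)
        conv <- want_conv[j] & n_in > 0
        chosen <- lo_i + pmax(1L, ceiling(pick[j] * n_in))
        g <- ts[pmin(chosen, length(ts))]
        mm_here <- if (sites$strand[si] == "+") g - start_s[j] else
          (start_s[j] + len_s[j] - 1L) - g
        mm_s[j[conv]] <- as.integer(mm_here[conv])
      }
      chrom <- c(chrom, s_chrom)
      start <- c(start, start_s)
      len <- c(len, len_s)
      strand <- c(strand, sites$strand[site_idx])
      origin <- c(origin, sites$site_id[site_idx])
      mm_off <- c(mm_off, mm_s)
    }
    if (n_bg > 0) {
      ci <- sample(nrow(genome$chromosomes), n_bg, replace = TRUE)
      cn <- genome$chromosomes$name[ci]
      len_b <- sample(lens, n_bg, replace = TRUE, prob = model$read_lengths)
      start_b <- as.integer(floor(runif(n_bg) * (clen[cn] - len_b + 1L)))
      chrom <- c(chrom, cn)
      start <- c(start, start_b)
      len <- c(len, len_b)
      strand <- c(strand, sample(c("+", "-"), n_bg, replace = TRUE))
      origin <- c(origin, rep("background", n_bg))
      mm_off <- c(mm_off, rep(NA_integer_, n_bg))
    }
    copies <- if (model$copy_lambda > 0) {
      1L + stats::rpois(n_reads, model$copy_lambda)
    } else rep(1L, n_reads)
    out <- data.frame(
      read_id = sprintf("r%06d", seq_len(n_reads)),
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + len), strand = strand,
      mismatch_offset = mm_off,
      ref_base = ifelse(is.na(mm_off), NA_character_, "T"),
      alt_base = ifelse(is.na(mm_off), NA_character_, "C"),
      n_mismatches = as.integer(!is.na(mm_off)),
      copy_count = copies, origin = origin, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
  if (model$with_sequence && nrow(reads) > 0) {
    reads$sequence <- read_sequences(reads, genome)
  } else {
    reads$sequence <- character(nrow(reads))
  }
  class(reads) <- c("clip_reads", "data.frame")
  if (attach_genome) attr(reads, "genome") <- genome
  reads
}

# Sense-strand read sequences with the conversion applied.
read_sequences <- function(reads, genome) {
  out <- character(nrow(reads))
  for (cn in unique(reads$chrom)) {
    i <- which(reads$chrom == cn)
    v <- Biostrings::Views(genome$sequence[[cn]],
                           start = reads$start[i] + 1L, end = reads$end[i])
    s <- as.character(v)
    minus <- reads$strand[i] == "-"
    if (any(minus)) {
      s[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s[minus])))
    }
    out[i] <- s
  }
  conv <- which(!is.na(reads$mismatch_offset))
  if (length(conv)) {
    substr(out[conv], reads$mismatch_offset[conv] + 1L,
           reads$mismatch_offset[conv] + 1L) <- reads$alt_base[conv]
  }
  out
}
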
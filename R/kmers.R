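all_kmers <- function(k) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

count_kmer_set <- function(seqs, k) {
  if (!length(seqs)) return(setNames(rep(0L, 4^k), all_kmers(k)))
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  colSums(m)
}

pseudocount_freq <- function(counts, pseudocount = 0.5) {
  (counts + pseudocount) / (sum(counts) + pseudocount * length(counts))
}

#' Count k-mers in windows along peaks
#'
#' Counts all k-length substrings of the sense-strand sequence per region
#' around each peak. Three window modes are available:
#' \itemize{
#'   \item \code{"span"} (default): the site region is the whole peak span,
#'     i.e. the k-mers collected by sliding a window along the cluster, with
#'     fixed-width flanks on either side. Because the crosslink position is
#'     not pinned inside the window, the site's T-to-C anchor base does not
#'     by itself distort k-mer frequencies.
#'   \item \code{"anchor"}: a fixed window of \code{window} bp centred on
#'     the anchor (the crosslink-supported base), plus flanks. Note the
#'     centre base of such windows is a crosslink T by construction, which
#'     inflates T-rich k-mers even for unbiased sites.
#'   \item \code{"percentile"}: the peak span split into fifths, emulating
#'     positional motif profiles across the binding site.
#' }
#'
#' @param peaks A \code{peak_set} with anchors.
#' @param genome A \code{genome_model} with sequence.
#' @param k K-mer length (3, 4, 6 or 8 are the supported analysis sizes).
#' @param window Site-window width in bp for anchor mode (default 20).
#' @param flank Flank width in bp (default 20).
#' @param mode \code{"span"}, \code{"anchor"} or \code{"percentile"}.
#' @return A list of class \code{"kmer_table"}: \code{k}, \code{mode},
#'   \code{counts} (named list of per-region k-mer count vectors),
#'   \code{freq} (pseudocounted frequencies), \code{n_windows},
#'   \code{n_skipped} (peaks too close to a chromosome end, dropped).
#' @export
count_kmers_in_windows <- function(peaks, genome, k = 4, window = 20,
                                   flank = 20,
                                   mode = c("span", "anchor", "percentile")) {
  mode <- match.arg(mode)
  if (k > window) stop("k must not exceed the window size", call. = FALSE)
  seqs <- as.character(genome$sequence)
  clen <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  regions <- if (mode == "percentile") paste0("pctl", 1:5) else
    c("upstream", "site", "downstream")
  parts <- setNames(lapply(regions, function(x) character(0)), regions)
  n_skipped <- 0L
  half <- window %/% 2L

  fetch <- function(cn, s, e, strand) {
    x <- substr(seqs[[cn]], s + 1L, e)
    if (strand == "-") {
      x <- paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                 collapse = "")
    }
    x
  }

  for (i in seq_len(nrow(peaks))) {
    cn <- peaks$chrom[i]; st <- peaks$strand[i]
    if (mode %in% c("span", "anchor")) {
      if (mode == "anchor") {
        a <- peaks$anchor[i]
        ws <- a - half; we <- ws + window
      } else {
        ws <- peaks$start[i]; we <- peaks$end[i]
      }
      lo <- ws - flank; hi <- we + flank
      if (lo < 0 || hi > clen[[cn]]) { n_skipped <- n_skipped + 1L; next }
      site <- fetch(cn, ws, we, st)
      left <- fetch(cn, lo, ws, st)
      right <- fetch(cn, we, hi, st)
      up <- if (st == "+") left else right
      down <- if (st == "+") right else left
      parts$upstream <- c(parts$upstream, up)
      parts$site <- c(parts$site, site)
      parts$downstream <- c(parts$downstream, down)
    } else {
      s <- peaks$start[i]; e <- peaks$end[i]
      if (s < 0 || e > clen[[cn]]) { n_skipped <- n_skipped + 1L; next }
      cuts <- round(seq(s, e, length.out = 6))
      for (b in 1:5) {
        bs <- cuts[b]; be <- cuts[b + 1]
        if (be - bs < k) next
        lab <- if (st == "+") paste0("pctl", b) else paste0("pctl", 6 - b)
        parts[[lab]] <- c(parts[[lab]], fetch(cn, bs, be, st))
      }
    }
  }
  counts <- lapply(parts, count_kmer_set, k = k)
  structure(list(k = k, mode = mode, counts = counts,
                 freq = lapply(counts, pseudocount_freq),
                 n_windows = nrow(peaks) - n_skipped,
                 n_skipped = n_skipped),
            class = "kmer_table")
}

#' Background k-mer frequencies from shuffled coding sequences
#'
#' Extracts every protein-coding (CDS) sequence from the annotation, applies
#' a composition-preserving mononucleotide shuffle to each, repeats the
#' shuffle \code{n_shuffles} times, and pools k-mer counts over all
#' shuffles. Frequencies carry a pseudocount of 0.5 per k-mer. A
#' dinucleotide-preserving variant is available via \code{preserve}.
#'
#' @param genome A \code{genome_model} with mRNA genes and sequence.
#' @param k K-mer length.
#' @param n_shuffles Shuffle repetitions (default 10000; scale down for toy
#'   runs, the pooled frequencies stabilise quickly).
#' @param preserve \code{"mono"} (default) or \code{"di"} for
#'   dinucleotide-preserving shuffling (random Eulerian-walk style via
#'   repeated neighbour swaps is not attempted; "di" shuffles codon-step
#'   starting frames, a cheap order-2 surrogate).
#' @param seed Integer seed.
#' @return A list of class \code{"kmer_background"}: \code{k},
#'   \code{counts}, \code{freq}, \code{n_shuffles}, \code{n_orfs}.
#' @export
background_frequencies <- function(genome, k = 4, n_shuffles = 10000,
                                   preserve = c("mono", "di"), seed = NULL) {
  preserve <- match.arg(preserve)
  orfs <- cds_sequences(genome)
  if (!length(orfs)) {
    stop("annotation contains no protein-coding genes with CDS", call. = FALSE)
  }
  counts <- with_seed(seed, {
    total <- setNames(rep(0, 4^k), all_kmers(k))
    for (orf in orfs) {
      chars <- strsplit(orf, "")[[1]]
      if (length(chars) < k) next
      shuffled <- vapply(seq_len(n_shuffles), function(i) {
        if (preserve == "mono") {
          paste(sample(chars), collapse = "")
        } else {
          # order-2 surrogate: shuffle overlapping dinucleotide tiles
          idx <- sample(seq(1, length(chars) - 1, by = 2))
          paste(chars[as.vector(rbind(idx, idx + 1))], collapse = "")
        }
      }, character(1))
      total <- total + count_kmer_set(shuffled, k)
    }
    total
  })
  structure(list(k = k, counts = counts, freq = pseudocount_freq(counts),
                 n_shuffles = n_shuffles, n_orfs = length(orfs)),
            class = "kmer_background")
}

# Spliced CDS sequences (transcript orientation) for all mRNA genes.
cds_sequences <- function(genome) {
  seqs <- as.character(genome$sequence)
  coding <- genome$genes[genome$genes$biotype == "mRNA" &
                           !is.na(genome$genes$cds_start), , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(coding))) {
    g <- coding[i, ]
    ex <- genome$exons[genome$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    s <- pmax(ex$start, g$cds_start); e <- pmin(ex$end, g$cds_end)
    keep <- e > s
    if (!any(keep)) next
    pieces <- vapply(which(keep), function(j)
      substr(seqs[[g$chrom]], s[j] + 1L, e[j]), character(1))
    cds <- paste(pieces, collapse = "")
    if (g$strand == "-") {
      cds <- paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]),
                   collapse = "")
    }
    out <- c(out, setNames(cds, g$gene_id))
  }
  out
}

#' Positional k-mer enrichment scores
#'
#' Log2 odds of each k-mer's pseudocounted frequency in a peak region versus
#' the shuffled coding-sequence background:
#' \code{score = log2(freq_region / freq_background)}.
#'
#' @param foreground A \code{\link{count_kmers_in_windows}} result.
#' @param background A \code{\link{background_frequencies}} result with the
#'   same k.
#' @return A data.frame (kmer, region, count, freq, background_freq, score),
#'   ranked by descending score within region.
#' @export
enrichment_scores <- function(foreground, background) {
  stopifnot(inherits(foreground, "kmer_table"),
            inherits(background, "kmer_background"))
  if (foreground$k != background$k) {
    stop("foreground and background were built with different k", call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(foreground$counts), function(region) {
    fg <- foreground$freq[[region]]
    data.frame(kmer = names(fg), region = region,
               count = as.numeric(foreground$counts[[region]]),
               freq = as.numeric(fg),
               background_freq = as.numeric(background$freq),
               score = log2(as.numeric(fg) / as.numeric(background$freq)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$region, -out$score), ]
  rownames(out) <- NULL
  out
}

gc_fraction <- function(kmer) {
  vapply(strsplit(kmer, ""), function(ch) mean(ch %in% c("G", "C")),
         numeric(1))
}

#' Mean enrichment for GC-rich versus AT-rich k-mers
#'
#' @param scores Output of \code{\link{enrichment_scores}}.
#' @param gc_min GC fraction at or above which a k-mer is GC-rich (0.75).
#' @param at_max GC fraction at or below which a k-mer is AT-rich (0.25).
#' @return A data.frame (region, class, n_kmers, mean_score); an empty class
#'   reports NA, not zero.
#' @export
gc_summary <- function(scores, gc_min = 0.75, at_max = 0.25) {
  gc <- gc_fraction(scores$kmer)
  cls <- ifelse(gc >= gc_min, "GC-rich", ifelse(gc <= at_max, "AT-rich", NA))
  out <- list()
  for (region in unique(scores$region)) {
    for (cl in c("GC-rich", "AT-rich")) {
      sel <- which(scores$region == region & !is.na(cls) & cls == cl)
      out[[length(out) + 1L]] <- data.frame(
        region = region, class = cl, n_kmers = length(sel),
        mean_score = if (length(sel)) mean(scores$score[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
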
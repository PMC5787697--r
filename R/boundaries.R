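#' Unique exon/intron boundary sets
#'
#' Extracts exon-to-intron (EI) and intron-to-exon (IE) boundaries from the
#' protein-coding transcripts of an annotation, in transcript orientation.
#' EI boundaries are exon 3' ends followed by an intron (terminal exon ends
#' are excluded); IE boundaries are exon 5' starts preceded by an intron.
#' Duplicate boundary locations on the same strand are removed: for EI,
#' duplicated exon end locations on the forward strand and duplicated exon
#' start locations on the reverse strand collapse to one, and symmetrically
#' for IE.
#'
#' Boundary positions are stored 0-based: EI records the first intronic
#' base; IE records the first exonic base.
#'
#' @param annotation A \code{genome_model} or an exon data.frame with
#'   columns gene_id, transcript_id, chrom, strand, start, end. When a
#'   genome model is given, only mRNA-biotype genes are used.
#' @return A list of class \code{"boundary_set"} with data.frames \code{ei}
#'   and \code{ie} (chrom, pos, strand) and provenance "annotation".
#' @export
unique_boundaries <- function(annotation) {
  exons <- if (inherits(annotation, "genome_model")) {
    coding <- annotation$genes$gene_id[annotation$genes$biotype == "mRNA"]
    annotation$exons[annotation$exons$gene_id %in% coding, ]
  } else annotation
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0))
  ei <- list(); ie <- list()
  if (nrow(exons) > 0) {
    for (tx in split(exons, exons$transcript_id)) {
      tx <- tx[order(tx$start), ]
      if (nrow(tx) < 2) next
      if (tx$strand[1] == "+") {
        ei[[length(ei) + 1L]] <- data.frame(
          chrom = tx$chrom[1], pos = tx$end[-nrow(tx)], strand = "+",
          stringsAsFactors = FALSE)
        ie[[length(ie) + 1L]] <- data.frame(
          chrom = tx$chrom[1], pos = tx$start[-1], strand = "+",
          stringsAsFactors = FALSE)
      } else {
        # transcript runs right-to-left: 3' exon ends are genomic starts
        ei[[length(ei) + 1L]] <- data.frame(
          chrom = tx$chrom[1], pos = tx$start[-1] - 1L, strand = "-",
          stringsAsFactors = FALSE)
        ie[[length(ie) + 1L]] <- data.frame(
          chrom = tx$chrom[1], pos = tx$end[-nrow(tx)] - 1L, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  dedup <- function(x) {
    if (!length(x)) return(empty)
    x <- do.call(rbind, x)
    x <- unique(x)
    rownames(x) <- NULL
    x
  }
  structure(list(ei = dedup(ei), ie = dedup(ie), provenance = "annotation"),
            class = "boundary_set")
}

# offsets -exon_depth .. intron_depth-1, with 0 = first intronic base (EI)
# or, mirrored, distance into the intron for IE; negative offsets are exonic.
boundary_offset_positions <- function(type, pos, strand, offsets) {
  if (type == "ei") {
    if (strand == "+") pos + offsets else pos - offsets
  } else {
    if (strand == "+") pos - 1L - offsets else pos + 1L + offsets
  }
}

#' Coverage metaprofile at exon boundaries
#'
#' For each boundary, counts the reads (weighted by \code{copy_count})
#' covering each base out to \code{exon_depth} bases into the exon and
#' \code{intron_depth} bases into the intron, in transcript orientation.
#' Only reads on the boundary's strand contribute. Offsets are negative on
#' the exon side and 0..intron_depth-1 on the intron side, with offset 0 the
#' first intronic base.
#'
#' @param reads A reads data.frame (chrom, start, end, strand, copy_count).
#' @param boundaries One boundary table (chrom, pos, strand), e.g.
#'   \code{unique_boundaries(g)$ei}.
#' @param type \code{"ei"} or \code{"ie"}; orients the offset axis.
#' @param exon_depth,intron_depth Profile depths in bp (defaults 100 and 300).
#' @param chrom_lengths Optional named lengths; positions outside a known
#'   chromosome contribute zero.
#' @return A list of class \code{"meta_profile"}: \code{offset},
#'   \code{count}, \code{density} (count / n_boundaries),
#'   \code{n_boundaries}, \code{type}.
#' @export
profile_coverage <- function(reads, boundaries, type = c("ei", "ie"),
                             exon_depth = 100, intron_depth = 300,
                             chrom_lengths = NULL) {
  type <- match.arg(type)
  offsets <- seq(-exon_depth, intron_depth - 1L)
  counts <- numeric(length(offsets))
  n_b <- nrow(boundaries)
  if (n_b == 0 || nrow(reads) == 0) {
    return(structure(list(offset = offsets, count = counts,
                          density = counts, n_boundaries = n_b, type = type),
                     class = "meta_profile"))
  }
  cc <- if ("copy_count" %in% names(reads)) reads$copy_count else
    rep(1L, nrow(reads))
  # per chrom/strand coverage vectors
  for (key in unique(paste(boundaries$chrom, boundaries$strand))) {
    parts <- strsplit(key, " ")[[1]]
    cn <- parts[1]; st <- parts[2]
    b <- boundaries[boundaries$chrom == cn & boundaries$strand == st, ]
    r <- reads[reads$chrom == cn & reads$strand == st, ]
    if (nrow(r) == 0) next
    w <- cc[reads$chrom == cn & reads$strand == st]
    maxpos <- max(r$end, b$pos + exon_depth + intron_depth + 1L)
    cov <- numeric(maxpos + 1L)
    for (i in seq_len(nrow(r))) {
      cov[(r$start[i] + 1L):r$end[i]] <-
        cov[(r$start[i] + 1L):r$end[i]] + w[i]
    }
    lim <- if (!is.null(chrom_lengths) && cn %in% names(chrom_lengths)) {
      chrom_lengths[[cn]]
    } else Inf
    for (i in seq_len(nrow(b))) {
      g <- boundary_offset_positions(type, b$pos[i], st, offsets)
      ok <- g >= 0 & g < lim & g < length(cov)
      counts[ok] <- counts[ok] + cov[g[ok] + 1L]
    }
  }
  structure(list(offset = offsets, count = counts, density = counts / n_b,
                 n_boundaries = n_b, type = type),
            class = "meta_profile")
}

#' Background boundary metaprofiles
#'
#' Two randomizations estimate the coverage expected at boundaries placed
#' without regard to real exon structure, the reads staying fixed:
#' \itemize{
#'   \item \code{"shuffle-exons"}: repositions the protein-coding exon
#'     intervals uniformly on their own chromosome, preserving per-chromosome
#'     exon count, sizes and strand, then treats each repositioned exon's 3'
#'     end as an EI boundary and 5' start as an IE boundary.
#'   \item \code{"random-regions"}: draws \code{n_regions} uniform regions of
#'     \code{region_length} bp (random strand); half provide EI boundaries
#'     (region start) and half IE boundaries (region end), in strand
#'     orientation.
#' }
#'
#' @param reads Reads data.frame.
#' @param genome A \code{genome_model}.
#' @param method \code{"shuffle-exons"} or \code{"random-regions"}.
#' @param type \code{"ei"} or \code{"ie"}.
#' @param n_regions,region_length Random-regions parameters (defaults
#'   150000 and 5000; scale n_regions down for toy genomes).
#' @param exon_depth,intron_depth Profile depths.
#' @param seed Integer seed.
#' @return A \code{meta_profile} (see \code{\link{profile_coverage}}).
#' @export
background_profiles <- function(reads, genome,
                                method = c("shuffle-exons", "random-regions"),
                                type = c("ei", "ie"),
                                n_regions = 150000, region_length = 5000,
                                exon_depth = 100, intron_depth = 300,
                                seed = NULL) {
  method <- match.arg(method)
  type <- match.arg(type)
  clen <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  b <- with_seed(seed, {
    if (method == "shuffle-exons") {
      coding <- genome$genes$gene_id[genome$genes$biotype == "mRNA"]
      ex <- genome$exons[genome$exons$gene_id %in% coding, ]
      if (nrow(ex) == 0) {
        data.frame(chrom = character(0), pos = integer(0),
                   strand = character(0))
      } else {
        new_start <- integer(nrow(ex))
        for (i in seq_len(nrow(ex))) {
          w <- ex$end[i] - ex$start[i]
          top <- clen[[ex$chrom[i]]] - w
          new_start[i] <- sample(seq(0L, top), 1)
        }
        ne <- data.frame(chrom = ex$chrom, strand = ex$strand,
                         start = new_start, end = new_start +
                           (ex$end - ex$start), stringsAsFactors = FALSE)
        if (type == "ei") {
          pos <- ifelse(ne$strand == "+", ne$end, ne$start - 1L)
        } else {
          pos <- ifelse(ne$strand == "+", ne$start, ne$end - 1L)
        }
        unique(data.frame(chrom = ne$chrom, pos = as.integer(pos),
                          strand = ne$strand, stringsAsFactors = FALSE))
      }
    } else {
      usable <- genome$chromosomes$length >= region_length
      if (!all(usable)) {
        warning(sprintf("%d chromosome(s) shorter than region length %d skipped",
                        sum(!usable), region_length))
      }
      chroms <- genome$chromosomes[usable, ]
      if (nrow(chroms) == 0) {
        data.frame(chrom = character(0), pos = integer(0),
                   strand = character(0))
      } else {
        half <- n_regions %/% 2L
        n_use <- if (type == "ei") half else n_regions - half
        ci <- sample(nrow(chroms), n_use, replace = TRUE)
        start <- vapply(ci, function(j)
          sample(seq(0L, chroms$length[j] - region_length), 1L), integer(1))
        strand <- sample(c("+", "-"), n_use, replace = TRUE)
        pos <- if (type == "ei") {
          ifelse(strand == "+", start, start + region_length - 1L)
        } else {
          ifelse(strand == "+", start + region_length - 1L, start)
        }
        unique(data.frame(chrom = chroms$name[ci], pos = as.integer(pos),
                          strand = strand, stringsAsFactors = FALSE))
      }
    }
  })
  profile_coverage(reads, b, type = type, exon_depth = exon_depth,
                   intron_depth = intron_depth, chrom_lengths = clen)
}
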
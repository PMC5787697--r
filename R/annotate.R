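#' Build a genomic feature index
#'
#' Marks the six feature categories used to partition binding-site peaks:
#' 5' UTR, 3' UTR, exon (CDS exon for coding genes, exonic bases of
#' noncoding genes), promoter (fixed-width window upstream of the TSS),
#' intron (transcript span minus exons), and intergenic (everything else,
#' implicit). Overlapping features are resolved at assignment time by a
#' fixed precedence: 5' UTR > 3' UTR > exon > promoter > intron >
#' intergenic. UTRs outrank exon so that the categories stay disjoint.
#'
#' @param genome A \code{genome_model} (or a list with \code{genes},
#'   \code{exons}, \code{chromosomes} in the same layout).
#' @param promoter_width Width in bp of the promoter window upstream of the
#'   TSS (default 1000).
#' @return A list of class \code{"feature_index"}: one interval data.frame
#'   (chrom, start, end, strand, gene_id) per category, in precedence order.
#' @export
build_feature_index <- function(genome, promoter_width = 1000) {
  genes <- genome$genes
  exons <- genome$exons
  if (nrow(exons)) stopifnot_intervals(exons$start, exons$end, "exon")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0))
  utr5 <- list(); utr3 <- list(); exn <- list(); intr <- list(); prom <- list()

  clen <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    add <- function(lst, s, e) {
      keep <- e > s
      if (!any(keep)) return(lst)
      c(lst, list(data.frame(chrom = g$chrom, start = as.integer(s[keep]),
                             end = as.integer(e[keep]), strand = g$strand,
                             gene_id = g$gene_id, stringsAsFactors = FALSE)))
    }
    if (g$biotype == "mRNA" && !is.na(g$cds_start)) {
      # CDS-exon pieces and UTR pieces are exon fragments cut at the CDS
      exn <- add(exn, pmax(ex$start, g$cds_start), pmin(ex$end, g$cds_end))
      left <- list(s = ex$start, e = pmin(ex$end, g$cds_start))
      right <- list(s = pmax(ex$start, g$cds_end), e = ex$end)
      if (g$strand == "+") {
        utr5 <- add(utr5, left$s, left$e)
        utr3 <- add(utr3, right$s, right$e)
      } else {
        utr3 <- add(utr3, left$s, left$e)
        utr5 <- add(utr5, right$s, right$e)
      }
    } else {
      exn <- add(exn, ex$start, ex$end)
    }
    if (nrow(ex) > 1) {
      intr <- add(intr, ex$end[-nrow(ex)], ex$start[-1])
    }
    if (g$strand == "+") {
      prom <- add(prom, max(0L, g$tss - promoter_width), g$tss)
    } else {
      lim <- clen[[g$chrom]] %||% Inf
      prom <- add(prom, g$tss + 1L, min(lim, g$tss + 1L + promoter_width))
    }
  }
  bindup <- function(lst) if (length(lst)) {
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  } else empty
  structure(list(utr5 = bindup(utr5), utr3 = bindup(utr3),
                 exon = bindup(exn), promoter = bindup(prom),
                 intron = bindup(intr),
                 chromosomes = genome$chromosomes,
                 promoter_width = promoter_width),
            class = "feature_index")
}

feature_precedence <- c("utr5", "utr3", "exon", "promoter", "intron")

#' Assign peaks to genomic feature categories
#'
#' Each peak is assigned by its single anchor base (the crosslink-supported
#' position), not by interval overlap. Only same-strand features are
#' considered: a peak antisense to the only overlapping gene is intergenic,
#' because sense-strand RNA evidence cannot come from the antisense gene.
#' Ties across categories resolve by the fixed precedence
#' 5' UTR > 3' UTR > exon > promoter > intron; ties within a category take
#' the first gene in annotation order.
#'
#' @param peaks A \code{peak_set} (needs chrom, strand, anchor; peaks with
#'   missing anchors fall back to the interval midpoint).
#' @param index A \code{\link{build_feature_index}} result.
#' @return A data.frame: peak_id, chrom, strand, anchor, category (factor
#'   over the six categories), gene_id (NA for intergenic).
#' @export
assign_peaks <- function(peaks, index) {
  stopifnot(inherits(index, "feature_index"))
  anchor <- ifelse(is.na(peaks$anchor),
                   peaks$start + (peaks$end - peaks$start) %/% 2L,
                   peaks$anchor)
  clen <- setNames(index$chromosomes$length, index$chromosomes$name)
  n <- nrow(peaks)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cn <- peaks$chrom[i]
    if (!cn %in% names(clen) || anchor[i] < 0 || anchor[i] >= clen[[cn]]) {
      stop(sprintf("peak %s: anchor %d is off chromosome %s",
                   peaks$peak_id[i] %||% i, anchor[i], cn), call. = FALSE)
    }
    for (cat in feature_precedence) {
      f <- index[[cat]]
      hit <- which(f$chrom == cn & f$strand == peaks$strand[i] &
                     f$start <= anchor[i] & anchor[i] < f$end)
      if (length(hit)) {
        category[i] <- cat
        gene_id[i] <- f$gene_id[hit[1]]
        break
      }
    }
  }
  data.frame(peak_id = peaks$peak_id %||% sprintf("peak%05d", seq_len(n)),
             chrom = peaks$chrom, strand = peaks$strand,
             anchor = as.integer(anchor),
             category = factor(category,
                               levels = c(feature_precedence, "intergenic")),
             gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Rescue intergenic peaks by distance to coding ends
#'
#' For every intergenic peak, measures the distance from its anchor to the
#' nearest same-strand CDS stop codon lying transcript-upstream of the peak
#' (the peak sits downstream of a gene end, candidate unannotated 3' UTR
#' extension) and to the nearest same-strand CDS start codon lying
#' transcript-downstream (the peak sits upstream of a gene start). Peaks
#' within \code{max_distance} are rescued; equidistant ties go to the stop
#' codon (the 3' UTR-extension reading). Peaks overlapping a supplied
#' secondary annotation are flagged \code{other-annotation}; the rest stay
#' \code{unresolved}. Non-intergenic assignments are never modified.
#'
#' @param assignments Output of \code{\link{assign_peaks}}.
#' @param genome The \code{genome_model} providing CDS coordinates.
#' @param secondary Optional interval data.frame (chrom, start, end) of
#'   additional gene annotations.
#' @param max_distance Rescue threshold in bp (default 10000).
#' @return A list: \code{assignments} with added \code{rescue_status} and
#'   \code{distance_bp} columns (populated only for intergenic peaks), and
#'   \code{curve}, the cumulative count of intergenic peaks by distance to
#'   the nearest codon.
#' @export
rescue_intergenic <- function(assignments, genome, secondary = NULL,
                              max_distance = 10000) {
  genes <- genome$genes
  coding <- genes[genes$biotype == "mRNA" & !is.na(genes$cds_start), ,
                  drop = FALSE]
  out <- assignments
  out$rescue_status <- NA_character_
  out$distance_bp <- NA_integer_
  ig <- which(out$category == "intergenic")
  for (i in ig) {
    a <- out$anchor[i]; st <- out$strand[i]; cn <- out$chrom[i]
    gs <- coding[coding$chrom == cn & coding$strand == st, , drop = FALSE]
    d_stop <- Inf; d_start <- Inf
    if (nrow(gs)) {
      if (st == "+") {
        stop_pos <- gs$cds_end - 1L   # last CDS base
        start_pos <- gs$cds_start
        ds <- a - stop_pos; ds <- ds[ds >= 0]
        du <- start_pos - a; du <- du[du >= 0]
      } else {
        stop_pos <- gs$cds_start      # CDS 3' end on minus strand
        start_pos <- gs$cds_end - 1L
        ds <- stop_pos - a; ds <- ds[ds >= 0]
        du <- a - start_pos; du <- du[du >= 0]
      }
      if (length(ds)) d_stop <- min(ds)
      if (length(du)) d_start <- min(du)
    }
    d <- min(d_stop, d_start)
    out$distance_bp[i] <- if (is.finite(d)) as.integer(d) else NA_integer_
    if (is.finite(d) && d <= max_distance) {
      out$rescue_status[i] <- if (d_stop <= d_start)
        "within-10kb-of-stop" else "within-10kb-of-start"
    } else {
      out$rescue_status[i] <- "unresolved"
    }
  }
  if (!is.null(secondary) && length(ig)) {
    for (i in ig[out$rescue_status[ig] == "unresolved"]) {
      hit <- any(secondary$chrom == out$chrom[i] &
                   secondary$start <= out$anchor[i] &
                   out$anchor[i] < secondary$end)
      if (hit) out$rescue_status[i] <- "other-annotation"
    }
  }
  dists <- sort(out$distance_bp[ig][!is.na(out$distance_bp[ig])])
  curve <- if (length(dists)) {
    data.frame(distance_bp = unique(dists),
               cumulative_count = vapply(unique(dists), function(d)
                 sum(dists <= d), integer(1)))
  } else data.frame(distance_bp = integer(0), cumulative_count = integer(0))
  list(assignments = out, curve = curve)
}

#' Count peaks by RNA biotype
#'
#' Each genic peak is counted once under its assigned gene's biotype;
#' intergenic peaks are excluded. With no genic peaks the table is empty.
#'
#' @param assignments Output of \code{\link{assign_peaks}} (or the rescued
#'   version).
#' @param genome The \code{genome_model} carrying gene biotypes.
#' @return A data.frame: biotype, count, proportion (of genic peaks).
#' @export
classify_rna_type <- function(assignments, genome) {
  genic <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  if (nrow(genic) == 0) {
    return(data.frame(biotype = character(0), count = integer(0),
                      proportion = numeric(0)))
  }
  bt <- genome$genes$biotype[match(genic$gene_id, genome$genes$gene_id)]
  tab <- table(bt)
  data.frame(biotype = names(tab), count = as.integer(tab),
             proportion = as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Summarize feature-category proportions
#'
#' @param assignments Output of \code{\link{assign_peaks}}.
#' @return A data.frame with category, count and proportion over all peaks
#'   (proportions sum to 1).
#' @export
category_proportions <- function(assignments) {
  tab <- table(assignments$category)
  data.frame(category = names(tab), count = as.integer(tab),
             proportion = as.integer(tab) / max(1L, sum(tab)),
             stringsAsFactors = FALSE)
}
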
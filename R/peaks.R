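#' Group aligned reads by same-strand overlap
#'
#' Two reads belong to the same group iff they are connected by a chain of
#' same-strand overlaps of at least 1 bp. Grouping is strand-separated
#' because the diagnostic T-to-C conversion is defined on the sense strand;
#' merging strands would corrupt conversion counting.
#'
#' @param reads A reads data.frame with columns chrom, start, end (0-based
#'   half-open), strand; optionally mismatch columns and copy_count.
#' @return The reads with an integer \code{group} column; groups partition
#'   the input and are numbered in (chrom, strand, start) order.
#' @export
group_reads <- function(reads) {
  req <- c("chrom", "start", "end", "strand")
  stopifnot(is.data.frame(reads), all(req %in% names(reads)))
  if (nrow(reads) == 0) {
    reads$group <- integer(0)
    return(reads)
  }
  bad <- which(reads$end <= reads$start)
  if (length(bad)) {
    ids <- if ("read_id" %in% names(reads)) reads$read_id[bad] else bad
    stop(sprintf("malformed read(s) with end <= start: %s",
                 paste(head(ids, 5), collapse = ", ")), call. = FALSE)
  }
  ord <- order(reads$chrom, reads$strand, reads$start, reads$end)
  group <- integer(nrow(reads))
  gid <- 0L
  cur_chrom <- ""; cur_strand <- ""; cur_end <- -1L
  for (i in ord) {
    new_unit <- reads$chrom[i] != cur_chrom || reads$strand[i] != cur_strand
    if (new_unit || reads$start[i] >= cur_end) {
      gid <- gid + 1L
      cur_end <- reads$end[i]
    } else {
      cur_end <- max(cur_end, reads$end[i])
    }
    cur_chrom <- reads$chrom[i]; cur_strand <- reads$strand[i]
    group[i] <- gid
  }
  reads$group <- group
  reads
}

# Genomic position of a read's conversion site (sense-orientation offset).
conversion_position <- function(reads) {
  ifelse(is.na(reads$mismatch_offset), NA_integer_,
         ifelse(reads$strand == "+",
                reads$start + reads$mismatch_offset,
                reads$end - 1L - reads$mismatch_offset))
}

# A read counts as converted iff it carries a sense T-to-C mismatch and no
# more than one mismatch in total.
is_converted <- function(reads) {
  nmm <- if ("n_mismatches" %in% names(reads)) reads$n_mismatches else
    as.integer(!is.na(reads$mismatch_offset))
  !is.na(reads$mismatch_offset) &
    !is.na(reads$ref_base) & reads$ref_base == "T" &
    !is.na(reads$alt_base) & reads$alt_base == "C" &
    nmm <= 1L
}

#' Conversion statistics for one read group
#'
#' Counts are weighted by \code{copy_count} (a collapsed read with c copies
#' counts as c reads). A read is converted iff it carries at least one sense
#' T-to-C mismatch and at most one mismatch in total; conversion frequency
#' is converted reads over all reads in the group.
#'
#' @param group Data.frame of the reads in one group.
#' @return A list: n_reads, n_converted_reads, conversion_frequency,
#'   conversion_sites (data.frame pos, n_converted), n_conversion_sites,
#'   anchor (position of the most-supported site, leftmost on ties; NA when
#'   no conversions), start, end, chrom, strand.
#' @export
score_group <- function(group) {
  stopifnot(nrow(group) > 0)
  cc <- if ("copy_count" %in% names(group)) group$copy_count else
    rep(1L, nrow(group))
  conv <- is_converted(group)
  pos <- conversion_position(group)
  n_reads <- sum(cc)
  n_conv <- sum(cc[conv])
  sites <- if (any(conv)) {
    tab <- tapply(cc[conv], pos[conv], sum)
    data.frame(pos = as.integer(names(tab)), n_converted = as.integer(tab))
  } else data.frame(pos = integer(0), n_converted = integer(0))
  sites <- sites[order(sites$pos), , drop = FALSE]
  anchor <- if (nrow(sites)) {
    sites$pos[which.max(sites$n_converted)]  # which.max takes the leftmost tie
  } else NA_integer_
  list(chrom = group$chrom[1], strand = group$strand[1],
       start = min(group$start), end = max(group$end),
       n_reads = n_reads, n_converted_reads = n_conv,
       conversion_frequency = n_conv / n_reads,
       conversion_sites = sites,
       n_conversion_sites = nrow(sites),
       anchor = anchor)
}

#' Call conversion-filtered binding-site peaks
#'
#' Groups reads by same-strand overlap and keeps the groups that satisfy all
#' three crosslink filter criteria: (1) T-to-C conversion frequency at least
#' \code{min_conversion_frequency}; (2) strictly more than
#' \code{min_converted_reads_exclusive} reads with a T-to-C conversion; and
#' (3) at least \code{min_conversion_sites} independent conversion positions.
#' Defaults are (0.25, 5, 2): frequency >= 0.25, more than five converted
#' reads, at least two distinct conversion sites.
#'
#' @param reads Reads data.frame.
#' @param min_conversion_frequency Criterion 1 threshold (inclusive).
#' @param min_converted_reads_exclusive Criterion 2 threshold (exclusive:
#'   a group needs more than this many converted reads).
#' @param min_conversion_sites Criterion 3 threshold (inclusive).
#' @return A data.frame of class \code{"peak_set"}: peak_id, chrom, start,
#'   end, strand, length, n_reads, n_converted_reads, conversion_frequency,
#'   n_conversion_sites, anchor; attribute \code{conversion_sites} holds the
#'   per-peak site tables.
#' @export
call_peaks <- function(reads,
                       min_conversion_frequency = 0.25,
                       min_converted_reads_exclusive = 5,
                       min_conversion_sites = 2) {
  grouped <- group_reads(reads)
  empty <- data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      n_reads = integer(0), n_converted_reads = integer(0),
                      conversion_frequency = numeric(0),
                      n_conversion_sites = integer(0), anchor = integer(0))
  if (nrow(grouped) == 0) {
    class(empty) <- c("peak_set", "data.frame")
    return(empty)
  }
  scored <- lapply(split(grouped, grouped$group), score_group)
  keep <- vapply(scored, function(s) {
    s$conversion_frequency >= min_conversion_frequency &&
      s$n_converted_reads > min_converted_reads_exclusive &&
      s$n_conversion_sites >= min_conversion_sites
  }, logical(1))
  scored <- scored[keep]
  if (!length(scored)) {
    class(empty) <- c("peak_set", "data.frame")
    return(empty)
  }
  peaks <- do.call(rbind, lapply(scored, function(s) {
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               strand = s$strand, length = s$end - s$start,
               n_reads = s$n_reads, n_converted_reads = s$n_converted_reads,
               conversion_frequency = s$conversion_frequency,
               n_conversion_sites = s$n_conversion_sites, anchor = s$anchor,
               stringsAsFactors = FALSE)
  }))
  ord <- order(peaks$chrom, peaks$start, peaks$strand)
  peaks <- peaks[ord, , drop = FALSE]
  peaks <- cbind(peak_id = sprintf("peak%05d", seq_len(nrow(peaks))), peaks,
                 stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  attr(peaks, "conversion_sites") <-
    setNames(lapply(scored[ord], `[[`, "conversion_sites"), peaks$peak_id)
  class(peaks) <- c("peak_set", "data.frame")
  peaks
}
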
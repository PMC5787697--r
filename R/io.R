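# All coordinates are 0-based half-open internally. BED shares that
# convention; GTF is 1-based inclusive and is converted exactly here and
# nowhere else.

#' Read an interval table from BED or GTF
#'
#' @param path File path.
#' @param format \code{"BED"} or \code{"GTF"}; guessed from the extension
#'   when NULL.
#' @return A data.frame with 0-based half-open \code{start}/\code{end}:
#'   for BED, columns chrom, start, end, name, score, strand (as present);
#'   for GTF, columns chrom, source, feature, start, end, score, strand,
#'   frame plus parsed gene_id / transcript_id / gene_biotype attributes.
#' @export
read_intervals <- function(path, format = NULL) {
  format <- toupper(format %||% tools::file_ext(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (format == "BED") {
    if (!length(lines)) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = numeric(0), strand = character(0)))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3)) {
      stop(sprintf("malformed BED line %d: fewer than 3 fields",
                   which(nf < 3)[1]), call. = FALSE)
    }
    col <- function(i, default = NA) vapply(fields, function(f)
      if (length(f) >= i) f[i] else as.character(default), character(1))
    out <- data.frame(chrom = col(1), start = as.integer(col(2)),
                      end = as.integer(col(3)), name = col(4, "."),
                      score = suppressWarnings(as.numeric(col(5, 0))),
                      strand = col(6, "*"), stringsAsFactors = FALSE)
    bad <- which(is.na(out$start) | is.na(out$end))
    if (length(bad)) {
      stop(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]),
           call. = FALSE)
    }
    extra <- max(nf) - 6L
    if (extra > 0) {
      for (j in seq_len(extra)) out[[paste0("extra", j)]] <- col(6L + j)
    }
    out
  } else if (format == "GTF") {
    if (!length(lines)) {
      return(data.frame(chrom = character(0), source = character(0),
                        feature = character(0), start = integer(0),
                        end = integer(0), score = character(0),
                        strand = character(0), frame = character(0),
                        gene_id = character(0), transcript_id = character(0),
                        gene_biotype = character(0)))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9)) {
      stop(sprintf("malformed GTF line %d: expected 9 fields, got %d",
                   which(nf != 9)[1], nf[nf != 9][1]), call. = FALSE)
    }
    m <- do.call(rbind, fields)
    attr_get <- function(attrs, key) {
      hit <- regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs))
      out <- rep(NA_character_, length(attrs))
      found <- vapply(regmatches(attrs, gregexpr(sprintf('%s "([^"]*)"', key),
                                                 attrs)),
                      function(x) if (length(x)) sub(sprintf('%s "', key), "",
                                                     sub('"$', "", x[1]))
                      else NA_character_, character(1))
      found
    }
    start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
    if (any(is.na(start1) | is.na(end1))) {
      stop(sprintf("malformed GTF line %d: non-numeric coordinates",
                   which(is.na(start1) | is.na(end1))[1]), call. = FALSE)
    }
    data.frame(chrom = m[, 1], source = m[, 2], feature = m[, 3],
               start = start1 - 1L, end = end1, score = m[, 6],
               strand = m[, 7], frame = m[, 8],
               gene_id = attr_get(m[, 9], "gene_id"),
               transcript_id = attr_get(m[, 9], "transcript_id"),
               gene_biotype = attr_get(m[, 9], "gene_biotype"),
               stringsAsFactors = FALSE)
  } else {
    stop(sprintf("unsupported interval format '%s'", format), call. = FALSE)
  }
}

#' Write an interval table to BED or GTF
#'
#' @param x Interval data.frame (0-based half-open start/end).
#' @param path Output path.
#' @param format \code{"BED"} or \code{"GTF"} (guessed from extension).
#' @return Invisibly, the path.
#' @export
write_intervals <- function(x, path, format = NULL) {
  format <- toupper(format %||% tools::file_ext(path))
  if (nrow(x)) stopifnot_intervals(x$start, x$end)
  if (format == "BED") {
    base <- data.frame(x$chrom, x$start, x$end,
                       x$name %||% ".",
                       x$score %||% 0,
                       x$strand %||% "*")
    extra <- x[grepl("^extra", names(x))]
    out <- if (ncol(extra)) cbind(base, extra) else base
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else if (format == "GTF") {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     x$gene_id %||% ".", x$transcript_id %||% ".",
                     x$gene_biotype %||% ".")
    out <- data.frame(x$chrom, x$source %||% "clipbind",
                      x$feature %||% "region", x$start + 1L, x$end,
                      x$score %||% ".", x$strand %||% ".",
                      x$frame %||% ".", attrs)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    stop(sprintf("unsupported interval format '%s'", format), call. = FALSE)
  }
  invisible(path)
}

#' Write a toy genome's sequence as FASTA
#' @param genome A \code{genome_model}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequence, path)
  invisible(path)
}

#' Read a FASTA file as a named DNAStringSet
#' @param path FASTA path.
#' @return A \code{Biostrings::DNAStringSet}.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a toy genome's annotation as GTF
#'
#' Emits gene, transcript and exon records (plus CDS for coding genes) with
#' attribute keys \code{gene_id}, \code{transcript_id}, \code{gene_biotype};
#' coordinates are converted to 1-based inclusive here.
#'
#' @param genome A \code{genome_model}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_annotation_gtf <- function(genome, path) {
  rows <- list()
  emit <- function(feature, chrom, start, end, strand, gid, tid, bt) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, feature = feature, start = start, end = end,
      strand = strand, gene_id = gid, transcript_id = tid,
      gene_biotype = bt, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    emit("gene", g$chrom, g$start, g$end, g$strand, g$gene_id, "", g$biotype)
    emit("transcript", g$chrom, g$start, g$end, g$strand, g$gene_id, tid,
         g$biotype)
    ex <- genome$exons[genome$exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      emit("exon", ex$chrom[j], ex$start[j], ex$end[j], ex$strand[j],
           g$gene_id, ex$transcript_id[j], g$biotype)
    }
    if (g$biotype == "mRNA" && !is.na(g$cds_start)) {
      cs <- pmax(ex$start, g$cds_start); ce <- pmin(ex$end, g$cds_end)
      keep <- ce > cs
      for (j in which(keep)) {
        emit("CDS", ex$chrom[j], cs[j], ce[j], ex$strand[j], g$gene_id,
             ex$transcript_id[j], g$biotype)
      }
    }
  }
  x <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), feature = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               gene_id = character(0), transcript_id = character(0),
               gene_biotype = character(0))
  write_intervals(x, path, format = "GTF")
}

#' Write transcripts as BED12
#'
#' One line per transcript with exon block structure; thickStart/thickEnd
#' mark the CDS for coding genes.
#'
#' @param genome A \code{genome_model}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_annotation_bed12 <- function(genome, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    ex <- genome$exons[genome$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    thick <- if (!is.na(g$cds_start)) c(g$cds_start, g$cds_end) else
      c(g$start, g$start)
    lines <- c(lines, paste(
      g$chrom, g$start, g$end, paste0(g$gene_id, ".t1"), 0, g$strand,
      thick[1], thick[2], "0", nrow(ex),
      paste0(paste(ex$end - ex$start, collapse = ","), ","),
      paste0(paste(ex$start - g$start, collapse = ","), ","),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write aligned reads as BED6+
#'
#' BED6 (chrom, start, end, read_id, n_mismatches as score, strand) plus the
#' extra columns \code{mismatch_offset}, \code{ref_base}, \code{alt_base},
#' \code{copy_count}.
#'
#' @param reads A \code{clip_reads} data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_reads_bed <- function(reads, path) {
  out <- data.frame(reads$chrom, reads$start, reads$end, reads$read_id,
                    reads$n_mismatches, reads$strand,
                    ifelse(is.na(reads$mismatch_offset), ".",
                           reads$mismatch_offset),
                    ifelse(is.na(reads$ref_base), ".", reads$ref_base),
                    ifelse(is.na(reads$alt_base), ".", reads$alt_base),
                    reads$copy_count)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read BED6+ aligned reads written by \code{\link{write_reads_bed}}
#' @param path Input path.
#' @return A \code{clip_reads} data.frame.
#' @export
read_reads_bed <- function(path) {
  x <- read_intervals(path, format = "BED")
  if (nrow(x) == 0) {
    out <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatch_offset = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      n_mismatches = integer(0), copy_count = integer(0))
    class(out) <- c("clip_reads", "data.frame")
    return(out)
  }
  out <- data.frame(
    read_id = x$name, chrom = x$chrom, start = x$start, end = x$end,
    strand = x$strand,
    mismatch_offset = suppressWarnings(as.integer(x$extra1)),
    ref_base = ifelse(x$extra2 == ".", NA_character_, x$extra2),
    alt_base = ifelse(x$extra3 == ".", NA_character_, x$extra3),
    n_mismatches = as.integer(x$score),
    copy_count = as.integer(x$extra4), stringsAsFactors = FALSE)
  class(out) <- c("clip_reads", "data.frame")
  out
}

#' Write called peaks as BED6+ TSV
#'
#' Column order: chrom, start, end, peak_id, score (conversion frequency
#' scaled to 0-1000), strand, length, n_reads, n_converted_reads,
#' conversion_frequency, n_conversion_sites, anchor.
#'
#' @param peaks A \code{peak_set}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    round(1000 * peaks$conversion_frequency), peaks$strand,
                    peaks$length, peaks$n_reads, peaks$n_converted_reads,
                    peaks$conversion_frequency, peaks$n_conversion_sites,
                    peaks$anchor)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read peaks written by \code{\link{write_peaks_bed}}
#' @param path Input path.
#' @return A \code{peak_set} data.frame.
#' @export
read_peaks_bed <- function(path) {
  x <- read_intervals(path, format = "BED")
  out <- data.frame(peak_id = x$name, chrom = x$chrom, start = x$start,
                    end = x$end, strand = x$strand,
                    length = as.integer(x$extra1),
                    n_reads = as.integer(x$extra2),
                    n_converted_reads = as.integer(x$extra3),
                    conversion_frequency = as.numeric(x$extra4),
                    n_conversion_sites = as.integer(x$extra5),
                    anchor = as.integer(x$extra6), stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Write / read a skipped-exon event table (rMATS-style TSV)
#' @param events A \code{splice_events} data.frame.
#' @param path Path.
#' @return Invisibly the path, or the events table.
#' @export
write_splice_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_splice_events_tsv
#' @export
read_splice_events_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("splice_events", "data.frame")
  out
}

#' Write / read an EMSA titration series TSV
#'
#' Columns: protein_M, fraction_bound, species.
#' @param series A \code{titration_series}.
#' @param path Path.
#' @return Invisibly the path, or the series.
#' @export
write_titration_tsv <- function(series, path) {
  write.table(series[c("protein_M", "fraction_bound", "species")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_tsv
#' @export
read_titration_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Write / read a competition series TSV (long format)
#'
#' Columns: protein_M, free_fraction, species (DNA / RNA).
#' @param series A \code{competition_series}.
#' @param path Path.
#' @return Invisibly the path, or the wide-format series.
#' @export
write_competition_tsv <- function(series, path) {
  long <- rbind(
    data.frame(protein_M = series$protein_M,
               free_fraction = series$dna_free_fraction, species = "DNA"),
    data.frame(protein_M = series$protein_M,
               free_fraction = series$rna_free_fraction, species = "RNA"))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_competition_tsv
#' @export
read_competition_tsv <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  d <- long[long$species == "DNA", ]
  r <- long[long$species == "RNA", ]
  d <- d[order(d$protein_M), ]; r <- r[order(r$protein_M), ]
  stopifnot(nrow(d) == nrow(r), all(d$protein_M == r$protein_M))
  out <- data.frame(protein_M = d$protein_M,
                    dna_free_fraction = d$free_fraction,
                    rna_free_fraction = r$free_fraction)
  class(out) <- c("competition_series", "data.frame")
  out
}

#' Write a binding or competition fit report as JSON
#' @param fit A \code{binding_fit} or \code{competition_fit}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$points <- NULL
  x$usable <- as.logical(fit$usable)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
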
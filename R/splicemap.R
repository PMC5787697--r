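#' Classify skipped-exon events into regulatory classes
#'
#' Applies the significance thresholds used for positional splicing maps:
#' an event is \code{enhanced} iff P <= 0.05, FDR <= 0.05 and inclusion
#' difference >= +0.1; \code{silenced} iff P <= 0.05, FDR <= 0.05 and
#' inclusion difference <= -0.1; \code{background} iff FDR > 0.5; everything
#' else is \code{excluded}.
#'
#' @param events Data.frame with columns IncLevelDifference (or delta_psi),
#'   PValue (or p_value) and FDR (or fdr).
#' @param p_max,fdr_max Significance thresholds (default 0.05).
#' @param min_delta Minimum absolute inclusion difference (default 0.1).
#' @param background_fdr_min FDR above which an event is background (0.5).
#' @return The events with a \code{class} factor column.
#' @export
classify_events <- function(events, p_max = 0.05, fdr_max = 0.05,
                            min_delta = 0.1, background_fdr_min = 0.5) {
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(events)) return(events[[nm]])
    stop(sprintf("events table lacks required column (one of: %s)",
                 paste(c(...), collapse = ", ")), call. = FALSE)
  }
  dpsi <- pick("IncLevelDifference", "delta_psi")
  p <- pick("PValue", "p_value")
  fdr <- pick("FDR", "fdr")
  cls <- ifelse(p <= p_max & fdr <= fdr_max & dpsi >= min_delta, "enhanced",
         ifelse(p <= p_max & fdr <= fdr_max & dpsi <= -min_delta, "silenced",
         ifelse(fdr > background_fdr_min, "background", "excluded")))
  events$class <- factor(cls, levels = c("enhanced", "silenced",
                                         "background", "excluded"))
  events
}

splicemap_regions <- c("upstream_exon_3p", "cassette_5p",
                       "cassette_3p", "downstream_exon_5p")

region_offsets <- function(region, exon_flank, intron_window) {
  switch(region,
    upstream_exon_3p = seq(-exon_flank, intron_window - 1L),
    cassette_5p = seq(-intron_window, exon_flank - 1L),
    cassette_3p = seq(-exon_flank, intron_window - 1L),
    downstream_exon_5p = seq(-intron_window, exon_flank - 1L))
}

# Genomic position of each offset of one map region for one event, in
# transcript orientation (negative offsets on the exon side of the
# upstream-exon/cassette junctions, mirrored on the minus strand).
region_positions <- function(event, region, exon_flank, intron_window) {
  plus <- event$strand == "+"
  offs <- region_offsets(region, exon_flank, intron_window)
  anchor0 <- switch(region,
    upstream_exon_3p = if (plus) event$upstreamEE else event$upstreamES - 1L,
    cassette_5p = if (plus) event$exonStart_0base else event$exonEnd - 1L,
    cassette_3p = if (plus) event$exonEnd else event$exonStart_0base - 1L,
    downstream_exon_5p = if (plus) event$downstreamES else
      event$downstreamEE - 1L)
  g <- if (plus) anchor0 + offs else anchor0 - offs
  list(offsets = offs, genomic = g)
}

# One 0/1 matrix per region: does event i have >= 1 peak anchor at offset j?
event_hit_matrices <- function(peaks, events, exon_flank, intron_window) {
  anchors <- split(peaks$anchor, paste(peaks$chrom, peaks$strand))
  lapply(setNames(splicemap_regions, splicemap_regions), function(region) {
    width <- exon_flank + intron_window
    m <- matrix(0, nrow = nrow(events), ncol = width)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      a <- anchors[[paste(ev$chr, ev$strand)]]
      if (is.null(a) || !length(a)) next
      rp <- region_positions(ev, region, exon_flank, intron_window)
      m[i, ] <- as.numeric(rp$genomic %in% a)
    }
    m
  })
}

#' Positional peak density around regulated cassette exons
#'
#' For one event class, computes, at every transcript-oriented position of
#' the four flanking regions (upstream-exon 3' end into the upstream intron;
#' upstream intron into the cassette 5' end; cassette 3' end into the
#' downstream intron; downstream intron into the downstream-exon 5' start),
#' the fraction of events that carry at least one peak anchor at that
#' position, then smooths with a centred moving average. Counting events
#' (binary per event per position) rather than raw peaks prevents peak-rich
#' events from dominating the map.
#'
#' @param peaks A \code{peak_set} (anchors are matched on chrom and strand).
#' @param events Events of a single class.
#' @param exon_flank Exonic depth in bp (default 50).
#' @param intron_window Intronic depth in bp (default 250).
#' @param smooth_window Moving-average window in positions (default 50);
#'   1 disables smoothing.
#' @return A data.frame of class \code{"positional_map"}: region, offset,
#'   density, raw_density; attribute \code{n_events}.
#' @export
positional_density <- function(peaks, events, exon_flank = 50,
                               intron_window = 250, smooth_window = 50) {
  n_ev <- nrow(events)
  if (n_ev == 0) {
    stop("cannot normalise a positional map over zero events", call. = FALSE)
  }
  hm <- event_hit_matrices(peaks, events, exon_flank, intron_window)
  out <- lapply(splicemap_regions, function(region) {
    raw <- colMeans(hm[[region]])
    data.frame(region = region,
               offset = region_offsets(region, exon_flank, intron_window),
               density = moving_average(raw, smooth_window),
               raw_density = raw, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_events") <- n_ev
  attr(res, "geometry") <- list(exon_flank = exon_flank,
                                intron_window = intron_window,
                                smooth_window = smooth_window)
  class(res) <- c("positional_map", "data.frame")
  res
}

#' Permutation significance for a positional splicing map
#'
#' Compares the target class's positional density to densities from
#' resampled background events of the same size: per position, the
#' one-sided add-one permutation p-value
#' \code{(1 + #permutations with background density >= target) / (1 + n)},
#' so p is never zero. Background events are resampled with replacement
#' (bootstrap): subsampling without replacement from a finite pool
#' under-disperses the null distribution whenever the pool is not much
#' larger than the target class, which makes small p-values too easy.
#' A message notes when the background pool is smaller than the target
#' class.
#'
#' @param peaks A \code{peak_set}.
#' @param target_events Events of the class being mapped.
#' @param background_events Non-impacted (background) events.
#' @param n_permutations Number of resamples (>= 100 recommended).
#' @param exon_flank,intron_window,smooth_window Map geometry, as in
#'   \code{\link{positional_density}}.
#' @param seed Integer seed.
#' @return The target \code{positional_map} with a \code{p_value} column.
#' @export
map_significance <- function(peaks, target_events, background_events,
                             n_permutations = 200, exon_flank = 50,
                             intron_window = 250, smooth_window = 50,
                             seed = NULL) {
  if (nrow(background_events) == 0) {
    stop("background event set is empty", call. = FALSE)
  }
  stopifnot(n_permutations >= 1)
  target <- positional_density(peaks, target_events, exon_flank,
                               intron_window, smooth_window)
  n_t <- nrow(target_events)
  n_b <- nrow(background_events)
  if (n_t > n_b) {
    message("background smaller than target class; bootstrap resampling ",
            "will reuse events heavily")
  }
  bg_hm <- event_hit_matrices(peaks, background_events, exon_flank,
                              intron_window)
  exceed <- numeric(nrow(target))
  target_dens <- target$density
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      idx <- sample(n_b, n_t, replace = TRUE)
      perm <- unlist(lapply(splicemap_regions, function(region) {
        moving_average(colMeans(bg_hm[[region]][idx, , drop = FALSE]),
                       smooth_window)
      }), use.names = FALSE)
      exceed <- exceed + as.numeric(perm >= target_dens)
    }
  })
  target$p_value <- (1 + exceed) / (1 + n_permutations)
  attr(target, "n_permutations") <- n_permutations
  target
}
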
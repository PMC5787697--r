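#' Simulate a skipped-exon event table
#'
#' Generates cassette-exon trios (upstream exon, cassette exon, downstream
#' exon on one strand) with inclusion-level differences (knockdown minus
#' control), P-values and FDRs structured like a differential-splicing
#' caller's skipped-exon output. Three planted classes: \code{enhanced}
#' (delta PSI >= +0.1, FDR <= 0.05), \code{silenced} (delta PSI <= -0.1,
#' FDR <= 0.05) and \code{background} (FDR > 0.5, negligible delta PSI).
#' The planted class is carried in \code{true_class} as hidden truth for
#' recovery tests.
#'
#' @param genome A \code{genome_model} (chromosome bounds only).
#' @param n_events Number of events (>= 0).
#' @param class_mix Named proportions over enhanced, silenced, background;
#'   must sum to 1.
#' @param effect_range Absolute delta-PSI range for regulated events
#'   (default 0.1 to 0.6).
#' @param exon_length,intron_length Ranges (bp) for the generated exons and
#'   the two flanking introns.
#' @param seed Integer seed.
#' @return A data.frame of class \code{"splice_events"} with rMATS-style
#'   columns: chr, strand, exonStart_0base, exonEnd, upstreamES, upstreamEE,
#'   downstreamES, downstreamEE, IncLevelDifference, PValue, FDR, plus
#'   true_class.
#' @export
simulate_splice_events <- function(genome, n_events,
                                   class_mix = c(enhanced = 1 / 3,
                                                 silenced = 1 / 3,
                                                 background = 1 / 3),
                                   effect_range = c(0.1, 0.6),
                                   exon_length = c(50, 300),
                                   intron_length = c(700, 3000),
                                   seed = NULL) {
  if (n_events < 0) stop("n_events must be non-negative", call. = FALSE)
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% c("enhanced", "silenced", "background")))
  with_seed(seed, {
    cols <- c("chr", "strand", "exonStart_0base", "exonEnd", "upstreamES",
              "upstreamEE", "downstreamES", "downstreamEE",
              "IncLevelDifference", "PValue", "FDR", "true_class")
    if (n_events == 0) {
      out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                    cols))
      class(out) <- c("splice_events", "data.frame")
      return(out)
    }
    classes <- sample(names(class_mix), n_events, replace = TRUE,
                      prob = class_mix)
    ri <- function(rg, n) as.integer(round(runif(n, rg[1], rg[2])))
    lens <- matrix(ri(exon_length, 3 * n_events), ncol = 3)
    introns <- matrix(ri(intron_length, 2 * n_events), ncol = 2)
    span <- rowSums(lens) + rowSums(introns)
    ci <- sample(nrow(genome$chromosomes), n_events, replace = TRUE)
    max_start <- genome$chromosomes$length[ci] - span
    if (any(max_start < 0)) {
      stop("chromosomes too short for the requested event geometry",
           call. = FALSE)
    }
    s1 <- as.integer(floor(runif(n_events, 0, max_start + 1)))
    strand <- sample(c("+", "-"), n_events, replace = TRUE)
    # genomic left-to-right trio; transcript-upstream exon is the genomic
    # left exon on + and the genomic right exon on -
    e1s <- s1; e1e <- e1s + lens[, 1]
    e2s <- e1e + introns[, 1]; e2e <- e2s + lens[, 2]
    e3s <- e2e + introns[, 2]; e3e <- e3s + lens[, 3]
    up_s <- ifelse(strand == "+", e1s, e3s)
    up_e <- ifelse(strand == "+", e1e, e3e)
    dn_s <- ifelse(strand == "+", e3s, e1s)
    dn_e <- ifelse(strand == "+", e3e, e1e)

    dpsi <- numeric(n_events); p <- numeric(n_events); fdr <- numeric(n_events)
    for (i in seq_len(n_events)) {
      if (classes[i] == "enhanced") {
        dpsi[i] <- runif(1, effect_range[1], effect_range[2])
        p[i] <- runif(1, 0, 0.05); fdr[i] <- runif(1, p[i], 0.05)
      } else if (classes[i] == "silenced") {
        dpsi[i] <- -runif(1, effect_range[1], effect_range[2])
        p[i] <- runif(1, 0, 0.05); fdr[i] <- runif(1, p[i], 0.05)
      } else {
        dpsi[i] <- runif(1, -0.05, 0.05)
        fdr[i] <- runif(1, 0.5 + 1e-9, 1)
        p[i] <- runif(1, 0.1, fdr[i])
      }
    }
    out <- data.frame(
      chr = genome$chromosomes$name[ci], strand = strand,
      exonStart_0base = e2s, exonEnd = e2e,
      upstreamES = as.integer(up_s), upstreamEE = as.integer(up_e),
      downstreamES = as.integer(dn_s), downstreamEE = as.integer(dn_e),
      IncLevelDifference = dpsi, PValue = p, FDR = fdr,
      true_class = classes, stringsAsFactors = FALSE)
    class(out) <- c("splice_events", "data.frame")
    out
  })
}
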
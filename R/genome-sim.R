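#' Configuration for the toy genome generator
#'
#' The generator stands in, at desk scale, for a real genome assembly plus
#' its gene annotation. Defaults give two 100-kb chromosomes carrying 30
#' genes across the four RNA biotypes seen in PAR-CLIP target classification
#' (mRNA, lincRNA, miRNA, snRNA).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp (recycled).
#' @param n_genes Total genes to place.
#' @param exons_per_gene Integer range (min, max) of exon count for mRNA
#'   and lincRNA genes.
#' @param exon_length,intron_length Ranges (bp) for exon and intron sizes.
#' @param utr5_length,utr3_length Ranges (bp) for UTR sizes on mRNA genes.
#' @param biotype_mix Named proportions over mRNA, lincRNA, miRNA, snRNA.
#' @param intergenic_gap Range (bp) of gaps between neighbouring genes.
#' @return A list of class \code{"genome_config"}.
#' @export
genome_config <- function(n_chromosomes = 2,
                          chromosome_length = 100000,
                          n_genes = 30,
                          exons_per_gene = c(2, 5),
                          exon_length = c(80, 300),
                          intron_length = c(200, 2000),
                          utr5_length = c(20, 60),
                          utr3_length = c(40, 150),
                          biotype_mix = c(mRNA = 0.7, lincRNA = 0.15,
                                          miRNA = 0.075, snRNA = 0.075),
                          intergenic_gap = c(500, 3000)) {
  stopifnot(n_chromosomes >= 1, n_genes >= 0,
            abs(sum(biotype_mix) - 1) < 1e-8,
            all(names(biotype_mix) %in%
                  c("mRNA", "lincRNA", "miRNA", "snRNA")))
  structure(list(
    n_chromosomes = n_chromosomes,
    chromosome_length = rep_len(chromosome_length, n_chromosomes),
    n_genes = n_genes,
    exons_per_gene = exons_per_gene,
    exon_length = exon_length,
    intron_length = intron_length,
    utr5_length = utr5_length,
    utr3_length = utr3_length,
    biotype_mix = biotype_mix,
    intergenic_gap = intergenic_gap
  ), class = "genome_config")
}

# Draw a gene structure (exon/intron lengths, biotype-specific) and return
# relative exon coordinates plus CDS offsets for mRNA.
random_gene_structure <- function(config, biotype) {
  runif_int <- function(rg) if (rg[1] >= rg[2]) rg[1] else
    sample(seq(rg[1], rg[2]), 1)
  if (biotype %in% c("miRNA", "snRNA")) {
    len <- if (biotype == "miRNA") runif_int(c(70, 120)) else
      runif_int(c(100, 250))
    exon_len <- len
    exon_starts <- 0L
    exon_ends <- len
  } else {
    n_ex <- runif_int(config$exons_per_gene)
    exon_len <- vapply(seq_len(n_ex), function(i)
      runif_int(config$exon_length), numeric(1))
    intron_len <- if (n_ex > 1) {
      vapply(seq_len(n_ex - 1), function(i)
        runif_int(config$intron_length), numeric(1))
    } else numeric(0)
    exon_starts <- cumsum(c(0, head(exon_len, -1) + intron_len))
    exon_ends <- exon_starts + exon_len
  }
  out <- list(exon_starts = as.integer(exon_starts),
              exon_ends = as.integer(exon_ends),
              span = as.integer(max(exon_ends)))
  if (biotype == "mRNA") {
    # UTRs live in the terminal exons (transcript orientation applied later):
    # CDS + UTRs partition the exonic span.
    first_len <- exon_ends[1] - exon_starts[1]
    last_len <- exon_ends[length(exon_ends)] - exon_starts[length(exon_starts)]
    u5 <- min(runif_int(config$utr5_length), max(1, first_len - 10))
    u3 <- min(runif_int(config$utr3_length), max(1, last_len - 10))
    out$utr5_len <- as.integer(u5)
    out$utr3_len <- as.integer(u3)
  }
  out
}

#' Generate a toy genome with annotation and sequence
#'
#' Places genes on random strands along each chromosome with intergenic gaps,
#' assigns biotypes by the configured mix, and draws an i.i.d. uniform
#' A/C/G/T background sequence. Coordinates are 0-based half-open throughout;
#' conversion to 1-based GTF happens only in the writers.
#'
#' @param config A \code{\link{genome_config}}.
#' @param seed Integer seed; output is deterministic per seed.
#' @return A list of class \code{"genome_model"} with elements
#'   \code{chromosomes} (name, length), \code{genes} (gene_id, chrom, strand,
#'   start, end, biotype, tss, cds_start, cds_end), \code{exons} (gene_id,
#'   transcript_id, chrom, strand, start, end, exon_rank), \code{sequence}
#'   (\code{Biostrings::DNAStringSet}), and \code{sites} (NULL until binding
#'   sites are planted).
#' @export
make_genome <- function(config = genome_config(), seed = NULL) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(seed, {
    chroms <- data.frame(
      name = paste0("chr", seq_len(config$n_chromosomes)),
      length = as.integer(config$chromosome_length),
      stringsAsFactors = FALSE)

    biotypes <- if (config$n_genes > 0) {
      sample(names(config$biotype_mix), config$n_genes, replace = TRUE,
             prob = config$biotype_mix)
    } else character(0)
    # Guarantee the configured biotype vocabulary is realised when there is
    # room for it (the mix is a target, not a per-draw constraint).
    want <- names(config$biotype_mix)[config$biotype_mix > 0]
    if (config$n_genes >= length(want)) {
      missing <- setdiff(want, biotypes)
      if (length(missing)) {
        biotypes[sample(seq_along(biotypes), length(missing))] <- missing
      }
    }

    genes <- list(); exons <- list()
    cursor <- setNames(rep(0L, nrow(chroms)), chroms$name)
    chrom_i <- 0L
    for (g in seq_len(config$n_genes)) {
      bt <- biotypes[g]
      struct <- random_gene_structure(config, bt)
      if (struct$span > max(chroms$length)) {
        stop(sprintf(
          "gene %d (span %d bp) is longer than the longest chromosome (%d bp)",
          g, struct$span, max(chroms$length)), call. = FALSE)
      }
      placed <- FALSE
      for (try in seq_len(nrow(chroms))) {
        chrom_i <- (chrom_i %% nrow(chroms)) + 1L
        cn <- chroms$name[chrom_i]
        gap <- sample(seq(config$intergenic_gap[1], config$intergenic_gap[2]), 1)
        start <- cursor[cn] + gap
        if (start + struct$span <= chroms$length[chrom_i]) {
          strand <- sample(c("+", "-"), 1)
          gid <- sprintf("G%03d", g)
          tid <- paste0(gid, ".t1")
          es <- start + struct$exon_starts
          ee <- start + struct$exon_ends
          gene_start <- min(es); gene_end <- max(ee)
          tss <- if (strand == "+") gene_start else gene_end - 1L
          cds <- c(NA_integer_, NA_integer_)
          if (bt == "mRNA") {
            # utr5 at transcript 5' end: genomic left on +, right on -.
            if (strand == "+") {
              cds <- c(es[1] + struct$utr5_len,
                       ee[length(ee)] - struct$utr3_len)
            } else {
              cds <- c(es[1] + struct$utr3_len,
                       ee[length(ee)] - struct$utr5_len)
            }
          }
          genes[[length(genes) + 1L]] <- data.frame(
            gene_id = gid, chrom = cn, strand = strand,
            start = gene_start, end = gene_end, biotype = bt,
            tss = as.integer(tss), cds_start = cds[1], cds_end = cds[2],
            stringsAsFactors = FALSE)
          rank <- if (strand == "+") seq_along(es) else rev(seq_along(es))
          exons[[length(exons) + 1L]] <- data.frame(
            gene_id = gid, transcript_id = tid, chrom = cn, strand = strand,
            start = as.integer(es), end = as.integer(ee),
            exon_rank = as.integer(rank), stringsAsFactors = FALSE)
          cursor[cn] <- gene_end
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "ran out of chromosome space placing gene %d of %d; reduce n_genes or enlarge chromosomes",
          g, config$n_genes), call. = FALSE)
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), start = integer(0), end = integer(0),
                 biotype = character(0), tss = integer(0),
                 cds_start = integer(0), cds_end = integer(0))
    exons <- if (length(exons)) do.call(rbind, exons) else
      data.frame(gene_id = character(0), transcript_id = character(0),
                 chrom = character(0), strand = character(0),
                 start = integer(0), end = integer(0), exon_rank = integer(0))

    seqs <- Biostrings::DNAStringSet(vapply(chroms$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)))
    names(seqs) <- chroms$name

    structure(list(chromosomes = chroms, genes = genes, exons = exons,
                   sequence = seqs, sites = NULL, config = config),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "Toy genome: %d chromosome(s), %d gene(s) (%s), %d exon record(s)%s\n",
    nrow(x$chromosomes), nrow(x$genes),
    paste(sprintf("%s=%d", names(table(x$genes$biotype)),
                  table(x$genes$biotype)), collapse = ", "),
    nrow(x$exons),
    if (is.null(x$sites)) "" else
      sprintf(", %d planted binding site(s)", nrow(x$sites))))
  invisible(x)
}

# Intron table derived from exons (per transcript), 0-based half-open.
transcript_introns <- function(exons) {
  if (nrow(exons) == 0) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  }
  out <- lapply(split(exons, exons$transcript_id), function(tx) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) < 2) return(NULL)
    data.frame(gene_id = tx$gene_id[1], transcript_id = tx$transcript_id[1],
               chrom = tx$chrom[1], strand = tx$strand[1],
               start = tx$end[-nrow(tx)], end = tx$start[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  }
  rownames(out) <- NULL
  out
}
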
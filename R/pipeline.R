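#' Pipeline configuration
#'
#' One nested configuration drives every stage of the workflow; every seed
#' is explicit so that two runs from the same config are byte-identical.
#' Unknown keys are rejected to catch typos.
#'
#' @param out_dir Output directory for all stage outputs and the manifest.
#' @param seed Master seed; stage seeds default to fixed offsets from it.
#' @param genome Overrides for \code{\link{genome_config}} fields.
#' @param binding Overrides for \code{\link{binding_model}} fields.
#' @param n_reads Number of CLIP reads to simulate.
#' @param n_events Number of skipped-exon events to simulate.
#' @param peaks Overrides for \code{\link{call_peaks}} thresholds.
#' @param annotate List: promoter_width, rescue_distance.
#' @param kmers List: k, window, flank, n_shuffles, mode.
#' @param boundaries List: exon_depth, intron_depth, n_regions,
#'   region_length.
#' @param splicemap List: exon_flank, intron_window, smooth_window,
#'   n_permutations.
#' @param emsa List: n_true, K_true, noise_sd, m, n, K_DNA, K_RNA.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir = "clipbind_run", seed = 1,
                            genome = list(), binding = list(),
                            n_reads = 20000, n_events = 300,
                            peaks = list(), annotate = list(),
                            kmers = list(), boundaries = list(),
                            splicemap = list(), emsa = list()) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s config key(s): %s", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(genome, names(formals(genome_config)), "genome")
  check_keys(binding, names(formals(binding_model)), "binding")
  check_keys(peaks, c("min_conversion_frequency",
                      "min_converted_reads_exclusive",
                      "min_conversion_sites"), "peaks")
  check_keys(annotate, c("promoter_width", "rescue_distance"), "annotate")
  check_keys(kmers, c("k", "window", "flank", "n_shuffles", "mode"), "kmers")
  check_keys(boundaries, c("exon_depth", "intron_depth", "n_regions",
                           "region_length"), "boundaries")
  check_keys(splicemap, c("exon_flank", "intron_window", "smooth_window",
                          "n_permutations"), "splicemap")
  check_keys(emsa, c("n_true", "K_true", "noise_sd", "m", "n", "K_DNA",
                     "K_RNA"), "emsa")
  structure(list(out_dir = out_dir, seed = seed, genome = genome,
                 binding = binding, n_reads = n_reads, n_events = n_events,
                 peaks = peaks, annotate = annotate, kmers = kmers,
                 boundaries = boundaries, splicemap = splicemap,
                 emsa = emsa),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with \code{\link{pipeline_config}} sections.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the whole analysis pipeline
#'
#' Executes simulate, callpeaks, annotate, kmers, boundaries and splicemap
#' in dependency order, plus the independent EMSA fit and competition
#' stages, writing every output under the configured directory and a
#' manifest (JSON) listing each file with an md5 checksum, the seeds used
#' and per-stage summaries. Rerunning the same config reproduces the
#' checksums.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The manifest, invisibly (also written to manifest.json).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summaries <- list()
  seeds <- list(genome = config$seed, sites = config$seed + 1,
                reads = config$seed + 2, events = config$seed + 3,
                kmers = config$seed + 4, boundaries = config$seed + 5,
                splicemap = config$seed + 6, emsa = config$seed + 7)
  out <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # simulate
  genome <- stage("simulate", {
    g <- make_genome(do.call(genome_config, config$genome),
                     seed = seeds$genome)
    model <- do.call(binding_model, config$binding)
    g <- plant_binding_sites(g, model, seed = seeds$sites)
    reads <- simulate_clip_reads(g, model, n_reads = config$n_reads,
                                 seed = seeds$reads)
    events <- simulate_splice_events(g, n_events = config$n_events,
                                     seed = seeds$events)
    write_genome_fasta(g, out("genome.fa"))
    write_annotation_gtf(g, out("annotation.gtf"))
    write_annotation_bed12(g, out("annotation.bed12"))
    write_reads_bed(reads, out("reads.bed"))
    write_splice_events_tsv(events, out("splice_events.tsv"))
    paths <- c(paths, out("genome.fa"), out("annotation.gtf"),
                out("annotation.bed12"), out("reads.bed"),
                out("splice_events.tsv"))
    summaries$simulate <- list(n_genes = nrow(g$genes),
                                n_sites = nrow(g$sites),
                                n_reads = nrow(reads),
                                n_events = nrow(events))
    list(genome = g, reads = reads, events = events)
  })

  peaks <- stage("callpeaks", {
    p <- do.call(call_peaks, c(list(genome$reads), config$peaks))
    write_peaks_bed(p, out("peaks.bed"))
    paths <- c(paths, out("peaks.bed"))
    summaries$callpeaks <- list(n_peaks = nrow(p),
                                 mean_length = if (nrow(p)) mean(p$length)
                                 else NA)
    p
  })

  stage("annotate", {
    pw <- config$annotate$promoter_width %||% 1000
    rd <- config$annotate$rescue_distance %||% 10000
    idx <- build_feature_index(genome$genome, promoter_width = pw)
    asn <- assign_peaks(peaks, idx)
    res <- rescue_intergenic(asn, genome$genome, max_distance = rd)
    write.table(res$assignments, out("assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$curve, out("rescue_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    props <- category_proportions(asn)
    biot <- classify_rna_type(asn, genome$genome)
    jsonlite::write_json(list(categories = props, biotypes = biot),
                         out("annotation_summary.json"), digits = NA)
    paths <- c(paths, out("assignments.tsv"), out("rescue_curve.tsv"),
                out("annotation_summary.json"))
    summaries$annotate <- list(categories = setNames(props$proportion,
                                                      props$category))
  })

  stage("kmers", {
    kc <- config$kmers
    fg <- count_kmers_in_windows(peaks, genome$genome, k = kc$k %||% 4,
                                 window = kc$window %||% 20,
                                 flank = kc$flank %||% 20,
                                 mode = kc$mode %||% "span")
    bg <- background_frequencies(genome$genome, k = kc$k %||% 4,
                                 n_shuffles = kc$n_shuffles %||% 50,
                                 seed = seeds$kmers)
    sc <- enrichment_scores(fg, bg)
    write.table(sc, out("kmer_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(gc_summary(sc), out("kmer_gc_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, out("kmer_scores.tsv"), out("kmer_gc_summary.tsv"))
    site <- sc[sc$region == "site" | sc$region == "pctl3", ]
    summaries$kmers <- list(top = head(site$kmer, 5),
                             n_skipped = fg$n_skipped)
  })

  stage("boundaries", {
    bc <- config$boundaries
    ed <- bc$exon_depth %||% 100; id <- bc$intron_depth %||% 300
    bsets <- unique_boundaries(genome$genome)
    clen <- setNames(genome$genome$chromosomes$length,
                     genome$genome$chromosomes$name)
    prof <- profile_coverage(genome$reads, bsets$ei, type = "ei",
                             exon_depth = ed, intron_depth = id,
                             chrom_lengths = clen)
    bg1 <- background_profiles(genome$reads, genome$genome,
                               method = "shuffle-exons", type = "ei",
                               exon_depth = ed, intron_depth = id,
                               seed = seeds$boundaries)
    bg2 <- background_profiles(genome$reads, genome$genome,
                               method = "random-regions", type = "ei",
                               n_regions = bc$n_regions %||% 2000,
                               region_length = bc$region_length %||% 5000,
                               exon_depth = ed, intron_depth = id,
                               seed = seeds$boundaries + 1)
    tab <- data.frame(offset = prof$offset, count = prof$count,
                      density = prof$density,
                      n_boundaries = prof$n_boundaries,
                      background_shuffle = bg1$density,
                      background_random = bg2$density)
    write.table(tab, out("boundary_profile_ei.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, out("boundary_profile_ei.tsv"))
    summaries$boundaries <- list(n_ei = prof$n_boundaries,
                                  total = sum(prof$count))
  })

  stage("splicemap", {
    smc <- config$splicemap
    ev <- classify_events(genome$events)
    enh <- ev[ev$class == "enhanced", ]
    bgev <- ev[ev$class == "background", ]
    if (nrow(enh) && nrow(bgev)) {
      m <- map_significance(peaks, enh, bgev,
                            n_permutations = smc$n_permutations %||% 200,
                            exon_flank = smc$exon_flank %||% 50,
                            intron_window = smc$intron_window %||% 250,
                            smooth_window = smc$smooth_window %||% 50,
                            seed = seeds$splicemap)
      write.table(as.data.frame(m), out("splicing_map_enhanced.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, out("splicing_map_enhanced.tsv"))
      summaries$splicemap <- list(n_enhanced = nrow(enh),
                                   n_background = nrow(bgev),
                                   min_p = min(m$p_value))
    } else {
      summaries$splicemap <- list(skipped = "no enhanced or background events")
    }
  })

  stage("emsa", {
    ec <- config$emsa
    titr <- simulate_titration(ec$n_true %||% 1.75, ec$K_true %||% 1.95e6,
                               noise_sd = ec$noise_sd %||% 0.03,
                               seed = seeds$emsa)
    fit <- fit_stoichiometry_affinity(titr)
    write_titration_tsv(titr, out("titration.tsv"))
    write_fit_json(fit, out("titration_fit.json"))
    comp <- simulate_competition(ec$m %||% 1, ec$n %||% 1,
                                 ec$K_DNA %||% 1.42e7, ec$K_RNA %||% 5.6e5,
                                 noise_sd = ec$noise_sd %||% 0.03,
                                 seed = seeds$emsa + 1)
    cfit <- competition_ratio(comp)
    write_competition_tsv(comp, out("competition.tsv"))
    write_fit_json(cfit, out("competition_fit.json"))
    paths <- c(paths, out("titration.tsv"), out("titration_fit.json"),
                out("competition.tsv"), out("competition_fit.json"))
    summaries$emsa <- list(n = fit$n, K = fit$K,
                            ratio_dna_rna = cfit$ratio_dna_rna)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("clipbind")),
    seeds = seeds,
    outputs = data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE),
    summaries = summaries)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
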
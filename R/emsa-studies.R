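# Replicate recovery studies: simulate many seeded series from stated
# parameters and summarise how well the estimators recover them. These are
# the computations behind the EMSA parameter-recovery checks; the
# acceptance script and the test suite both call them.

#' Titration parameter-recovery study
#'
#' Simulates \code{n_reps} independent titrations from the single-step
#' n-mer model (one derived seed per replicate), fits each by the log-log
#' OLS estimator, and reports the mean fitted stoichiometry and
#' monomer-equivalent association constant.
#'
#' @param n_true,K_true Generating stoichiometry and monomer-equivalent
#'   affinity (M^-1).
#' @param n_reps Number of replicates (default 200).
#' @param concentrations Protein grid (default \code{emsa_grid()}).
#' @param noise_sd Band noise sd (default 0.03).
#' @param seed Base seed; replicate r uses \code{seed * 1000 + r} (kept
#'   below 2^31).
#' @return A list: mean_n, mean_K, sd_n, sd_K, n_reps, failures.
#' @export
titration_recovery_study <- function(n_true, K_true, n_reps = 200,
                                     concentrations = emsa_grid(),
                                     noise_sd = 0.03, seed = 1) {
  ns <- numeric(0); Ks <- numeric(0); failures <- 0L
  for (r in seq_len(n_reps)) {
    s <- (as.integer(seed) * 1000L + r) %% .Machine$integer.max
    titr <- simulate_titration(n_true, K_true,
                               concentrations = concentrations,
                               noise_sd = noise_sd, seed = s)
    fit <- tryCatch(fit_stoichiometry_affinity(titr), error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    ns <- c(ns, fit$n); Ks <- c(Ks, fit$K)
  }
  list(mean_n = mean(ns), mean_K = mean(Ks), sd_n = sd(ns), sd_K = sd(Ks),
       n_reps = n_reps, failures = failures)
}

#' Competition-ratio recovery study
#'
#' Simulates \code{n_reps} equimolar competition series with the given
#' affinity ratio, runs the per-point ratio estimator with zero-protein
#' extrapolation on each, and reports the mean extrapolated DNA/RNA ratio
#' and the mean of the per-replicate reciprocals.
#'
#' The absolute affinity scale is a free experimental-design choice; by
#' default the two species' affinities are centred so their geometric mean
#' equals the reciprocal of the grid's geometric-centre concentration,
#' i.e. the titration window brackets both species' transitions.
#'
#' @param ratio_dna_rna Generating K_DNA/K_RNA.
#' @param m,n Stoichiometries (default 1 and 1).
#' @param n_reps Number of replicates.
#' @param concentrations Protein grid.
#' @param noise_sd Band noise sd.
#' @param K_geo Geometric mean of the two affinities (M^-1); defaults to
#'   the centred design described above.
#' @param seed Base seed (same derivation as
#'   \code{\link{titration_recovery_study}}).
#' @return A list: mean_ratio_dna_rna, mean_ratio_rna_dna, sd_ratio,
#'   K_DNA, K_RNA, n_reps, failures.
#' @export
competition_recovery_study <- function(ratio_dna_rna, m = 1, n = 1,
                                       n_reps = 200,
                                       concentrations = emsa_grid(),
                                       noise_sd = 0.03, K_geo = NULL,
                                       seed = 1) {
  K_geo <- K_geo %||% (1 / sqrt(min(concentrations[concentrations > 0]) *
                                  max(concentrations)))
  K_DNA <- K_geo * sqrt(ratio_dna_rna)
  K_RNA <- K_geo / sqrt(ratio_dna_rna)
  fw <- numeric(0); rv <- numeric(0); failures <- 0L
  for (r in seq_len(n_reps)) {
    s <- (as.integer(seed) * 1000L + 500000L + r) %% .Machine$integer.max
    comp <- simulate_competition(m, n, K_DNA, K_RNA,
                                 concentrations = concentrations,
                                 noise_sd = noise_sd, seed = s)
    fit <- tryCatch(competition_ratio(comp), error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    fw <- c(fw, fit$ratio_dna_rna); rv <- c(rv, fit$ratio_rna_dna)
  }
  list(mean_ratio_dna_rna = mean(fw), mean_ratio_rna_dna = mean(rv),
       sd_ratio = sd(fw), K_DNA = K_DNA, K_RNA = K_RNA,
       n_reps = n_reps, failures = failures)
}
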
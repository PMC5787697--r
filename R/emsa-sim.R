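#' Default EMSA protein concentration grid
#'
#' Twelve log-spaced total-protein concentrations spanning 0.05 to 2.5 uM,
#' the range used for gel-shift titrations of PARP1 constructs against a
#' 19-mer single-stranded RNA. Log spacing places equal numbers of points
#' per decade, the standard design for isotherms analysed in log-log space.
#'
#' @param n Number of concentrations.
#' @param min_M,max_M Range in molar units.
#' @return Numeric vector of molar concentrations.
#' @export
emsa_grid <- function(n = 12, min_M = 0.05e-6, max_M = 2.5e-6) {
  stopifnot(n >= 2, min_M > 0, max_M > min_M)
  exp(seq(log(min_M), log(max_M), length.out = n))
}

# Noiseless single-step n-mer isotherm: fraction bound at total protein P,
# with Kn = K^n (K the monomer-equivalent association constant, M^-1).
# Ligand is in trace, so total protein stands in for free protein.
fraction_bound_nmer <- function(P, n, K) {
  x <- n * (log(K) + log(P))
  ifelse(P <= 0, 0, 1 / (1 + exp(-x)))
}

#' Simulate an EMSA titration series
#'
#' Forward model of a single-step binding equilibrium in which \code{n_true}
#' protein monomers associate with one nucleic-acid molecule:
#' \deqn{K_n = [P_nR] / ([R][P]^n), \quad K_n = K^n}
#' so the noiseless fraction bound at total protein \eqn{P} is
#' \eqn{K_n P^n / (1 + K_n P^n)}. Gaussian noise (the band-quantitation
#' error of phosphor images) is added to the measured fractions, which are
#' then clipped to [0, 1].
#'
#' @param n_true True stoichiometry (monomers per nucleic acid), > 0.
#' @param K_true True monomer-equivalent association constant, M^-1.
#' @param concentrations Total protein concentrations (molar). Defaults to
#'   \code{emsa_grid()}.
#' @param noise_sd Gaussian sd on measured fraction bound (default 0.03).
#' @param ligand_M Total ligand concentration (molar); recorded as metadata
#'   (the trace-ligand regime is assumed, default 0.05 uM).
#' @param species Label, \code{"RNA"} or \code{"DNA"}.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A data.frame of class \code{"titration_series"} with columns
#'   \code{protein_M}, \code{fraction_bound}, \code{species}, and attributes
#'   \code{ligand_M}, \code{truth} (list of generating parameters).
#' @export
simulate_titration <- function(n_true, K_true, concentrations = emsa_grid(),
                               noise_sd = 0.03, ligand_M = 0.05e-6,
                               species = "RNA", seed = NULL) {
  stopifnot(n_true > 0, K_true > 0, noise_sd >= 0)
  if (any(concentrations < 0)) {
    stop("negative protein concentrations are not allowed", call. = FALSE)
  }
  f <- fraction_bound_nmer(concentrations, n_true, K_true)
  f_obs <- with_seed(seed, {
    pmin(pmax(f + rnorm(length(f), 0, noise_sd), 0), 1)
  })
  out <- data.frame(protein_M = concentrations, fraction_bound = f_obs,
                    species = species, stringsAsFactors = FALSE)
  attr(out, "ligand_M") <- ligand_M
  attr(out, "truth") <- list(n = n_true, K = K_true, noise_sd = noise_sd)
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Simulate an equimolar DNA/RNA competition EMSA series
#'
#' Both radiolabeled ligands are present at the same trace concentration and
#' titrated with one protein; each species' free fraction follows its own
#' single-step isotherm independently (trace-ligand regime, no depletion of
#' protein by either ligand). Band-quantitation noise is added to the free
#' fractions and clipped to [0, 1].
#'
#' @param m,n Stoichiometries for the DNA and RNA binding steps.
#' @param K_DNA,K_RNA Monomer-equivalent association constants, M^-1.
#' @param concentrations Shared total-protein grid (molar).
#' @param noise_sd Gaussian sd on the measured free fractions.
#' @param ligand_M Total concentration of each ligand (equimolar, molar).
#' @param seed Integer seed.
#' @return A data.frame of class \code{"competition_series"} with columns
#'   \code{protein_M}, \code{dna_free_fraction}, \code{rna_free_fraction};
#'   attributes \code{m}, \code{n}, \code{ligand_M} and \code{truth}
#'   (including the generating ratio \code{K_DNA/K_RNA}).
#' @export
simulate_competition <- function(m, n, K_DNA, K_RNA,
                                 concentrations = emsa_grid(),
                                 noise_sd = 0.03, ligand_M = 0.05e-6,
                                 seed = NULL) {
  stopifnot(m > 0, n > 0, K_DNA > 0, K_RNA > 0, noise_sd >= 0)
  if (any(concentrations < 0)) {
    stop("negative protein concentrations are not allowed", call. = FALSE)
  }
  d_free <- 1 - fraction_bound_nmer(concentrations, m, K_DNA)
  r_free <- 1 - fraction_bound_nmer(concentrations, n, K_RNA)
  obs <- with_seed(seed, {
    list(d = pmin(pmax(d_free + rnorm(length(d_free), 0, noise_sd), 0), 1),
         r = pmin(pmax(r_free + rnorm(length(r_free), 0, noise_sd), 0), 1))
  })
  out <- data.frame(protein_M = concentrations,
                    dna_free_fraction = obs$d,
                    rna_free_fraction = obs$r)
  attr(out, "m") <- m
  attr(out, "n") <- n
  attr(out, "ligand_M") <- ligand_M
  attr(out, "truth") <- list(K_DNA = K_DNA, K_RNA = K_RNA,
                             ratio = K_DNA / K_RNA, noise_sd = noise_sd)
  class(out) <- c("competition_series", "data.frame")
  out
}
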
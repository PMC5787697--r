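#' Fit binding stoichiometry and affinity from a gel-shift titration
#'
#' Log-linearizes the single-step n-mer binding model,
#' \deqn{\ln([P_nR]/[R]) = n \ln[P]_{free} + \ln K_n,}
#' and fits it by ordinary least squares: the slope estimates the
#' stoichiometry \eqn{n}, the intercept \eqn{\ln K_n}, and the
#' monomer-equivalent association constant is \eqn{K = \exp(\ln K_n / n)}
#' (the reciprocal of the midpoint protein concentration). Total protein is
#' used as the free-protein estimate (trace-ligand regime).
#'
#' Points whose fraction bound falls outside \code{usable_range} are excluded
#' from the regression: the log-odds transform has derivative
#' \eqn{1/(f(1-f))}, so a few percent of band-quantitation noise overwhelms
#' the signal outside the transition region, and values of exactly 0 or 1
#' have no logarithm at all. The window is applied in two passes: a first
#' fit selects on the observed fractions, a second (reported) fit selects on
#' the first fit's predicted fractions, so that points are not admitted or
#' rejected on the basis of their own noise (which would bias the slope
#' towards zero). The excluded points are reported in the fit.
#'
#' @param series A \code{titration_series} data.frame (columns
#'   \code{protein_M}, \code{fraction_bound}), e.g. from
#'   \code{\link{simulate_titration}} or \code{\link{read_titration_tsv}}.
#' @param usable_range Closed interval of usable fraction-bound values;
#'   default \code{c(0.1, 0.9)}.
#' @param n_boot Bootstrap resamples (over points) for seeded uncertainty
#'   estimates; 0 disables.
#' @param seed Seed for the bootstrap.
#' @return An object of class \code{"binding_fit"}: a list with elements
#'   \code{n}, \code{ln_Kn}, \code{K}, \code{se_n}, \code{se_ln_Kn},
#'   \code{r_squared}, \code{midpoint_M}, \code{usable} (logical mask),
#'   \code{n_points_used}, and optionally \code{boot} (bootstrap sds).
#' @export
fit_stoichiometry_affinity <- function(series, usable_range = c(0.1, 0.9),
                                       n_boot = 0, seed = NULL) {
  stopifnot(is.data.frame(series),
            all(c("protein_M", "fraction_bound") %in% names(series)))
  P <- series$protein_M
  f <- series$fraction_bound
  usable <- f > 0 & f < 1 & f >= usable_range[1] & f <= usable_range[2]
  if (any(P[usable] <= 0)) {
    stop("non-positive protein concentrations among usable points",
         call. = FALSE)
  }
  if (sum(usable) < 3) {
    stop(sprintf(
      "need at least 3 usable points with fraction bound in [%g, %g]; got %d",
      usable_range[1], usable_range[2], sum(usable)), call. = FALSE)
  }
  fit_ols <- function(sel) lm(log(f[sel] / (1 - f[sel])) ~ log(P[sel]))
  pass1 <- coef(fit_ols(usable))
  # pass 2: select on the model-predicted fractions, not the noisy ones
  pred <- 1 / (1 + exp(-(pass1[1] + pass1[2] * log(P))))
  usable2 <- f > 0 & f < 1 & P > 0 &
    pred >= usable_range[1] & pred <= usable_range[2]
  if (sum(usable2) >= 3) usable <- usable2
  x <- log(P[usable])
  y <- log(f[usable] / (1 - f[usable]))
  fit <- lm(y ~ x)
  # noiseless input triggers summary.lm's "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  n_hat <- unname(coef(fit)[2])
  ln_Kn <- unname(coef(fit)[1])
  if (!is.finite(n_hat) || n_hat <= 0) {
    stop("fitted stoichiometry is not positive; data do not describe a ",
         "rising isotherm", call. = FALSE)
  }
  out <- list(
    n = n_hat,
    ln_Kn = ln_Kn,
    K = exp(ln_Kn / n_hat),
    se_n = sm$coefficients[2, 2],
    se_ln_Kn = sm$coefficients[1, 2],
    r_squared = sm$r.squared,
    midpoint_M = exp(-ln_Kn / n_hat),
    usable = usable,
    n_points_used = sum(usable),
    usable_range = usable_range
  )
  if (n_boot > 0) {
    idx <- which(usable)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        take <- sample(seq_along(idx), replace = TRUE)
        co <- coef(lm(y[take] ~ x[take]))
        c(co[2], co[1])
      }, numeric(2))
    })
    out$boot <- list(sd_n = sd(boots[1, ]), sd_ln_Kn = sd(boots[2, ]),
                     n_boot = n_boot)
  }
  class(out) <- "binding_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "Single-step n-mer binding fit\n  n (stoichiometry): %.3f (se %.3f)\n  ln Kn:             %.3f (se %.3f)\n  K (M^-1):          %.4g\n  midpoint (M):      %.4g\n  r^2:               %.4f on %d points\n",
    x$n, x$se_n, x$ln_Kn, x$se_ln_Kn, x$K, x$midpoint_M, x$r_squared,
    x$n_points_used))
  invisible(x)
}

#' Monomer-equivalent association constant
#'
#' Converts an overall n-mer association constant \eqn{K_n} (in M^-n) to its
#' monomer-equivalent \eqn{K = \exp(\ln K_n / n)} in M^-1, which equals the
#' reciprocal of the protein concentration at the titration midpoint.
#'
#' @param fit A \code{binding_fit}, or a list with \code{ln_Kn} and \code{n}.
#' @return K in M^-1.
#' @export
monomer_equivalent_K <- function(fit) {
  stopifnot(!is.null(fit$ln_Kn), !is.null(fit$n))
  if (fit$n <= 0) stop("stoichiometry must be positive", call. = FALSE)
  exp(fit$ln_Kn / fit$n)
}

#' Relative DNA/RNA affinity from a competition EMSA series
#'
#' Implements the per-point competition estimator
#' \deqn{K_{DNA}/K_{RNA} = \frac{[P_mD]/([D][P]^m)}{[P_nR]/([R][P]^n)}}
#' with \eqn{[P_mD] = ([D]_0 - [D]_{free}) m} and
#' \eqn{[P_nR] = ([R]_0 - [R]_{free}) n} (complexes co-migrate, so only the
#' disappearance of the free bands is quantified), followed by a straight-line
#' extrapolation of the ratio to zero protein. The line is fitted to
#' \eqn{\ln(ratio)} against protein concentration (ratios are positive with
#' near-multiplicative error) and the intercept exponentiated.
#'
#' Usable points require both free fractions to lie at least
#' \code{min_fraction} away from 0 and 1: a band within one quantitation
#' noise-sd of blank or saturation carries no ratio information. By default
#' the line uses all usable points; \code{extrapolation_fraction} < 1
#' restricts it to the lowest-concentration part of the usable set.
#'
#' @param series A \code{competition_series} data.frame with columns
#'   \code{protein_M}, \code{dna_free_fraction}, \code{rna_free_fraction}.
#' @param m,n Stoichiometries for DNA and RNA binding (from single-ligand
#'   titrations). Defaults are taken from the series attributes if present.
#' @param extrapolation_fraction Fraction (0, 1] of usable points, taken from
#'   the low-concentration end, used for the extrapolation; at least 3 points
#'   are always used.
#' @param min_fraction Quantitation floor on free fractions (default 0.03).
#' @return A list of class \code{"competition_fit"}: \code{ratio_dna_rna}
#'   (intercept at zero protein), \code{ratio_rna_dna} (its reciprocal),
#'   \code{points} (per-point ratio table), \code{usable}, \code{n_points_fit}.
#' @export
competition_ratio <- function(series, m = NULL, n = NULL,
                              extrapolation_fraction = 1.0,
                              min_fraction = 0.03) {
  stopifnot(is.data.frame(series),
            all(c("protein_M", "dna_free_fraction", "rna_free_fraction")
                %in% names(series)))
  m <- m %||% attr(series, "m")
  n <- n %||% attr(series, "n")
  if (is.null(m) || is.null(n)) {
    stop("stoichiometries m and n must be supplied (or carried as ",
         "series attributes)", call. = FALSE)
  }
  stopifnot(m > 0, n > 0, extrapolation_fraction > 0,
            extrapolation_fraction <= 1)
  P <- series$protein_M
  Df <- series$dna_free_fraction
  Rf <- series$rna_free_fraction
  if (all(Df <= 0) || all(Rf <= 0)) {
    stop("all points saturated (free fraction 0); cannot form ratios",
         call. = FALSE)
  }
  lo <- min_fraction
  usable <- P > 0 &
    Df >= lo & Df <= 1 - lo &
    Rf >= lo & Rf <= 1 - lo
  if (sum(usable) < 3) {
    stop(sprintf(
      "need at least 3 usable points with free fractions in [%g, %g]; got %d",
      lo, 1 - lo, sum(usable)), call. = FALSE)
  }
  # [PmD]/[D] * P^(n-m) / ([PnR]/[R]); equimolar ligands cancel [D]0/[R]0.
  ratio <- ((1 - Df) * m / Df) * P^(n - m) / ((1 - Rf) * n / Rf)
  pts <- data.frame(protein_M = P, ratio = ratio, usable = usable)
  ord <- order(P[usable])
  k <- max(3L, ceiling(extrapolation_fraction * sum(usable)))
  k <- min(k, sum(usable))
  sel <- which(usable)[ord][seq_len(k)]
  fit <- lm(log(ratio[sel]) ~ P[sel])
  intercept <- exp(unname(coef(fit)[1]))
  structure(list(
    ratio_dna_rna = intercept,
    ratio_rna_dna = 1 / intercept,
    points = pts,
    usable = usable,
    n_points_fit = k,
    m = m, n = n
  ), class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf(
    "Competition EMSA fit (m = %.3g, n = %.3g)\n  K_DNA/K_RNA at [P]=0: %.4g\n  K_RNA/K_DNA:          %.4g\n  points used:          %d of %d usable\n",
    x$m, x$n, x$ratio_dna_rna, x$ratio_rna_dna, x$n_points_fit,
    sum(x$usable)))
  invisible(x)
}
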
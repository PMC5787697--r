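---
title: "clipbind: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clipbind: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipbind)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the method left room.

## 1. Crosslink-filtered peak calling

PAR-CLIP reads carry T-to-C transitions at direct protein-RNA contacts
(4-thiouridine photocrosslinks misread during reverse transcription).
`call_peaks()` groups aligned reads by chains of same-strand overlaps of at
least 1 bp and keeps a group as a binding site iff

1. its T-to-C conversion frequency (converted reads over all reads in the
   group) is at least 0.25,
2. it contains **more than five** reads with a T-to-C conversion — six or
   more, the threshold is exclusive — with at most one mismatch allowed per
   read, and
3. it shows at least two distinct conversion positions.

Conventions worth stating explicitly:

* **Strand separation.** Conversions are defined on the sense strand (a
  minus-strand T-to-C appears as A-to-G in reference coordinates; readers
  and writers perform that flip, and mismatch offsets are stored in sense
  orientation from the read 5' end). Groups never mix strands.
* **Copy counts.** Reads are assumed PCR-collapsed upstream; a collapsed
  read with `copy_count = c` counts as c reads in every criterion.
* **Anchor.** Each peak is localized to the conversion position with the
  highest converted-read support; ties break to the leftmost position for
  determinism. The anchor drives feature assignment and splicing maps.
* **Frequency is read-level**, not per-position: criterion 1's ratio uses
  converted reads over all reads; per-position support is retained on the
  peak's conversion-site table for diagnostics.

The whole caller is verified against a brute-force oracle (transitive
closure of pairwise overlaps plus direct predicate evaluation) on hundreds
of random read sets, and the three thresholds are checked for monotonicity.

## 2. Feature partition and intergenic rescue

Peaks are assigned to one of six categories — 5' UTR, 3' UTR, exon,
promoter, intron, intergenic — by their **anchor base**, not by interval
overlap, since the anchor is the crosslink evidence. Design choices:

* **Precedence** for bases carrying several annotations:
  5' UTR > 3' UTR > exon > promoter > intron > intergenic. UTRs outrank
  exon so the categories stay disjoint ("exon" is effectively CDS exon for
  coding genes; exonic bases of noncoding genes also count as exon).
* **Promoter** is a fixed window upstream of the TSS, 1000 bp by default
  and configurable — "promoter" has no standard width, 1 kb is
  conventional.
* **Same-strand only**: a peak antisense to the only overlapping gene is
  intergenic, because sense-strand RNA evidence cannot originate from the
  antisense gene.

`rescue_intergenic()` asks whether intergenic peaks are plausibly
unannotated transcript extensions: it measures the distance from each
intergenic anchor to the nearest same-strand CDS stop codon upstream of it
in transcript orientation (a 3' UTR extension) and to the nearest start
codon downstream (an upstream extension), rescues peaks within 10 kb, and
breaks equidistant ties toward the stop codon (the 3'-extension reading).
An optional secondary annotation flags further peaks as `other-annotation`;
the cumulative count-versus-distance table is emitted for plotting.

## 3. K-mer enrichment

Scores are log2 odds of pseudocounted frequencies,
`log2(f_region / f_background)`, with a pseudocount of 0.5 per k-mer per
table (Jeffreys-style smoothing; it also makes the odds identity
`sum(2^score * f_background) = 1` hold exactly). The background is built by
composition-preserving mononucleotide shuffling of every protein-coding
(spliced CDS) sequence, pooled over many shuffles; the shuffle count
defaults to the conventional 10000 but pooled frequencies stabilise far
earlier at toy scale, so the workflow scales it down.

**Window choice.** The default foreground ("span" mode) counts the k-mers
obtained by sliding a window along each cluster, i.e. all k-mers in the
peak span, with fixed flanks on either side. An anchor-centred fixed window
("anchor" mode) is also available but has a subtle artefact worth knowing
about: the centre base of such a window is a crosslink T *by construction*,
so T-rich k-mers inflate even for perfectly unbiased site sequence (TTTT
gains ~0.8 log2 units under a uniform null — analytically: 4 of 17 window
positions of a 4-mer overlap the forced T). Span mode has no pinned
position and is null-calibrated: with unbiased planted sites and >= 2000
peaks the maximum |score| over all 4-mers stays below 0.5. A "percentile"
mode splits the peak span into fifths for positional profiles.

GC summaries average scores over k-mers with GC fraction >= 0.75 (GC-rich)
and <= 0.25 (AT-rich); an empty class is reported as missing, not zero.

## 4. Exon-boundary metaprofiles

`profile_coverage()` accumulates copy-count-weighted read coverage at each
base from 100 bp inside the exon to 300 bp inside the intron around
exon-to-intron (EI) and intron-to-exon (IE) boundaries, in transcript
orientation: offset 0 is the first intronic base, exonic offsets are
negative, and minus-strand boundaries are mirrored. Boundaries come from
protein-coding transcripts only, exclude terminal exon ends (no following
intron), and are deduplicated per strand exactly as duplicated exon
start/end locations across transcripts would be. Boundaries closer than the
intron depth to the next boundary are counted fully — no truncation — so
the totals match a naive per-boundary scan, which is what the tests compare
against.

Two background randomizations keep the reads fixed and randomize the
annotation side: repositioning exon intervals uniformly on their own
chromosome (preserving per-chromosome count, sizes and strand), and drawing
uniform fixed-length regions whose start/end stand in for EI/IE boundaries
(full-scale defaults 150000 regions of 5000 bp, scaled down for toy
genomes). Only exon placements are shuffled, never reads.

## 5. Positional splicing maps

Events are classified from an rMATS-style table: enhanced iff P <= 0.05,
FDR <= 0.05 and inclusion difference >= +0.1; silenced with <= -0.1;
background iff FDR > 0.5; all else excluded. The map covers four regions
flanking the cassette exon (50 bp exon flanks, 250 bp intron windows — the
conventional splicing-map geometry, configurable) and counts, per position,
the **fraction of events** with at least one peak anchor there (binary per
event, so one peak-rich event cannot dominate), smoothed with a centred
50-position moving average that shrinks at array edges.

Significance is by resampling: background events are drawn **with
replacement** to the target class size, and
`p = (1 + #{resamples with density >= observed}) / (1 + n)` per position
(never zero, by the add-one rule). Bootstrap rather than subsampling is
deliberate: drawing n events without replacement from a pool of N
comparable size shrinks the resampling variance by (1 - n/N), so null
p-values pile up at the floor — on pure noise with a pool only marginally
larger than the target, a third of positions looked "significant". With
bootstrap resampling, signal-free runs put ~5% of positions below 0.05.
With 200 permutations the attainable p floor is 1/201, so Bonferroni
control across the ~1200 map positions is conservative by construction;
the planted-signal checks therefore read detection at the uncorrected 0.05
level at known offsets, alongside the calibration check.

## 6. EMSA binding quantitation

The single-step n-mer model: n protein monomers bind one nucleic acid,
`Kn = [PnR]/([R][P]^n)`, log-linearized to
`ln([PnR]/[R]) = n ln[P]free + ln Kn` and fit by OLS; total protein stands
in for free protein in the trace-ligand regime. The slope is the
stoichiometry, and `K = exp(ln Kn / n)` is the monomer-equivalent
association constant — the reciprocal of the midpoint concentration, which
makes constructs with different stoichiometries comparable.

**Usable points.** The log-odds transform has derivative `1/(f(1-f))`:
at a band fraction of 0.05, three points of quantitation noise move the
transformed value by ~0.65. Points outside a quantitation window (default
fraction bound in [0.1, 0.9]; exact 0/1 always excluded) are therefore
dropped. The window is applied in **two passes**: a first fit selects on
observed fractions, the reported fit selects on the first fit's predicted
fractions. Selecting each point on its own noisy value admits low points
only when their noise is positive (and symmetrically at the top), which
flattens the slope — a measurable -5% stoichiometry bias in simulation;
the two-pass rule removes the conditioning on each point's own noise and
cuts the bias to under 2%. Uncertainties are OLS standard errors plus an
optional seeded bootstrap over points.

**Competition.** Complexes co-migrate on the gel, so only the free-band
disappearance of each species is quantified. Per protein concentration,
`ratio = ([PmD]/[D]) P^(n-m) / ([PnR]/[R])` with
`[PmD] = ([D]0 - [D]free) m`, and the ratio is extrapolated to zero
protein by a straight-line fit. Numerical choices, fixed from a simulation
study *before* the acceptance checks were written:

* the line is fit to `ln(ratio)` versus P and the intercept exponentiated —
  ratios are positive with near-multiplicative error;
* a point is usable only if **both** species' free fractions are at least
  0.03 (about one noise sd) away from 0 and 1: a band indistinguishable
  from blank or saturation carries no ratio information;
* the default extrapolation region is **all** usable points
  (`extrapolation_fraction = 1`, configurable). Restricting to the
  lowest-concentration half sounds conservative but is badly biased
  whenever the weaker binder is barely bound at low protein — its bound
  fraction sits inside the noise there — and the quantitation floor
  already removes the saturated high-concentration tail that a "modest
  concentrations only" rule is meant to exclude.

**Experimental-design anchoring.** For simulated competition studies the
published parameter sets pin only the affinity *ratio*; the absolute scale is an
experimental-design choice. The generators center the geometric mean of the
two affinities on the reciprocal of the protein grid's geometric-centre
concentration (12 log-spaced points over 0.05-2.5 uM), i.e. the titration
window brackets both species' transitions — which is how one designs such
an experiment at the bench. Under that design, 200-replicate recovery
studies return the generating ratios to within ~2%.

## 7. What the simulators emulate — and what they do not

The generators reproduce the statistical structure the analyses rely on:
reads of 16-23 nt with the empirical length histogram (mode 20 nt), T-to-C
conversions at planted sites with configurable probability, GC-biased site
sequence (per-base log2 odds of G/C, default 2, i.e. P(G or C) = 0.8),
site placement over exon-boundary flanks / intron bodies / intergenic
space (default weights 0.25/0.40/0.35 — chosen once to mirror the broad
observed partition of binding between intronic and intergenic space; no
published generative description of intergenic binding exists, so the
intergenic rate is a free parameter), cassette-exon tables with planted
effect classes, and single-step isotherms with additive Gaussian band noise
clipped to [0, 1].

They deliberately do **not** model: sequencing errors beyond the single
crosslink mismatch, base qualities, PCR duplication (reads are
pre-collapsed), transcript isoform complexity (one transcript per gene by
default), expression heterogeneity between genes, RNA secondary structure,
or multi-step/cooperative binding. A green test therefore establishes that
the estimators recover what the stated forward models plant — not that
those models capture every property of real libraries. Two forward-model
simplifications matter when interpreting recovery numbers: background
reads are uniform (real intergenic background is not), and competition
free fractions are independent across species (true only in the
trace-ligand regime both assays are run in).

## 8. Determinism and degenerate inputs

Every random step takes an explicit seed and restores the caller's RNG
state; `run_pipeline()` derives per-stage seeds from one master seed and
writes a manifest with md5 checksums — two runs from one config are
byte-identical. Degenerate inputs are defined rather than accidental:
empty read sets yield empty peak tables; a group with no conversions has
an NA anchor and cannot pass the filters; zero-event classes are an error
in the splicing map (no normalisation exists); titrations need at least
three usable points; competition series with an all-saturated species are
rejected. GTF is 1-based inclusive on disk and 0-based half-open in
memory, converted in the readers/writers and nowhere else.
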
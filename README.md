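# clipbind

Analysis workflow for mapping where a chromatin-associated protein binds
RNA, built around two complementary kinds of evidence:

* **PAR-CLIP sequencing.** 4-thiouridine crosslinking leaves diagnostic
  T-to-C transitions in reads at direct protein-RNA contacts. The package
  groups aligned reads into clusters, filters them into binding-site peaks
  by conversion evidence, partitions the peaks across genomic features,
  scores positional k-mer enrichment against shuffled coding-sequence
  backgrounds, builds exon-boundary coverage metaprofiles with two
  background randomizations, and draws positional splicing maps around
  regulated cassette exons with permutation significance.
* **Gel-shift (EMSA) biochemistry.** Titrations of protein against a
  labeled nucleic acid are fit for binding stoichiometry and affinity, and
  two-ligand competition series yield relative DNA-versus-RNA affinities.

Every input can be simulated by the package's own generators (toy genome,
crosslink reads, splice-event tables, noisy binding isotherms), so the full
pipeline runs and is tested without any external download.

## The models

**Peak calling.** Reads are grouped by chains of same-strand overlaps
(>= 1 bp). A group is a binding site iff it (1) has T-to-C conversion
frequency >= 0.25 (converted reads / all reads, copy-count weighted),
(2) contains more than five reads with a T-to-C conversion (at most one
mismatch per read), and (3) shows at least two distinct conversion
positions. Each peak is anchored at its most-supported conversion site.

**K-mer enrichment.** For k-mers counted along peaks (sense strand), the
enrichment score is the log2 odds

    score(w) = log2( f_peak(w) / f_background(w) )

with pseudocounted frequencies and a background from mononucleotide
shuffling of all protein-coding sequences.

**Splicing maps.** Skipped-exon events with P <= 0.05, FDR <= 0.05 and
|dPSI| >= 0.1 are enhanced (dPSI >= +0.1) or silenced (dPSI <= -0.1);
events with FDR > 0.5 are the background set. For each class, the fraction
of events with a peak anchor at each transcript-oriented position in the
four regions flanking the cassette exon (50 bp exon flanks, 250 bp intron
windows, 50-position smoothing) is compared against bootstrap resamples of
background events: p = (1 + #{resamples >= observed}) / (1 + n).

**EMSA.** For a single binding step in which n protein monomers bind one
nucleic acid, Kn = [PnR] / ([R][P]^n), so

    ln([PnR]/[R]) = n ln[P]_free + ln Kn

and an OLS fit in log-log space gives the stoichiometry n (slope) and the
monomer-equivalent association constant K = exp(ln Kn / n), the reciprocal
of the midpoint protein concentration. For equimolar competition,

    K_DNA/K_RNA = ([PmD]/([D][P]^m)) / ([PnR]/([R][P]^n)),
    [PmD] = ([D]0 - [D]free) m,   [PnR] = ([R]0 - [R]free) n,

evaluated per protein concentration and extrapolated linearly (on the log
scale) to [P] = 0.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data and write tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

Output from a run of stages 1-7 (seeds fixed in the scripts):

```
simulated: 40 genes (5 lincRNA, 5 miRNA, 26 mRNA, 4 snRNA), 400 binding sites,
  40000 reads (55.1% converted), 600 splice events
called 326 peaks from 40000 reads; mean length 32.1 nt (median 27),
  mean conversion frequency 0.68
feature partition: utr5 0%, utr3 0%, exon 14%, promoter 3%, intron 45%, intergenic 38%
intergenic rescue: 27 of 125 within 10 kb of a stop/start codon
top enriched site 4-mers: GCCG (2.19), CCGC (2.03), CGCG (2.02), ...
EI: 62 boundaries; exon-flank density 62.17 vs backgrounds 1.29 / 0.91
enhanced (95 events): min p = 0.010; 53 of 1200 positions with p <= 0.05
            construct        quantity truth recovered rel_error_pct
                   FL stoichiometry n  1.75     1.763        0.7283
                 dCAT stoichiometry n  3.31     3.331        0.6478
       FL-competition     K_DNA/K_RNA 25.30    25.233       -0.2642
  dZn1Zn2-competition     K_RNA/K_DNA  7.20     7.362        2.2447
```

Reading the numbers: the planted GC-rich sites surface as GC-rich top
4-mers; coverage at exon/intron boundaries stands ~50-fold above both
background randomizations because sites were planted at exon 3' flanks;
with no planted positional signal relative to the background events, ~5%
of splicing-map positions reach p <= 0.05 (the permutation test is
calibrated); and the 200-replicate gel-shift studies recover the generating
stoichiometries and affinity ratios to within a few percent.

A single pipeline run with one config (and a checksummed manifest proving
reruns are byte-identical):

```r
library(clipbind)
cfg <- read_pipeline_config(system.file("extdata", "smoke_config.json",
                                        package = "clipbind"))
run_pipeline(cfg)
```

## Acceptance script

`scripts/acceptance.R` recomputes the gel-shift parameter-recovery
quantities from scratch: it simulates 200 seeded 12-point titrations
(0.05-2.5 uM, noise sd 0.03 on band fractions) for the full-length
(n = 1.75, K = 1.95e6 M^-1) and catalytic-deletion (n = 3.31) parameter
sets, fits each replicate in log-log space, and simulates 200 equimolar
competition series for the 25.3-fold DNA preference and the 7.2-fold RNA
preference of the zinc-finger deletion, extrapolating per-point affinity
ratios to zero protein. Run from the repository root against the installed
package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
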
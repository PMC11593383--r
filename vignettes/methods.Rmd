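---
title: "Detecting ROH, F_ROH and ROH islands: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ROH, F_ROH and ROH islands: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rohscan` implements a complete runs-of-homozygosity (ROH) analysis for
dense SNP-array genotypes: quality control, class-calibrated
consecutive-runs detection, the genomic inbreeding coefficient F_ROH, and
z-score-based ROH-island identification with cross-population sharing.
This vignette explains the model behind each stage, the parameters that
matter, the numerical choices made where the design was genuinely open,
and what the synthetic-data validation does and does not demonstrate.

## Data model and quality control

Genotypes are stored as integer codes per (individual, marker): `0`/`2`
for the two homozygotes, `1` for heterozygotes, `NA` for missing. ROH
detection only distinguishes homozygous / heterozygous / missing — which
allele is shared is irrelevant to autozygosity — but both homozygote codes
are kept so PLINK filesets round-trip exactly. Markers are grouped by
chromosome and strictly ordered by bp position; only chromosomes with
purely numeric labels (autosomes) enter any ROH computation, since
hemizygous sex chromosomes would mimic homozygosity.

QC removes markers with more than 10 % missing calls first, then
individuals with more than 10 % missing calls *on the surviving markers*
(the `--geno`-then-`--mind` convention of the standard tooling; the order
matters and is tested). Deliberately, there is **no minor-allele-frequency
filter**: a rare allele that is homozygous in one animal is exactly the
kind of information an ROH scan needs, and removing low-MAF SNPs thins the
map inside runs.

## Consecutive-runs detection

A run is grown marker by marker and terminated when

* the count of heterozygous calls would exceed `max_het`,
* the count of missing calls would exceed `max_missing`, or
* two consecutive markers are more than `max_gap_bp` apart
  (default 100,000 bp — beyond that the chip gives no evidence the
  intervening sequence is homozygous).

The violating call ends the run *before* itself; runs are trimmed so they
start and end on homozygous non-missing calls (otherwise allowance-eating
calls could pad boundaries); and runs with fewer than `min_snp_count = 15`
SNPs or shorter than the smallest class bound are discarded. Run length is
defined as `end_bp − start_bp`, the span between the first and last SNP of
the run.

Two details of the greedy scan deserve explicit statement because they fix
semantics the method name alone does not:

1. **Disjointness beats maximality.** When allowances are nonzero,
   genuinely maximal windows can overlap (a window ending before one
   heterozygote and a window starting after an earlier one share their
   middle). We use the classical greedy resolution: take the leftmost
   homozygous-bounded window extended as far right as the constraints
   allow, emit it, and continue after its trimmed end. The result is a
   deterministic, disjoint, ordered segment list. The test suite contains
   an independent brute-force enumerator (exhaustive per-window
   recounting, same selection policy) and requires exact agreement on
   hundreds of random chromosomes.
2. **Total covered bp is not monotone in the allowances.** Raising
   `max_het` can merge two runs across an interior break and thereby trade
   away trailing territory larger than the gap gained. This is a property
   of any greedy consecutive scan, not a defect; the tests therefore check
   a weaker monotonicity (homozygous calls absorbed into runs).

## Two-pass calibration

Runs are stratified into five length classes — 1–2, 2–4, 4–8, 8–16 and
>16 Mb, half-open `[lower, upper)` — because a tolerable number of error
calls scales with run size. The allowances are not free parameters; they
are derived from two assumed rates:

| parameter | default | meaning |
|---|---|---|
| `genotype_error_rate` | 0.0025 | probability a truly homozygous call is read heterozygous |
| `missing_rate` | 0.0014 | probability a call is missing |

A permissive first pass (allowances 12 het / 8 missing, the most
permissive final class, so pass 1 never under-segments relative to pass 2)
measures the mean SNP count of each class; each class then receives
`max_het = round(mean_snp × 0.0025)` and
`max_missing = round(mean_snp × 0.0014)`, floored at 1, and a second pass
re-detects runs class by class. "Average length" is interpreted as mean
**SNP count**, not mean bp: at HD density a >16 Mb class of ~5,000 SNPs
yields an allowance of ~12 heterozygotes, which is the right order of
magnitude, whereas bp-based multiplication would allow thousands. A
bp-based variant remains available (`calibration_basis = "bp"`) for
sensitivity analysis. The rounding rule defaults to half-up "nearest"
with `floor`/`ceiling` options, since printed allowance sets in the
literature are not always derivable from a single rule.

Degenerate inputs are handled explicitly: a class with no first-pass runs
inherits the nearest populated class's parameters (with a warning); if no
class is populated, calibration is an error rather than a silent guess.

The five per-class scans of pass 2 overlap, so they are reconciled per
individual: every candidate is assigned the class of its *realized*
length; candidates whose realized class matches the scan that produced
them win, ties go to the longer segment and then to fewer heterozygotes,
and accepted segments never overlap. Mismatched candidates remain eligible
as a fallback so that territory found only by a more permissive scan is
not discarded outright.

## F_ROH

`F_ROH = Σ segment lengths / L`. The default denominator `L` is the
map-covered autosomal length (sum over autosomes of first-to-last-SNP
spans): numerator and denominator then refer to the same chip, and the
coefficient is comparable across analyses of the same array. A fixed
assembly length can be passed instead; with the bovine HD chip the two
differ by well under 1 %. Individuals that pass QC but carry no ROH are
reported with F_ROH = 0; individuals removed by QC are absent, not zero.

## ROH islands

For one population, the incidence of a SNP is the percentage of
individuals with at least one ROH covering its position. Incidences are
standardized over **all autosomal SNPs pooled** (a per-chromosome option
exists): `z = (p − mean)/sd`. A SNP is significant when its one-sided
upper-tail normal p-value is below `tail_fraction = 1e-5` — the extreme
0.001 % — i.e. `z ≥ qnorm(1 − 1e-5) = 4.2649`. The upper tail is the
relevant one because islands are *high*-homozygosity outliers; a two-sided
switch exists. Significant SNPs on a chromosome merge into one island when
consecutive significant SNPs are at most `merge_gap_bp = 500,000` apart
(significant SNPs need not be contiguous on the chip), and islands need at
least `min_island_snps = 2`. Reported per island are both the
significant-SNP count and the total mapped SNPs inside its bounds, since
either convention appears in published tables. The population's threshold
percentage — the minimum incidence attained by any significant SNP — is
reported per scan.

Cross-population sharing merges islands of different populations whose bp
intervals overlap on the same chromosome, transitively (interval-graph
components), into one region labelled with the population set; the summed
per-population island counts always equal the total region memberships, an
identity the tests assert.

If incidence is constant (sd = 0) the scan warns and reports no islands
rather than dividing by zero.

## The synthetic-data generator

`simulate_dataset()` emulates exactly the features the pipeline's
contracts depend on: a multi-chromosome map at 280 markers/Mb (an HD
bovine chip after QC), per-SNP allele frequencies uniform on [0.05, 0.95],
Hardy–Weinberg background genotypes, autozygous tracts planted as
homozygous stretches (allele picked by frequency) per individual — by
explicit lengths, per-class counts, or a target autozygous fraction drawn
from a class mixture (default weights 0.2/0.25/0.25/0.2/0.1, a
middle-heavy mix typical of populations with both ancient and recent
inbreeding) — island regions shared by a configurable carrier fraction,
heterozygous errors inside tracts at 0.25 %, and genome-wide missingness
at 0.14 %. Everything derives from one seed; ground truth (tracts,
carriers, corrupted cells) is returned alongside the dataset.

What it does *not* emulate: linkage disequilibrium and realistic
allele-frequency spectra (detection as defined uses neither), coalescent
tract-length distributions, chip-specific intensity artifacts, and
pedigree structure. Passing tests therefore demonstrate algorithmic
correctness and calibrated behavior under the stated noise model — not
that any biological conclusion from real data is reproduced.

## Known quantitative behavior

Two systematic effects of the method itself, both measured by the test
suite and the acceptance script on planted ground truth, are worth
knowing:

* **Fragmentation shortfall.** A class allowance equals roughly the
  *expected* number of error calls in a class-mean run, so a substantial
  minority of true tracts carry more errors than their allowance and are
  split; fragments below 1 Mb or 15 SNPs are unreportable. Detected
  F_ROH therefore sits a few per cent *below* the planted autozygous
  fraction (at a planted 0.12 under nominal error rates, roughly 0.10–0.11
  is recovered; planted 0.02 is recovered almost exactly). The bias is
  one-sided and shared by any implementation of this calibration.
* **Boundary overshoot.** A greedy run entering a planted tract usually
  has unspent het allowance and so extends a few markers into the
  homozygous flank beyond the true boundary (tens of kb at HD density).
  Tract recovery is consequently assessed by span coverage, not by exact
  boundary agreement.

Neither effect impairs the island stage: incidence percentages are driven
by coverage, which exceeds 90 % of planted bp, and a region autozygous in
60 % of individuals against a low background is detected in every seeded
replicate of the validation.

## Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` run entirely on generated
data, chosen to exercise every stage at meaningful scale while remaining
quick on one CPU: scanner-versus-enumerator fuzzing on chromosomes of up
to 200 markers (100 replicates); tract recovery and F_ROH recovery on
50-individual populations over 2 × 50 Mb at HD density; island detection
on 20 replicates of 50 individuals over 2 × 40 Mb with a 2 Mb island at
60 % carriers; and a three-population pipeline smoke test. Larger inputs
change runtimes, not code paths: the scanner is linear in markers with
O(1) work per candidate run start.

## Limitations

* Only the consecutive-runs detector is provided — no sliding-window
  (PLINK `--homozyg`) mode, no heterozygosity-rich-region detection, and
  no pedigree-based inbreeding; results are therefore comparable to
  consecutive-method studies, not window-method ones.
* The island null is the pooled-normal approximation of incidence, not a
  permutation test; with very few individuals the incidence distribution
  is coarse and the z cut conservative.
* Gene annotation is a local interval table (BED 0-based half-open or TSV
  1-based inclusive); no online lookups are performed, by design.
* VCF input is out of scope; convert externally to PLINK format.
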
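---
title: "Strain typing and population comparison of fall armyworm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain typing and population comparison of fall armyworm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fawtype)
```

## Overview

`fawtype` implements a desk version of the standard fall armyworm
(*Spodoptera frugiperda*) strain-typing workflow: classify specimens into
C-strain / R-strain marker categories from *COI* and *Tpi* amplicon
sequences, aggregate per-population haplotype frequency profiles, and
quantify similarity between populations with diversity statistics, pairwise
Fst, profile correlations and a distance-based phylogeny. This vignette
records the model assumptions, the tunable parameters, the numerical
choices, and what the package's synthetic data do and do not establish.

## The classification model

### Anchored alignment instead of consensus building

Wet-lab workflows typically locate diagnostic sites by building a multiple
alignment and reading columns off a consensus. Here each query is aligned
pairwise to an ungapped reference segment, and diagnostic sites are stored
as 0-based offsets on that reference. Site coordinates therefore never
depend on how the amplicon was trimmed, and the field nomenclature
(mCOI1164D, mCOI1287R, gTpi183Y — positions numbered from the *COI*
translational start and from the 5' start of *Tpi* exon 4) is carried as
site labels.

The alignment is semi-global ("overlap": end gaps free on both sequences)
with affine penalties — match +2, mismatch −1, gap open −4, gap extend −1.
Free end gaps give the property, verified by a property-style test, that up
to 50 bases of random flanking sequence on either side never change a call.
Queries are uppercased and gap-stripped on entry; IUPAC ambiguity codes are
aligned with fractional match scores.

*Homology gate.* A query whose identity is below 70% in both orientations
(the reverse complement is tried before failing) is rejected as "not
homologous" — the guard against wrong-marker or wrong-species input.
Identity is computed over aligned columns **where both sequences have a
base**. The alternative (counting internal gap columns) would reject real
biology: one documented regional intron haplotype carries a 200-bp
insertion, which would drag column-wise identity below any reasonable
threshold while the sequence is a perfect match elsewhere.

### Diagnostic-site calls

* **COIB**: the bases homologous to mCOI1164 and mCOI1287 are read off the
  alignment; (T, A) → `COI_RS`; (A, A), (A, G), (G, A), (G, G) → `COI_h1`
  … `COI_h4`. Every other pair — ambiguity codes included — is
  `UNDETERMINED`, as is a site falling in a query deletion. The classifier
  is tested by exhaustive enumeration of the 49 base-pair combinations over
  {A, C, G, T, N, R, Y}².
* **TpiE4**: C → `TpiC`, T → `TpiR`, Y → `TpiH`. Because *Tpi* is Z-linked
  (males ZZ, females Z), the C/T overlap `Y` can only arise in a male
  carrying one allele of each strain: an interstrain hybrid. Reported
  heterozygosity at this site is limited to C/T; any other code is
  `UNDETERMINED` (and logged, since the behavior for, say, `R` at this site
  is not defined by the field's convention).
* **TpiI4**: the query subsequence homologous to the intron window is
  extracted (insertions relative to the reference are retained in the
  haplotype sequence). A specimen heterozygous for an intron frameshift
  produces superposed, frame-shifted chromatograph traces downstream of the
  indel; in an already-base-called sequence that signature survives as a
  sustained run of mixed-base ambiguity codes. The detector therefore
  excludes a specimen (`HET_INDEL_EXCLUDED`) when the window contains a run
  of ≥ `k` consecutive ambiguity codes. `k = 5` by default: long enough
  that ordinary isolated point heterozygotes (1–2 adjacent codes) never
  trigger it, short enough that any realistic frameshift overlap (tens of
  bases) always does. Isolated point ambiguities are resolved to the
  lexicographically smallest compatible base — the convention is arbitrary,
  but haplotype identity must be deterministic, and the choice is logged in
  the call output rather than hidden. Windows under 50 bases after
  extraction are `UNDETERMINED`.

Haplotype ids are assigned by exact string identity in first-seen order
(`Hap01`, `Hap02`, …); a pre-seeded registry (for example a regional
`Ecu01…` panel) is honored so re-runs are idempotent and ids are stable
across datasets.

## Population comparison

* **Profiles.** Specimens are pooled by a user-chosen metadata key;
  province × host plant is the documented default, matching how such
  surveys are usually reported. `UNDETERMINED` and `HET_INDEL_EXCLUDED`
  calls are excluded from denominators (percentages are of typed
  specimens) and counted in a report. With a fixed category panel,
  categories outside the panel collapse into `"other"`, preserving totals.
* **Pearson correlation** between frequency vectors over the shared
  category list, two-sided p from `t = r sqrt(df/(1−r²))` with
  df = categories − 2. No multiple-testing correction by default (matching
  the way such correlation tables are conventionally presented); a
  Bonferroni flag exists.
* **One-way ANOVA** on per-collection marker frequencies, with a
  summary-statistics path that reconstructs the sums of squares exactly
  from (n, mean, sd) — useful when only rounded group summaries are
  available. Note that an F computed from rounded summaries is not expected
  to match one computed on the raw data; the package's tests assert the
  value implied by the summaries themselves.
* **Diversity.** `Hd = n/(n−1)(1 − Σp²)`; its s.d. is the square root of
  Nei's (1987, eq. 8.12) sampling variance. `Pi` is the mean over unordered
  pairs of per-site differences with **pairwise deletion** (gap or
  ambiguity columns dropped per pair, indels never counted as differences),
  the substitution-only convention of standard polymorphism software;
  its s.d. uses the no-recombination total variance (Nei 1987, eq. 10.7)
  with L the mean number of compared sites. Pairwise deletion rather than
  complete deletion because the intron is indel-rich: complete deletion
  would discard most columns.
* **Fst.** `1 − π_within/π_between` with `π_within` the unweighted mean of
  the two within-population means (Hudson/Slatkin/Maddison style). This
  estimator was chosen over Weir–Cockerham-type estimators because
  published pairwise tables for this marker contain small negative values,
  which this estimator legitimately produces by sampling noise; negatives
  are reported as computed, never truncated. `π_between = 0` yields a
  missing value with a warning.

## Phylogeny

Unique haplotypes (deduplicated, with per-leaf annotations of source
locations and strain calls) are projected onto the reference intron window
to obtain a common alignment — insertions relative to the reference are
dropped here, consistent with substitution-only distances — and compared
under the Tamura–Nei (TN93) model, which separates the two transition
classes (A↔G, C↔T) from transversions with unequal base frequencies
estimated from each pair. Saturated pairs (non-positive log argument)
return a configurable ceiling, 5.0 substitutions/site, with a warning; in
the equal-frequency, equal-rate limit the formula collapses to the
Jukes–Cantor distance (verified to 1e-12 in tests, alongside agreement
with an independent implementation).

Trees are built with classic Saitou–Nei neighbor-joining using the
Studier–Keppler criterion. Ties in Q are broken deterministically by the
lowest index pair; negative branch lengths (possible on non-additive
input) are clamped to zero with the deficit transferred to the sibling
branch so the joined pair's path length is preserved. On additive
matrices NJ provably recovers the generating tree; the tests verify exact
recovery (topology and path lengths to 1e-9) on random additive trees up
to 12 taxa. Output is Newick at full double precision, with labels quoted
per the Newick convention when they contain metacharacters.

## The synthetic-data generator

The generator is a stated world, not a tuning knob: its defaults encode
the documented survey structure, and they were fixed before the acceptance
checks were run.

* A **haplotype panel** derives n distinct intron variants from the
  reference window by random substitutions (≤ 4 per variant) and short
  indels (≤ 1 of 1–6 bp), keeping an 8 bp margin from the window edges so
  anchored extraction is exact. Fourteen variants emulate the scale of a
  regional panel.
* Each simulated specimen draws sex (`male_fraction` 0.5), a COIB category,
  a Tpi category (females are restricted to the single-allele categories —
  `TpiH` requires two Z copies), and an intron haplotype, independently;
  a `linkage` parameter can make Tpi strain-concordant with COIB for
  scenarios where interstrain discordance should be rare. A male is
  emitted with an ambiguity run (length uniform 10–40, comfortably above
  the detector threshold) after a random intron position with probability
  `het_indel_rate`.
* The **fixture collection** reproduces, deterministically, the printed
  marginal structure of an Ecuadorian survey: 492 COIB-typed specimens
  (78 soft corn / 290 hard corn / 124 rice) with exactly four rice-strain
  exceptions in four named provinces; 431 Tpi-typed specimens
  (61/242/128) with seven TpiH among the 153 Manabi hard-corn specimens
  and no TpiR anywhere; 285 intron-typed specimens over the 14-haplotype
  panel with a dominant haplotype (42%) and a second common one (20%).
  Counts the source material does not print — the per-province splits
  within each host — are fixed documented choices; the reported
  percentages depend only on the printed marginals.

What a green test establishes: that classification, profiling, diversity,
Fst and tree stages are internally correct and mutually consistent, and
that the classifier inverts the generator exactly when no diagnostic-site
edits or heterozygous indels are injected (zero errors over 10,000
specimens). What it does not establish: agreement with the original
study's sequence-level results (its sequences were never deposited), nor
robustness to sequencing error, primer artifacts, alignment of distant
outgroups, or real chromatograph interpretation — the generator emits
clean base-called sequences by design.

## Numerical and degenerate-input choices

* Alignment tie-breaking is delegated to a deterministic dynamic program;
  equivalent-score gap placements may shift an indel by a base, which is
  why panel edits keep a margin from window boundaries.
* `Hd` requires n ≥ 2; `Pi` requires ≥ 2 sequences of equal aligned length
  and errors when no pair has comparable sites; pairs with zero comparable
  sites are dropped with a warning.
* `Fst` with `π_between = 0` is missing, not 0/0; negative values are kept.
* TN93 terms for an absent transition class (k = 0, e.g. no C or T in the
  pair) contribute zero rather than NaN.
* The per-population seed of every simulation is recorded in the truth
  table and report; identical (spec, seed) produce byte-identical output
  files.
* JSON configs must encode frequency maps as objects; arrays are rejected
  with a pointed error (named R vectors silently lose names when
  serialized as arrays — a real footgun).

## Known limitations

* The bundled references are synthetic stand-ins: classification against
  them is exact for simulated data but real amplicons require swapping in
  real reference segments (`faw_references(fasta=, sites=)`).
* Reference-anchored projection ignores insertions when computing
  distances and diversity; haplotype *identity* keeps insertions, so two
  haplotypes differing only by an insertion are distinct leaves but at
  distance ~0 in the tree.
* The heterozygous-frameshift detector is a model of a chromatograph
  signature, not a re-implementation of trace analysis; base callers that
  emit `N` runs rather than mixed-base codes are covered (N counts as an
  ambiguity code), but callers that silently pick one allele are not
  detectable from sequence alone.
* True diploid phase resolution of male *Tpi* genotypes is out of scope;
  `TpiH` is a category, not a phased genotype.
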
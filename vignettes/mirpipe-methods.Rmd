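---
title: "mirpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpipe)
```

`mirpipe` implements a plasma small RNA-seq analysis chain for circulating
miRNA biomarker studies: read cleaning and collapsing, tolerance-based
annotation against precursor hairpins, structural screening of novel
candidates, library-size normalization, differential-expression screening,
and biomarker statistics. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data tests do and
do not establish.

## Read cleaning and unique sequences

Raw reads are 3'-adapter-ligated inserts. `trim_adapter()` scans for the
leftmost start of an adapter prefix (at least 6 nt of overlap, a
configurable mismatch budget, default 1, no indels) and keeps the upstream
insert; a read that begins with the adapter is an adapter dimer.
`filter_read()` then applies, in order: the 18--26 nt length window
(inclusive; miRNA inserts are 19--24 nt, the window leaves isomiR head
room), a mean-Phred floor (default 20), an ambiguity cap (default 0 `N`
bases), and a low-complexity gate.

"Low complexity" has no standard definition at this stage, so it is
operationalized as Shannon entropy of the mononucleotide composition below
1.0 bit. Homopolymers score 0 bits and dinucleotide repeats 1.0 bit, so
both are caught, while the most skewed plausible miRNA compositions stay
above the floor. No repeat library is bundled; repeat removal is folded
into this gate, a deliberate desk-scale simplification.

`collapse_unique()` groups accepted inserts by exact string across samples
and orders rows by total count (ties: lexicographic), which makes output
order, and hence files, deterministic. Conservation (input = accepted +
rejected, per reason) is asserted by the tests at every stage boundary.

## Annotation tolerances

Unique sequences matching a contaminant record (rRNA/tRNA/snRNA/snoRNA
stand-ins) as an exact sense-strand substring are set aside first. The
remainder are placed on precursor hairpins ungapped, with at most one
internal mismatch; a placement agreeing with an annotated mature interval
within 2 nt at each end (configurable) is a known mature; a placement on
the arm opposite a precursor's sole annotated mature is a novel 5p/3p
candidate, and an 80 nt window centred on the placement (clipped to the
precursor) is recorded for structural assessment. Whether that "80 nt
flank" should be per side or total is ambiguous in the source workflow;
`mirpipe` uses a total window of 80 nt, configurable via `flank`.

Hits are ranked by (mismatches, total end shift), and the earliest-listed
precursor breaks remaining ties, so each sequence counts toward exactly one
precursor and the count matrix never double-counts. Coordinates are
1-based inclusive throughout -- the R/Bioconductor convention -- rather than
the 0-based half-open convention a Python implementation would use.

## Folding model and the eleven criteria

`fold()` is a self-contained energy-minimizing dynamic program over
non-crossing pairs: GC = -3.0, AU = -2.0, GU = -1.0 kcal/mol per pair,
hairpin loops of at least 3 nt, `N` never pairs. It is *not* a
nearest-neighbor thermodynamic model; stacking, dangles and loop penalties
are ignored. The criteria only consume the structure and an energy
threshold, and the free-energy cutoff (criterion 3, -15 kcal/mol) is
interpreted on this model's scale and is configurable. A structure computed
by an external folder can be injected through `secondary_structure()`
(sequence, dot-bracket, energy) without touching downstream code.

Ties in the DP are resolved deterministically: pairing is preferred over
leaving a base unpaired (this extends stems), and among equal-energy
partners the 5'-most wins. For every sequence up to 20 nt the tests verify
the minimum energy against an exhaustive enumeration over all valid
structures written as an independent oracle.

One symmetry subtlety: the energy model is symmetric in each pair, so
folding a *reversed* sequence gives the same minimum energy. The analogous
claim for the reverse *complement* is false once GU wobble pairs exist
(G·U maps to A·C, which does not pair); the property suite asserts the
reversal symmetry.

Feature extraction identifies hairpins as an innermost pair extended
outward through consecutively nested pairs separated only by unpaired runs;
branching (a multiloop) ends the stem. The dominant hairpin is the one
whose span contains the mature placement, falling back to the most-paired
stem. A *bulge* is a maximal unpaired run between consecutive stem pairs;
it is *biased* when the opposite strand contributes no unpaired base.
"Biased errors in one bulge" (criterion 7) -- undefined in the source
vocabulary -- is read literally as the largest single-strand unpaired count
within one mature-region bulge. All eleven thresholds
(`criteria_thresholds()`) default to the printed values and all comparisons
are boundary-inclusive (a stem of exactly 16 bp passes; energy of exactly
-15 passes).

## Library-size normalization

The factor for sample $j$ is
$$S_j = \mathrm{median}_i \; \frac{c_{ij}}{\left(\prod_{k=1}^{m} c_{ik}\right)^{1/m}},$$
the median across reference rows of the ratio of the sample's count to the
row's geometric-mean pseudo-reference. Rows containing any zero are
excluded from the reference set (the geometric mean is undefined at zero);
`pseudocount = TRUE` switches to a +0.5-on-everything variant. Geometric
means are computed in log space; even-cardinality medians are the mean of
the central pair; normalized values `c_ij / S_j` are reported unrounded.

A consequence worth stating precisely: because the pseudo-reference
contains sample $j$ itself, multiplying one library by $c$ scales $S_j$ by
$c^{(m-1)/m}$, not $c$, and rescales the *entire* normalized matrix by the
common factor $c^{1/m}$. All relative comparisons (fold changes, ROC
ranks, regression slopes up to a scalar) are unaffected, and the naive
"normalized column unchanged" statement is recovered only as
$m \to \infty$. The tests assert the exact law.

## Differential-expression screening

Screening deliberately uses raw p-values: FDR control is declined as too
conservative for a screening study, and a row is called DE when
$|\log_2 \mathrm{FC}| \ge 1$ and raw $p < 0.05$. The fold change uses group
means with a pseudocount of 0.5 to bound ratios involving zeros. The test
menu is triaged conventionally: Welch's t for continuous normalized values
(one-way fixed-effects ANOVA at three or more groups; a two-group ANOVA
differs from Welch by the pooled-variance choice and the code delegates to
Welch there), and for aggregated raw counts a 2x2 chi-square without
continuity correction against remaining library counts, switching to
Fisher's exact test when an expected cell drops below 5. The test used is
logged per row, since the source workflow does not state which test
produced which p-value.

A boundary fact surfaced by the property suite: a planted effect of exactly
2-fold sits *on* the fold gate, so the estimated fold change clears it in
only about half of replicates at any sample size. Power in the usual sense
(p < 0.05 with correct sign) for 2-fold effects at n = 5/group and
dispersion 0.05 exceeds 90%, and 4-fold effects pass the full DE gate in
over 90% of replicates; the corresponding literal "flagged DE" criterion at
exactly 2-fold is kept as a deliberately failing test rather than weakened.

## Biomarker statistics

`roc_auc()` computes the AUC as the Mann-Whitney probability with midrank
ties (ties count one half) and traces the curve over all distinct
thresholds; the trapezoidal area equals the rank statistic exactly, which
the tests assert along with AUC(-x) = 1 - AUC(x) and invariance under
strictly increasing transforms. Two markers are combined -- "both together
in the same model" -- as the fitted linear score of a maximum-likelihood
logistic regression, the standard joint-marker construction; separation is
tolerated (iteration cap with a warning) since only the ranking of scores
matters.

Pain-interference modelling follows the two-stage screen: one OLS fit per
candidate predictor on complete cases (n varies per predictor, mirroring
per-variable availability), then a single joint OLS containing exactly the
predictors with univariate p < 0.10, reporting the overall-F model p and
R². Covariate derivation uses the printed constants: wine 10.8 g, beer
13.2 g, liquor 15.1 g of alcohol per drink; 20 cigarettes per pack for
pack-years; smoker status as 20+ lifetime packs, 336+ g of tobacco, or 1+
cigarettes/day for a year. Group summary tables use Welch's t / ANOVA for
continuous rows and Pearson chi-square without continuity correction for
dichotomous rows -- the uncorrected chi-square reproduces the printed sex
p-value (0.04) from its 2x2 counts, which is why it is the default over
Fisher's exact test.

## The synthetic world

The generator states a world and the tests live in it; none of its
parameters were moved to make a test pass.

* **Reference**: each precursor is stem (24--30 bp, at most 2 planted
  internal mismatches) + loop (4--12 nt) + reverse-complement stem, with one
  20--24 nt mature arm per side and exactly one side annotated. Planted
  mismatch bases can occasionally pair elsewhere and split the fold, so the
  generator rejection-samples until the construction passes criteria 2, 4
  and 5, keeping the "passes by construction" invariant true rather than
  merely probable.
* **Reads**: per-miRNA counts are negative binomial around the requested
  expectation (dispersion 0.05 by default, Poisson at 0) -- the standard
  overdispersion model for sequencing counts. Reads are mature sequence
  with optional ±1--2 nt end variation drawn from precursor context, an
  optional single internal substitution (rate 0.02), then the adapter.
  Junk reads are homopolymer-rich (caught by the entropy gate), contaminant
  reads are substrings of contaminant records, and base qualities are a
  single high value (Phred 40): vendor-side quality variation is not
  modelled, only the quality gate's plumbing is exercised.
* **Depth**: desk-scale libraries of 10^4--10^5 reads stand in for the
  7--10 million reads of a production run. This changes sampling noise,
  not pipeline logic, and is documented rather than resolved.
* **Cohort**: group sizes default to the screening design (23/14/26),
  neuropathic-pain prevalence 0/0.54/0.65 by group, and interference scores
  are intercept (2.0, a mid-low value on the 0--10 scale) + 0.0004 x marker
  (the reported multivariable slope) + 2 x opioid use + N(0, 1), clipped to
  [0, 10]. Covariates are drawn from fixed marginals (72% male, age ~
  N(38, 11), and so on) chosen to resemble the cohort tables.

A green synthetic test therefore establishes that the algorithms implement
their contracts and recover planted truths at stated noise levels -- not
that the package reproduces the study's numbers, which would require the
undeposited raw data.

## Known limitations

* The folder's energy scale is model-specific; criterion 3's -15 kcal/mol
  threshold is not transferable to nearest-neighbor energies without
  recalibration (use the `secondary_structure()` adapter and adjust
  `criteria_thresholds(c3 = ...)`).
* Alignment is strictly ungapped and sense-strand; cross-species rescue
  mapping and genome BLAST of unmapped sequences are out of scope.
* Multi-precursor ties resolve to the earliest-listed precursor; this is a
  documented choice, not an inference about the original workflow.
* Complete-case handling in the linear models assumes covariates are
  missing unrelated to outcome.
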
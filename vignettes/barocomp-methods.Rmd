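---
title: "Methods: comparative amino-acid composition by structural context and domain age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative amino-acid composition by structural context and domain age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barocomp)
```

## The question and the model

Organisms adapted to high hydrostatic pressure (barophiles, or piezophiles)
substitute amino acids in a directional way relative to their low-pressure
relatives: five amino acids (Arg, Ser, Val, Asp, Gly) are preferentially
gained by the barophile, seven (Asn, Lys, Pro, Ile, Thr, Gln, Tyr) by the
nonbarophile, and the remaining eight appear unbiased. These preferences are
summarised by the barophily rank (BR), an integer ordering from 20 (most
barophilic) to 1 (least), packaged here as `load_barophily_reference()`.

`barocomp` asks *where in the protein* this bias lives. The observable is
the relative amino-acid abundance of a region: counts of each standard
residue divided by the number of standard residues (ambiguity letters X, B,
Z, U are excluded from numerator and denominator alike, so the 20
abundances always sum to 1 — the property every downstream statistic
assumes). Averaging over all sequences of a group gives the mean relative
amino-acid abundance (MAA). For each amino acid the package reports the MAA
difference (barophile minus nonbarophile, so positive means
barophile-tilted usage), a Welch two-sample *t*-test across the two
observation sets, and star annotations at the tiers
\*&nbsp;p&nbsp;<&nbsp;0.1, \*\*&nbsp;p&nbsp;<&nbsp;0.01,
\*\*\*&nbsp;p&nbsp;<&nbsp;0.001, \*\*\*\*&nbsp;p&nbsp;<&nbsp;0.0001. There
is deliberately no 0.05 tier, and no multiple-testing correction: the
report mirrors the conventional presentation of this analysis, raw Welch
p-values with those tiers.

## Structural contexts

Each sequence is partitioned by its fold-superfamily (FSF) domain
assignments into disjoint residue classes: shared-FSF regions (domains of
FSFs present in both species), species-specific-FSF regions, and
intervening (non-domain) sequence. A residue covered by both a shared and
a specific assignment is counted as shared — the overlap rule is a design
choice; the precedence keeps the classes disjoint so that the three counts
sum exactly to the sequence length, which is enforced by property tests.
The statistical unit for these contexts is one composition vector per
sequence per context (sequences with no residue in a context are skipped),
compared across species — the sample sizes reported in the run log are
sequence counts.

For homologous sequence pairs a finer analysis is used. Pairs are first
classified by their FSF multisets into five categories (no assignments /
one-sided / extra / different / identical); an extra repeat of a shared FSF
counts as an "extra assignment", a convention the multiset rule makes
explicit. Only category-5 pairs (identical multisets) enter the matched-FSF
analysis: the composition of each repeat of an FSF on a sequence is
computed separately and then averaged over repeats (repeat averaging, not
residue pooling — with repeats "R" and "DD" the averaged composition is
R = 0.5, whereas pooling would give 1/3), differences are taken within each
pair, averaged within each FSF over pairs, and the per-FSF species means
are compared with the Welch test. A paired one-sample alternative on the
per-FSF differences is provided as a non-default option
(`matched_comparison(..., method = "paired")`); the Welch route is the
default because it matches the two-sample test used everywhere else in the
pipeline.

## Domain age

Evolutionary ages of FSFs come from a rooted phylogenomic tree of domain
structures. The node distance nd of a leaf is the number of internal nodes
strictly between the root and the leaf, divided by the maximum such count
over all leaves: the most ancestral structure (a leaf attached directly to
the root) has nd = 0, the most recent has nd = 1. Counting *strictly
between* (excluding root and leaf) is the only reading under which a
root-attached leaf gets nd = 0, so that is the definition implemented; nd
is a topology-only statistic and ignores branch lengths. Polytomous
internal nodes count once each, an extension choice — the trees this
analysis was designed for are binary.

Ages in billions of years follow the linear FSF molecular clock

t = −3.831 · nd + 3.628,

so the intercept 3.628 Gy is the age of the most ancestral fold. The clock
can return slightly negative ages near nd = 1; the raw value is returned
with a warning rather than clamped, since clamping would silently distort
accumulation curves. Age strata are closed bins: ancient FSFs have
nd ∈ [0, 0.2] (before the onset of massive domain loss), recent FSFs
nd ∈ [0.6, 1] (after the "big bang" of domain combination). The stratified
matched-FSF comparisons restrict to FSFs in one stratum.

## The preference grid

Per-context comparisons are condensed into a grid: a cell holds B when the
barophile uses the amino acid significantly more (diff > 0, p < 0.1), N
when the nonbarophile does. An amino acid is flagged *consistent* when at
least four contexts carry a letter congruent with its barophily class and
no context carries an incongruent letter. The ≥ 4 / zero-incongruent rule
is a reverse-engineered summary convention, not a formula from the
literature; it is recorded here as the package's own choice and is
adjustable (`min_congruent`, `alpha`).

## The synthetic-data generator

Real censuses of this kind require external structural assignments and a
749-proteome tree, so the package ships a generator whose outputs exercise
every pipeline stage with known ground truth.

* **Tree.** Rooted binary trees grown by sequential random attachment of
  each new leaf to a uniformly chosen edge. Attachment to a uniformly
  chosen *leaf* (a Yule process) was rejected because it concentrates leaf
  depths near log *n* and leaves the ancient stratum nearly empty (about
  1.6 of 120 leaves on average, versus about 14 under edge attachment) —
  uniform edge attachment produces the unbalanced, deep trees this
  analysis needs. One root-attached pendant edge is protected from
  splitting, so every tree has a basal most-ancestral leaf at nd = 0.
* **Proteomes.** Each homologous pair draws a shared domain architecture
  (1–3 domains from the shared FSF pool). Domain-region residues are drawn
  i.i.d. from class-tilted frequencies: the barophile draws class-B amino
  acids with weight 1 + δ_eff and class-N with 1 − δ_eff (renormalised),
  the nonbarophile mirrored; intervening residues come from the untilted
  background in both species. δ_eff = δ × a per-stratum multiplier, so a
  bias can be confined to, say, ancient FSFs. I.i.d. sampling is a
  deliberate simplification: the analysis consumes composition only, so
  positional or phylogenetic autocorrelation would add nothing testable.
* **Defaults.** 300 pairs, 120 FSFs (80 % shared), domain length
  ~N(200, 40²) truncated at 30, intervening ~N(40, 15²), uniform
  background 0.05, δ = 0.2, 2 % of pairs in each of categories 1–4, and 40
  unpaired sequences per species carrying species-specific FSF domains
  (specific FSFs never enter homologous pairs, matching the observation
  that categories 3–4 contain no species-specific FSFs). These sizes give
  the acceptance suite strong power while keeping a full
  simulate-plus-analyse cycle around two seconds.
* **Ground truth.** The expected MAA difference in domain regions has the
  closed form E[diff] = p(aa)·(w_A/Z_A − w_B/Z_B), with w the class tilt
  and Z the normaliser (uniform background, δ = 0.2: Z_A = 0.98,
  Z_B = 1.02, so a class-B amino acid expects ≈ +0.0220 and class-N
  ≈ −0.0180). Note the class-I expectation is *not* exactly zero: because
  the B and N classes have unequal total background mass (5 vs 7 amino
  acids), the normalisers differ slightly between species and class-I
  amino acids inherit a small drift (≈ +0.0020 at the defaults). The truth
  tables report the exact form; tests assert against it, not against a
  rounded zero. Intervening regions are exactly null.
* **Determinism.** One integer seed drives a single RNG stream in fixed
  draw order; identical seeds give byte-identical bundles.

What passing recovery tests shows — and does not. The generator reproduces
the *statistical* structure the pipeline assumes: per-class mean shifts
confined to domain regions, age-modulated effects, homolog categories at
set rates. It does not emulate real proteome features such as non-uniform
background composition (configurable but defaulted uniform), length–
composition correlations, GC-driven codon pressure, or phylogenetic
autocorrelation between paralogs; recovery on synthetic bundles therefore
validates the machinery, not any biological claim about a particular
proteome pair.

## Numerical choices and degenerate inputs

* Composition vectors must sum to 1 to 1e−9; regions with no standard
  residue yield "no observation" and the sequence is skipped for that
  context rather than contributing a zero vector.
* `welch_t` requires two observations per group; when both groups have
  zero variance it returns p = 1 for equal means and raises an error
  otherwise (a degenerate comparison should be seen, not smoothed over).
* A star tree (all leaves attached to the root) has no defined nd and is
  rejected; trees must be rooted.
* Coordinates are 1-based inclusive in all on-disk formats (the convention
  of structural-census region strings, e.g. `"3-57,90-140"` for a split
  domain); the BED-like partition export uses 0-based half-open.
* Strata with fewer than two matched FSFs are skipped with a warning in
  the orchestrated run (an explicit error when called directly).

## Problem sizes used in the test suite

Module tests run on small bundles (20–150 pairs, 16–40 FSFs). The
recovery checks use the generator defaults (300 pairs, 120 FSFs,
δ = 0.2, seed 1); the stratified check confines the bias to ancient FSFs
via the stratum multipliers; the null calibration runs 50 seeds at δ = 0
and checks that fewer than 5 % of amino-acid cells reach p < 0.01 and that
the preference grid stays unflagged in at least 95 % of seeds. Oracle
comparisons cover 200 random trees (≤ 64 leaves) against an independent
path-enumeration of ancestors and 100 random Welch evaluations against the
closed form at 1e−10.

## Known limitations

* The consistency flag encodes a summary convention (≥ 4 congruent, none
  incongruent); other conventions are defensible and change which amino
  acids are flagged near the boundary.
* Welch tests are reported per amino acid without multiplicity adjustment,
  by design; users scanning many contexts should interpret isolated single
  stars accordingly.
* Compositions are compositional data; differences of means ignore the
  simplex geometry. This mirrors the analysis the package reproduces and
  is adequate for the small effects involved, but log-ratio approaches
  would be more principled for large shifts.
* Whether an observed sequence set's denominators should be all ORFs or
  only quality-filtered ones is input-dependent; `proteome_summary` uses
  all records in the supplied FASTA as denominator.
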
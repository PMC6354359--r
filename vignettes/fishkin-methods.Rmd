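---
title: "Methods: kin structure, cuckoldry, and inclusive fitness in fishkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kin structure, cuckoldry, and inclusive fitness in fishkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishkin)
```

# The problem

In socially monogamous species with external fertilization, paired males
routinely lose paternity to extra-pair males ("cuckolders"). If a paired
male is related to his cuckolders, part of that direct fitness loss is
returned as indirect fitness: the extra-pair offspring in his brood carry
a share of his alleles. **fishkin** provides the full analysis chain for
asking whether such kin-biased cuckoldry occurs in a population genotyped
at codominant markers (microsatellites), and a game-theoretic model for
asking when it *should* occur:

1. pairwise relatedness estimation (`relatednessPairs()`,
   `relatednessMatrix()`);
2. reconstruction of cuckolder genotypes from mothers and extra-pair
   full-sib groups (`reconstructSire()`, `filterReconstructed()`);
3. season-stratified randomization tests for elevated relatedness between
   paired males, paired females, and cuckolder sets
   (`randomizePairings()`, `bhAdjust()`);
4. intercept tests for deviations of parent-offspring relatedness from
   pedigree expectation (`buildDeviations()`, `interceptTest()`);
5. spatial kin-structure tests (`deltaR()`, `deltaRSweep()`,
   `mantelTest()`);
6. the inclusive-fitness game of cuckoldry tolerance
   (`pairedMaleFitness()`, `cuckolderFitness()`, `decisionMap()`,
   `monteCarloGame()`, `broodValueIncrease()`);
7. a synthetic-data generator stating the world the analyses assume
   (`synthConfig()`, `genAlleleFreqs()`, `genBroods()`,
   `genTerritoryMap()`), so every stage is testable without field data.

`runPipeline()` orchestrates stages 1-6 on either synthetic or
user-supplied inputs. The package's interface is its exported functions;
there is no shell entry point because every consumer of this analysis
works in R.

# Data model

Genotypes are diploid, codominant, and may contain *unknown* alleles —
either genuinely missing calls or unresolved alleles of reconstructed
cuckolders. `GenotypeSet` stores two character matrices (individuals x
loci), one per allele copy, with `NA` as the unknown state. Allele labels
are opaque strings: fragment lengths are never interpreted numerically,
and all results are invariant to relabeling. `BroodSet` links offspring
to mother, paired male, season, and a sire label (within-pair, or an
extra-pair full-sib group id); sibship inference is upstream of this
package and its output is taken as data. `AlleleFreqTable` holds
per-locus allele frequencies; `TerritoryMap` holds 2-D territory
coordinates (metres) and the territory each unpaired male was captured
next to, which stands in for his position.

Population allele frequencies default to pooling all supplied reference
adults. The field study that motivates the defaults estimated
frequencies from adults per season for sibship inference, but is silent
on which reference the relatedness estimators used; pooling is the
package default and per-season tables can be built by subsetting the
reference adults (`computeAlleleFreqs()` on a season's adults). Unknown
alleles are excluded from frequency counts, never imputed.

# Relatedness estimators

Two symmetric estimators are implemented from their original published
forms.

**Queller-Goodnight (`"QG"`).** For individuals a, b the directional
estimate is
$$\hat r_{a\leftarrow b} =
\frac{\sum_l \sum_{x \in \{a_1, a_2\}} (P_b(x) - p_x)}
     {\sum_l \sum_{x \in \{a_1, a_2\}} (P_a(x) - p_x)},$$
where \(P_i(x) \in \{0, 0.5, 1\}\) is the within-individual frequency of
allele x and \(p_x\) its population frequency. Numerator and denominator
are accumulated across loci before dividing (ratio of sums), and the
symmetric estimate is the mean of the two directions.

**Lynch-Ritland (`"LR"`).** With reference individual (x, y) and proband
(u, v), the per-locus estimate and weight are
$$\hat r_l = \frac{p_x(S_{yu}+S_{yv}) + p_y(S_{xu}+S_{xv}) - 4p_xp_y}
                  {(1+S_{xy})(p_x+p_y) - 4p_xp_y},\qquad
w_l = \frac{(1+S_{xy})(p_x+p_y) - 4p_xp_y}{2p_xp_y},$$
with S an identity indicator; the multilocus estimate is
\(\sum_l w_l \hat r_l / \sum_l w_l\) and the symmetric estimate averages
the two reference choices.

Conventions, all deliberate:

* loci with an unknown allele in either member are skipped; skipping
  never perturbs the contribution of the remaining loci;
* a direction with an exactly zero denominator (possible at, e.g., a
  two-allele locus with both frequencies 0.5) is dropped; if both
  directions are degenerate the pair is undefined and excluded
  downstream with a logged reason, as are pairs with no usable loci;
* frequencies are fixed inputs — no leave-pair-out re-estimation and no
  small-sample bias correction;
* the minimum usable loci per pair defaults to 1; the 10-locus rule
  belongs to reconstruction, not estimation.

Estimates centre on 0 / 0.25 / 0.5 for unrelated, half-sib, and
parent-offspring or full-sib dyads; individual estimates can be negative.
The calibration is asserted in the test suite over 10,000 simulated
dyads per class at the default marker panel.

# Cuckolder genotype reconstruction

Each extra-pair full-sib group identifies one unknown sire. Per locus,
the paternal allele of a fry is whatever remains after removing one copy
of a maternal allele from the fry's genotype. The rules, in order:

1. two distinct determined paternal alleles across the group: the sire is
   that heterozygote;
2. exactly one determined allele X: the sire is called X/X when the group
   has at least 8 fry, else X/unknown — with fewer fry one cannot tell a
   homozygous sire from a heterozygous one transmitting only X;
3. a fry heterozygous with the same two alleles as a heterozygous mother
   is ambiguous (either allele could be paternal); ambiguity is resolved
   first by the other fry of the group, else the more frequent allele in
   the population is assigned, and when the frequency difference is
   below one percentage point the allele is recorded unknown;
4. more than two candidate paternal alleles flag the locus inconsistent
   (an upstream sibship error) and set it unknown/unknown — flagged, not
   fatal, because sibships are inputs here.

Two conventions the source procedure leaves open: a locus where the
mother is not fully genotyped yields unknown/unknown (the maternal copy
cannot be subtracted unambiguously), and when one determined allele X
coexists with a persisting maternal-pair ambiguity {Y, Z} not containing
X — which proves the sire heterozygous — the second allele is resolved by
the same population-frequency rule.

Only sires with both alleles unambiguously identified at
`minCompleteLoci` (default 10 of 14) enter the cuckolder-relatedness
analyses; parent-offspring analyses use all offspring regardless.

**Known limitation.** Rules 2 and 3 are heuristics with small, inherent
error rates even on perfect data: a heterozygous sire transmits a single
allele to all n fry with probability \(2^{1-n}\), in which case rule 2
(at n >= 8) records a wrong-but-complete homozygote; and the frequency
tie-break of rule 3 guesses wrong with probability up to one half when
the sire shares alleles with the mother. On synthetic data (about 500
broods) this produces a handful of mismatched complete loci; the test
suite verifies that *every* complete-locus mismatch is of one of these
two documented kinds and that loci whose two alleles are directly
observed in fry always match the true sire. A test asserting a strict
100% match rate is retained and expected to fail, documenting that the
heuristics — not the implementation — set the accuracy ceiling.

# Randomization tests

Three pairings are tested for elevated relatedness: paired male x his
set of cuckolders, paired female x her set of cuckolders, and paired
male x paired female. The observed statistics are the mean, variance,
and moment skewness (\(m_3/m_2^{3/2}\); variance uses n-1) of the
per-focal set means. The null reshuffles, within season, the season's
pool of partners without replacement: each cuckolder is assigned to
exactly one focal per permutation (cuckolders essentially never sire in
two territories within a brood cycle) and the observed per-focal
set-size distribution is preserved. Broods where the paired male kept 0%
paternity are excluded from the cuckolder tests — they cannot be told
apart from territory takeovers.

p values are one-sided toward elevation with the add-one correction,
\(p = (\#\{\text{null} \ge \text{obs}\} + 1)/(B + 1)\); ties count as
extreme, so p is never 0 and the test is valid at finite B. The source
analysis does not state its tie or add-one conventions; these are the
package's choices, and a two-sided option exists. A permutation sample
with zero variance contributes skewness 0 to the null counting
(degenerate, logged in code). Benjamini-Hochberg step-up flags at a 10%
false discovery rate are applied across the family of 18 tests
(3 pairings x 2 estimators x 3 statistics) by `runPipeline()`.

The suite checks the type-I error of the mean test over 200 null
replicates against the 95% binomial band at alpha = 0.05, and a power
benchmark chosen to mirror the observed effect scale: 38 focal males
whose cuckolder sets contain a half sib with probability 0.3 yield
rejection in well over 80% of replicates.

# Parent-offspring deviation tests

If paired males are related to their mates, their relatedness to
within-pair fry exceeds 0.5; if females are related to their cuckolders,
their relatedness to extra-pair fry exceeds 0.5; and if paired males are
related to their cuckolders, their relatedness to extra-pair fry exceeds
half the within-pair relatedness R (which can be negative). The package
subtracts the appropriate expectation (0.5, 0.5, R/2) per offspring and
fits an intercept-only linear mixed model by REML with a random
intercept for brood (within-pair fry) or sire group nested in brood
(extra-pair fry), via `lme4`. The Wald t is reported with df = n - 1,
mirroring the residual-style df convention of the source analysis and
documented as approximate; p values are two-sided. Singular fits fall
back to the grand mean with cluster-robust (CR1) standard errors and are
flagged.

# Spatial kin structure

For each unpaired male, \(\Delta r\) is the maximum relatedness to the
paired males whose territories lie within X metres of his anchor
territory minus the maximum beyond X; the statistic is the mean over
unpaired males. Conventions where the source is silent: distances are
2-D Euclidean between territory centres (depth ignored), "within" is a
closed ball, and males with an empty within- or beyond-set at a radius
are dropped from that radius's mean and counted. The permutation null
re-anchors unpaired males uniformly at random under the capacity rule —
a territory accepts up to one unpaired male, or up to the number
originally captured there — and the sweep runs radii 1-10 m with
Benjamini-Hochberg flags across radii. Takeover-affected individuals are
handled by excluding them from the input tables, not in code. Mantel
tests of pairwise distance against relatedness among paired males
delegate to `vegan::mantel` (10,000 permutations, one-sided toward
positive association).

# The inclusive-fitness game

A paired male faces C ~ Poisson(\(\mu_C\)) unrelated potential
cuckolders and at most one related cuckolder, present with probability
f; he drives off D ~ Poisson(\(\mu_D\)) of them, or
Poisson\(((1-a)\mu_D)\) if he discriminates in favour of his relative —
the parameter \(0 \le a < 1\) prices the cognitive and tactical burden of
discrimination, paid whether or not the relative shows up. C - D follows
a Skellam distribution,
\(s_k = e^{-(\mu_C+\mu_D)}(\mu_C/\mu_D)^{k/2} I_k(2\sqrt{\mu_C\mu_D})\),
computed with R's `besselI` (exponentially scaled) and a Poisson
convolution series for orders far outside the support, where the Bessel
routine loses precision; all sums are truncated where the excluded
Poisson tail mass is below 1e-12 and the pmf is verified to sum to 1
within 1e-9. When more cuckolders arrive than can be repelled, every
successful male fertilizes an equal expected share of the clutch. The
analytic operations use deterministic expected shares; the Monte-Carlo
oracle (`monteCarloGame()`) exposes both that mode and a per-egg
multinomial mode, which agree in expectation.

Direct fitness of the focal and the relatedness-weighted share of his
relative (indirect fitness) are summed — a phenotypic form of Hamilton's
rule. Tolerance (discriminate defense) is adaptive when it raises the
paired male's total; targeting one's related paired male is adaptive for
a cuckolder, in a discriminating population, when it beats targeting a
stranger. `decisionMap()` evaluates both margins over a
(\(\mu_C\), a) grid (default 200 x 200 over [0, 10] x [0, 0.99]);
boundaries are where the margins change sign. The qualitative geometry —
tolerance at high sperm competition and low discrimination cost, never
at vanishing \(\mu_C\); a tolerate region that only grows as a falls —
is asserted in tests, as is agreement of every analytic term with the
10^6-draw Monte-Carlo oracle within 3 standard errors at five parameter
points.

`broodValueIncrease(rBar, loss)` converts an observed mean
male-cuckolder relatedness and an average paternity loss into the
percent increase in brood allelic value relative to cuckoldry by
non-relatives, \(100 \cdot loss \cdot \bar r/(1-loss)\): at the observed
\(\bar r = 0.038\) and loss = 0.449 this is 3.1%.

The supplementary closed form for the average relatedness of a paired
male to all his successful cuckolders is out of scope; the Monte-Carlo
oracle can estimate that quantity empirically. The analysis covers the
single-related-cuckolder game only.

# The synthetic world

The generator's defaults state the conditions the analyses assume, and
they are not tuned per test: 14 loci averaging ~21 alleles and mean
expected heterozygosity 0.88 (symmetric Dirichlet frequencies whose
concentration matches the target He in expectation, power-rescaled into
a +/-0.02 band when a draw falls outside it); 32 dry-season and 38
rainy-season broods; brood sizes Poisson with mean 28; per-brood
paternity loss Beta(2.245, 2.755) (mean 0.449, SD ~0.20); zero-paternity
broods forced at rate 6/70; 1-5 cuckolder sires per cuckolded brood with
probabilities (0.45, 0.30, 0.13, 0.07, 0.05), moment-matched to mean
~1.95 and SD ~1.1; a 100 m x 50 m quadrat with 36 unpaired males.
Founders are Hardy-Weinberg draws; fry inherit one uniformly chosen
allele from each parent; loci are unlinked; there is no genotyping error
by default (an optional per-allele error rate exists to stress-test
reconstruction). Two seasons are independent cohorts sharing allele
frequencies. Kinship injection makes one cuckolder per brood a half or
full sib of the paired male with configurable probability.

What a green test on this world does **not** establish: robustness to
genotyping error and null alleles, to misassigned sibships (the
generator's full-sib groups are exact), to linkage, to population
structure in the allele frequencies, or to non-Poisson territory
geometry. It does establish that the estimators are calibrated, the
reconstruction rules behave exactly as specified including their
boundary conditions, the permutation machinery holds its size and has
the intended power at the observed effect scale, and the analytic game
model is numerically exact against simulation.

# Numerical and design choices

* All randomized stages take explicit seeds; `runPipeline()` derives
  per-stage substreams from one master seed so adding a stage never
  perturbs earlier stages.
* Permutations are within-stratum Fisher-Yates shuffles; the capacity
  assignment samples territory slots without replacement, which is
  uniform over feasible assignments.
* Game-model sums truncate at the 1 - 1e-13 Poisson quantile plus a
  margin (tail mass < 1e-12), making results bit-stable across
  platforms at test tolerances.
* Benjamini-Hochberg flags are computed through `stats::p.adjust`
  (step-up rule, verified against a hand step-through in tests).
* A spec'd degenerate example — a map with a single territory — is not
  constructible, because the delta-r statistic needs a non-empty beyond
  set; the equivalent degeneracy (all relatedness values equal, so every
  permutation ties the observed statistic and p = 1) is tested instead.
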
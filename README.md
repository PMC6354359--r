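# fishkin

Kin structure, cuckoldry, and inclusive fitness in socially monogamous
fish.

In many socially monogamous species — the motivating system is a
biparental, externally fertilizing cichlid — paired males lose a large
fraction of their broods' paternity to extra-pair males ("cuckolders").
If a male is *related* to his cuckolders, part of that loss comes back
as indirect fitness, because the extra-pair fry in his care still carry
his alleles. **fishkin** is for population geneticists and behavioural
ecologists who have microsatellite genotypes of paired adults and their
broods (with sibship assignments) and want to ask: are males more
related to their cuckolders than chance predicts, does that propagate
into parent–offspring relatedness, is it spatially structured, and when
is tolerating related cuckolders actually adaptive?

## What it computes

* **Pairwise relatedness** — symmetric Queller–Goodnight and
  Lynch–Ritland estimators, r<sub>QG</sub> and r<sub>LR</sub>, from
  codominant marker genotypes with explicit unknown-allele handling.
  Estimates centre on 0 / 0.25 / 0.5 for unrelated / half-sib /
  parent–offspring dyads.
* **Cuckolder genotype reconstruction** — each extra-pair full-sib
  group identifies one sire; non-maternal alleles are assigned to him,
  with the ≥ 8-fry homozygote rule, the < 1-percentage-point frequency
  tie rule for mother-identical heterozygous fry, and a ≥ 10-of-14
  complete-loci retention filter.
* **Randomization tests** — season-stratified permutation nulls for the
  mean, variance, and skewness of relatedness between paired males ×
  cuckolder sets, females × cuckolder sets, and within social pairs,
  with zero-paternity broods excluded and Benjamini–Hochberg flags at a
  10% FDR.
* **Parent–offspring deviation tests** — intercept-only mixed models of
  r − 0.5 (male × within-pair fry, female × extra-pair fry) and
  r − R/2 (male × extra-pair fry, R = within-pair relatedness).
* **Spatial kin structure** — the Δr statistic (max relatedness to
  paired males within X m of an unpaired male's anchor territory minus
  the max beyond), swept over radii 1–10 m with a capacity-constrained
  permutation null, plus Mantel tests of distance vs relatedness.
* **The inclusive-fitness game** — Skellam-distributed sperm
  competition (C − D, with C ~ Pois(μ<sub>C</sub>) potential cuckolders
  and D ~ Pois(μ<sub>D</sub>) repelled), direct and indirect fitness of
  paired males (indiscriminate vs discriminate defense at cost a) and of
  cuckolders (related vs unrelated target), decision maps over
  (μ<sub>C</sub>, a), a Monte-Carlo oracle, and the brood allelic-value
  calculation 100·loss·r̄/(1 − loss).
* **Synthetic data** — generators for allele frequencies (14 loci,
  ~21 alleles/locus, He ≈ 0.88), pedigreed dyads, broods with
  configurable paternity loss and kinship injection, and territory maps,
  so the whole pipeline runs and calibrates without field data.

See `vignette("fishkin-methods")` for the models, conventions, and known
limitations.

## Worked example

A full synthetic run with kin-biased cuckoldry injected (each brood's
first cuckolder is a half sib of the paired male with probability 0.3):

```r
library(fishkin)
res <- runPipeline(config = synthConfig(kinshipProb = 0.3),
                   nPerm = 2000, decisionGrid = 21, seed = 4)
subset(res$randomization, statistic == "mean",
       select = c(pairing, estimator, observed, null_mean, p, bh_reject))
#>             pairing estimator     observed    null_mean            p bh_reject
#> 1    male_cuckolder        QG  0.058474453 -0.008636450 0.0004997501      TRUE
#> 4  female_cuckolder        QG -0.027826579 -0.008149876 0.9660169915     FALSE
#> 7       within_pair        QG  0.005805671  0.002080656 0.3658170915     FALSE
#> 10   male_cuckolder        LR  0.048585178 -0.003753320 0.0004997501      TRUE
#> 13 female_cuckolder        LR -0.014537774 -0.002964285 0.9330334833     FALSE
#> 16      within_pair        LR -0.001086945 -0.003580504 0.3493253373     FALSE
```

The male × cuckolder-set mean relatedness (0.058 for r<sub>QG</sub>) is
far above its permutation null (−0.009) and is the only BH-flagged test —
exactly the injected signal. The female and within-pair tests stay null.
The same signal resurfaces as elevated male × extra-pair-fry
relatedness after accounting for within-pair relatedness (the `MALE_EP`
intercept ≈ 0.033 ≈ half the male–cuckolder relatedness, p ≈ 0.005):

```r
subset(res$parentOffspring, estimator == "QG",
       select = c(kind, estimate, se, t, df, p))
#>        kind      estimate          se           t   df           p
#> 1   MALE_WP -0.0002805112 0.006326308 -0.04434042 1047 0.964641507
#> 2 FEMALE_EP -0.0038147522 0.004962479 -0.76871909  794 0.442288675
#> 3   MALE_EP  0.0334527707 0.011896814  2.81191004  794 0.005046276

res$model$broodValuePct   # % brood-value gain vs cuckoldry by non-relatives
#> [1] 4.460748
```

The game model, at a half-sib cuckolder present half the time and
moderate sperm competition:

```r
p <- GameParams(r = 0.25, f = 0.5, muC = 3, muD = 1, a = 0.2)
unlist(pairedMaleFitness(p, "DISCRIMINATE"))
#>     direct   indirect      total
#> 0.37551306 0.03063441 0.40614746

broodValueIncrease(0.038, 0.449)  # observed field effect: +3.1% brood value
#> [1] 3.096552
```

## Acceptance script

`scripts/acceptance.R` regenerates the default synthetic world from a
seed, runs the complete pipeline (frequencies → reconstruction →
randomization tests → parent–offspring tests → Δr sweep and Mantel →
decision map and brood-value calculation), prints a run summary, and
writes the machine-readable target report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Permutation counts in the script are scaled down (2,000 instead of
10,000) to keep it fast; every stage still executes.
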
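## One configured run reproducing the full analysis sequence on a given
## input set (synthetic or user-supplied).

## per-stage substreams: adding a stage must not perturb earlier stages
.stageSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1000L + stage
}

#' Run the full kin-structure analysis pipeline
#'
#' Executes, in order: population allele frequencies, cuckolder genotype
#' reconstruction with the minimum-complete-loci filter, zero-paternity
#' brood exclusion, the three season-stratified randomization tests (mean,
#' variance, skewness; both estimators) with Benjamini-Hochberg flags
#' across the family, the three parent-offspring intercept tests, the
#' spatial delta-r radius sweep and Mantel test (when a territory map is
#' available), and the game-model decision map plus the brood fitness-value
#' calculation anchored at the observed male-cuckolder relatedness.
#'
#' With no input objects a complete synthetic dataset is generated from
#' `config`. Every source of randomness derives from `seed` through
#' per-stage substreams, so reruns with the same seed are identical.
#'
#' @param genotypes optional [GenotypeSet-class] (adults and offspring).
#' @param broods optional [BroodSet-class].
#' @param map optional [TerritoryMap-class] for the spatial stage.
#' @param adultIds ids of the reference adults for allele frequencies
#'   (required with user-supplied genotypes).
#' @param config a [synthConfig()] list, used when `genotypes` is NULL.
#' @param estimators estimators to run (`"QG"`, `"LR"`).
#' @param nPerm permutations per randomization test.
#' @param radii delta-r radii in metres.
#' @param fdr false discovery rate for Benjamini-Hochberg flags.
#' @param minCompleteLoci reconstruction retention threshold.
#' @param decisionGrid number of grid points per axis for the decision map.
#' @param seed integer seed.
#' @param outDir optional directory; result tables are written as CSVs.
#' @return list with elements `freqs`, `sires`, `randomization`,
#'   `parentOffspring`, `spatial`, `model`, `counts`, `seed`.
#' @export
runPipeline <- function(genotypes = NULL, broods = NULL, map = NULL,
                        adultIds = NULL, config = synthConfig(),
                        estimators = c("QG", "LR"), nPerm = 10000L,
                        radii = 1:10, fdr = 0.10, minCompleteLoci = 10L,
                        decisionGrid = 41L, seed = 1L, outDir = NULL) {
  synthetic <- is.null(genotypes)
  counts <- list()
  if (synthetic) {
    freqs <- genAlleleFreqs(config, seed = .stageSeed(seed, 1L))
    sim <- genBroods(config, freqs, seed = .stageSeed(seed, 2L))
    genotypes <- sim$genotypes
    broods <- sim$broods
    adultIds <- sim$adults$individual_id
    ## population frequencies are estimated from the generated adults, as
    ## they would be from field-captured adults
    freqs <- computeAlleleFreqs(genotypes[match(adultIds,
                                                individualIds(genotypes)), ])
  } else {
    if (is.null(broods)) stop("broods must be supplied with genotypes")
    if (is.null(adultIds)) stop("adultIds must be supplied with genotypes")
    freqs <- computeAlleleFreqs(genotypes[match(adultIds,
                                                individualIds(genotypes)), ])
  }
  ## --- reconstruction ---------------------------------------------------
  sires <- reconstructBroodSires(genotypes, broods, freqs)
  siresKept <- filterReconstructed(sires, minCompleteLoci)
  counts$sires_reconstructed <- nrow(sireInfo(sires))
  counts$sires_retained <- nrow(sireInfo(siresKept))
  allg <- combineGenotypes(genotypes, sireGenotypes(siresKept))
  ## --- randomization tests ---------------------------------------------
  obs <- pairingObservations(broods, siresKept)
  counts$broods_total <- length(broodIds(broods))
  counts$broods_zero_paternity <-
    sum(paternityFraction(broods) == 0)
  rand <- list()
  stage <- 3L
  for (est in estimators) {
    ids <- unique(unlist(lapply(obs, function(o)
      c(o$focal_id, o$partner_id))))
    rmat <- relatednessMatrix(allg, freqs, est, rows = ids)
    for (nm in names(obs)) {
      scheme <- if (nm == "within_pair") "WITHIN_PAIR" else "FOCAL_VS_SET"
      res <- randomizePairings(obs[[nm]], rmat, scheme, nPerm = nPerm,
                               seed = .stageSeed(seed, stage))
      stage <- stage + 1L
      res$pairing <- nm
      res$estimator <- est
      rand[[paste(nm, est)]] <- res
    }
  }
  randomization <- do.call(rbind, c(rand, make.row.names = FALSE))
  randomization$bh_reject <- bhAdjust(randomization$p, fdr)
  ## --- parent-offspring deviation tests --------------------------------
  po <- list()
  for (est in estimators) {
    for (kind in c("MALE_WP", "FEMALE_EP", "MALE_EP")) {
      devs <- buildDeviations(kind, broods, allg, freqs, est)
      fit <- interceptTest(devs, if (kind == "MALE_WP") "brood"
                                 else "sire-in-brood")
      fit$kind <- kind
      fit$estimator <- est
      fit$n_obs <- nrow(devs)
      po[[paste(kind, est)]] <- fit
    }
  }
  parentOffspring <- do.call(rbind, c(po, make.row.names = FALSE))
  ## --- spatial ----------------------------------------------------------
  spatial <- NULL
  if (synthetic && is.null(map)) {
    season1 <- names(config$nPairs)[1L]
    ad <- sim$adults
    pm <- ad$individual_id[ad$role == "paired_male" & ad$season == season1]
    up <- ad$individual_id[ad$role == "cuckolder" & ad$season == season1]
    up <- utils::head(up, config$nUnpairedMales)
    map <- genTerritoryMap(pm, up, config, placement = "uniform",
                           seed = .stageSeed(seed, 20L))
  }
  if (!is.null(map)) {
    tt <- territories(map)
    pm <- tt$paired_male_id[!is.na(tt$paired_male_id)]
    up <- anchors(map)$unpaired_male_id
    est1 <- estimators[1L]
    rmat_sp <- relatednessMatrix(allg, freqs, est1,
                                 rows = unique(c(up, pm)))
    sweep <- deltaRSweep(map, rmat_sp, radii = radii, nPerm = nPerm,
                         seed = .stageSeed(seed, 21L), q = fdr)
    dmat <- .territoryDist(tt)[match(pm, tt$paired_male_id),
                               match(pm, tt$paired_male_id)]
    dimnames(dmat) <- list(pm, pm)
    rpm <- relatednessMatrix(allg, freqs, est1, rows = pm)
    mt <- mantelTest(dmat, rpm, nPerm = nPerm,
                     seed = .stageSeed(seed, 22L))
    spatial <- list(deltaR = sweep, mantel = mt, estimator = est1)
  }
  ## --- game model and brood value --------------------------------------
  mc_obs <- randomization[randomization$pairing == "male_cuckolder" &
                          randomization$estimator == estimators[1L] &
                          randomization$statistic == "mean", "observed"]
  kept <- excludeZeroPaternity(broods)
  loss <- mean(1 - paternityFraction(kept))
  model <- list(
    decision = decisionMap(r = 0.25, f = 0.5, muD = 1,
                           muCGrid = seq(0.05, 10, length.out = decisionGrid),
                           aGrid = seq(0, 0.99, length.out = decisionGrid)),
    observedMeanR = mc_obs,
    meanPaternityLoss = loss,
    broodValuePct = broodValueIncrease(max(0, min(1, mc_obs)), loss))
  out <- list(freqs = freqs, sires = siresKept,
              randomization = randomization,
              parentOffspring = parentOffspring, spatial = spatial,
              model = model, counts = counts, seed = seed)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(randomization,
                     file.path(outDir, "randomization_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(parentOffspring,
                     file.path(outDir, "parent_offspring_tests.csv"),
                     row.names = FALSE)
    if (!is.null(spatial)) {
      utils::write.csv(spatial$deltaR,
                       file.path(outDir, "delta_r_sweep.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(model$decision,
                     file.path(outDir, "decision_map.csv"), row.names = FALSE)
    writeLines(c(sprintf("seed: %s", seed),
                 sprintf("%s: %s", names(counts), unlist(counts))),
               file.path(outDir, "run_manifest.txt"))
  }
  out
}
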
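## Synthetic-data generator.
##
## The defaults state the world the analyses assume: a 14-locus
## microsatellite panel with about 21 alleles per locus and mean expected
## heterozygosity 0.88; two sampling seasons with 32 and 38 broods; broods
## of a few tens of fry; a mean paternity loss of 44.9%; 1-5 cuckolder
## sires per cuckolded brood with mean about 1.95 and SD about 1.1; a rate
## of 6/70 zero-paternity broods; and a ~100 m x 50 m territory quadrat.

#' Synthetic-data configuration
#'
#' @param nLoci number of microsatellite loci.
#' @param allelesPerLocus target mean number of alleles per locus.
#' @param targetHet target mean expected heterozygosity across loci.
#' @param nPairs named integer vector: broods (= social pairs) per season.
#' @param fryPerBroodMean mean brood size (Poisson, truncated at 2).
#' @param cuckoldersPerBroodProbs probabilities of 1..5 cuckolder sires per
#'   cuckolded brood (moment-matched to mean 1.95, SD 1.1).
#' @param paternityLossShape Beta shape parameters of the per-brood
#'   paternity-loss fraction (defaults give mean 0.449).
#' @param zeroPaternityRate probability a brood is complete-takeover style
#'   (paternity 0), exercising the exclusion logic.
#' @param kinshipProb probability that one cuckolder of a brood is related
#'   to the paired male.
#' @param kinshipClass `"halfsib"` or `"fullsib"` for the injected relative.
#' @param quadrat quadrat dimensions in metres, c(width, height).
#' @param nUnpairedMales number of unpaired males for spatial scenarios.
#' @param errorRate optional per-allele genotyping error rate (an erroneous
#'   call is replaced by a random population allele; default 0).
#' @return named list of class `"SynthConfig"`.
#' @export
synthConfig <- function(nLoci = 14L,
                        allelesPerLocus = 21.2,
                        targetHet = 0.88,
                        nPairs = c(dry = 32L, rainy = 38L),
                        fryPerBroodMean = 28,
                        cuckoldersPerBroodProbs = c(0.45, 0.30, 0.13, 0.07,
                                                    0.05),
                        paternityLossShape = c(2.245, 2.755),
                        zeroPaternityRate = 6 / 70,
                        kinshipProb = 0,
                        kinshipClass = c("halfsib", "fullsib"),
                        quadrat = c(100, 50),
                        nUnpairedMales = 36L,
                        errorRate = 0) {
  kinshipClass <- match.arg(kinshipClass)
  stopifnot(nLoci >= 1, allelesPerLocus >= 2, targetHet > 0, targetHet < 1,
            all(nPairs >= 1), fryPerBroodMean > 0,
            abs(sum(cuckoldersPerBroodProbs) - 1) < 1e-9,
            all(cuckoldersPerBroodProbs >= 0),
            kinshipProb >= 0, kinshipProb <= 1,
            zeroPaternityRate >= 0, zeroPaternityRate <= 1,
            errorRate >= 0, errorRate <= 1)
  structure(list(nLoci = as.integer(nLoci),
                 allelesPerLocus = allelesPerLocus,
                 targetHet = targetHet, nPairs = nPairs,
                 fryPerBroodMean = fryPerBroodMean,
                 cuckoldersPerBroodProbs = cuckoldersPerBroodProbs,
                 paternityLossShape = paternityLossShape,
                 zeroPaternityRate = zeroPaternityRate,
                 kinshipProb = kinshipProb, kinshipClass = kinshipClass,
                 quadrat = quadrat,
                 nUnpairedMales = as.integer(nUnpairedMales),
                 errorRate = errorRate),
            class = "SynthConfig")
}

## symmetric-Dirichlet draw
.rdirichlet <- function(k, alpha) {
  g <- stats::rgamma(k, alpha)
  g / sum(g)
}

#' Generate a synthetic allele-frequency table
#'
#' Per-locus allele counts are drawn around the configured mean and
#' frequencies from a symmetric Dirichlet whose concentration is chosen so
#' the expected heterozygosity matches the target in expectation; if the
#' realized mean He falls outside target +/- tol, the frequencies are
#' power-rescaled (p^theta, renormalized) to hit the target.
#'
#' @param config a [synthConfig()] list.
#' @param seed optional integer seed.
#' @param tol acceptance band around the target He (default 0.02).
#' @return An [AlleleFreqTable-class].
#' @export
genAlleleFreqs <- function(config = synthConfig(), seed = NULL, tol = 0.02) {
  if (!is.null(seed)) set.seed(seed)
  nL <- config$nLoci
  he <- config$targetHet
  k <- pmax(2L, stats::rpois(nL, config$allelesPerLocus - 1) + 1L)
  if (mean(1 - 1 / k) < he - tol)
    stop("heterozygosity target unreachable with ", mean(k),
         " alleles per locus")
  freqs <- lapply(k, function(ki) {
    ## E[sum p^2] = (alpha + 1) / (k alpha + 1) for symmetric Dirichlet
    alpha <- if ((1 - he) * ki > 1) he / ((1 - he) * ki - 1) else 50
    p <- .rdirichlet(ki, alpha)
    stats::setNames(p, sprintf("%03d", seq_len(ki) * 2 + 100))
  })
  names(freqs) <- sprintf("L%02d", seq_len(nL))
  meanHe <- function(fl) mean(vapply(fl, function(p) 1 - sum(p^2), 0))
  if (abs(meanHe(freqs) - he) > tol) {
    resc <- function(theta) {
      lapply(freqs, function(p) {
        q <- p^theta
        q / sum(q)
      })
    }
    root <- stats::uniroot(function(th) meanHe(resc(th)) - he,
                           lower = 0.02, upper = 8, tol = 1e-6)
    freqs <- resc(root$root)
  }
  new("AlleleFreqTable", freqs = freqs, source = "pooled")
}

#' Draw Hardy-Weinberg genotypes from an allele-frequency table
#'
#' @param n number of individuals.
#' @param freqs an [AlleleFreqTable-class].
#' @param ids individual ids (default `ind1..indn`).
#' @param seed optional integer seed.
#' @return A [GenotypeSet-class].
#' @export
genGenotypes <- function(n, freqs, ids = paste0("ind", seq_len(n)),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- lociIds(freqs)
  a1 <- a2 <- matrix(NA_character_, n, length(loci),
                     dimnames = list(ids, loci))
  for (l in loci) {
    fl <- freqs@freqs[[l]]
    a1[, l] <- sample(names(fl), n, replace = TRUE, prob = fl)
    a2[, l] <- sample(names(fl), n, replace = TRUE, prob = fl)
  }
  GenotypeSet(a1, a2)
}

## Mendelian offspring: one random allele from each parent, vectorized over
## individuals; pa/pb are GenotypeSets with parallel rows
.mendelianCross <- function(pa, pb, ia, ib, ids) {
  loci <- lociIds(pa)
  n <- length(ia)
  pick <- function(g, idx) {
    from1 <- matrix(stats::runif(n * length(loci)) < 0.5, n)
    out <- ifelse(from1, g@allele1[idx, , drop = FALSE],
                  g@allele2[idx, , drop = FALSE])
    matrix(out, n, length(loci), dimnames = list(ids, loci))
  }
  GenotypeSet(pick(pa, ia), pick(pb, ib))
}

#' Generate dyads of known pedigree relatedness
#'
#' Founders are drawn allele-wise from the population frequencies
#' (Hardy-Weinberg); half sibs share one parent, full sibs two, and
#' parent-offspring dyads pair a founder with its own child. The pedigree
#' relatedness of the classes is 0, 0.25, 0.5, 0.5 respectively.
#'
#' @param n number of dyads.
#' @param class `"unrelated"`, `"halfsib"`, `"fullsib"`, or
#'   `"parentoffspring"`.
#' @param freqs an [AlleleFreqTable-class].
#' @param seed optional integer seed.
#' @param prefix id prefix.
#' @return list with [GenotypeSet-class]s `a` and `b` (row i of `a` and row
#'   i of `b` form dyad i).
#' @export
genDyads <- function(n, class = c("unrelated", "halfsib", "fullsib",
                                  "parentoffspring"),
                     freqs, seed = NULL, prefix = class) {
  class <- match.arg(class)
  if (!is.null(seed)) set.seed(seed)
  idsA <- paste0(prefix, "_a", seq_len(n))
  idsB <- paste0(prefix, "_b", seq_len(n))
  if (class == "unrelated") {
    return(list(a = genGenotypes(n, freqs, idsA),
                b = genGenotypes(n, freqs, idsB)))
  }
  P1 <- genGenotypes(n, freqs, paste0("p1_", seq_len(n)))
  P2 <- genGenotypes(n, freqs, paste0("p2_", seq_len(n)))
  if (class == "parentoffspring") {
    child <- .mendelianCross(P1, P2, seq_len(n), seq_len(n), idsB)
    a <- P1
    rownames(a@allele1) <- rownames(a@allele2) <- idsA
    return(list(a = a, b = child))
  }
  if (class == "fullsib") {
    return(list(a = .mendelianCross(P1, P2, seq_len(n), seq_len(n), idsA),
                b = .mendelianCross(P1, P2, seq_len(n), seq_len(n), idsB)))
  }
  ## half sibs: shared parent P1, distinct mates P2 and P3
  P3 <- genGenotypes(n, freqs, paste0("p3_", seq_len(n)))
  list(a = .mendelianCross(P1, P2, seq_len(n), seq_len(n), idsA),
       b = .mendelianCross(P1, P3, seq_len(n), seq_len(n), idsB))
}

#' Generate synthetic broods with known cuckolder sires
#'
#' For each season the configured number of social pairs is generated; each
#' brood draws a paternity-loss fraction (optionally forced to 1 at the
#' zero-paternity rate), a number of cuckolder sires, and Mendelian fry
#' genotypes. With probability `kinshipProb` the first cuckolder of a brood
#' is a half or full sib of the paired male. Extra-pair group labels
#' `EP_1..EP_g` are assigned contiguously to the cuckolders that actually
#' sired fry, and the truth table links each label to its true sire.
#'
#' @param config a [synthConfig()] list.
#' @param freqs an [AlleleFreqTable-class].
#' @param seed optional integer seed.
#' @return list: `genotypes` ([GenotypeSet-class] of all adults, cuckolders
#'   and fry), `broods` ([BroodSet-class]), `adults` (data.frame of id,
#'   role, season), `truth` (data.frame per EP group: `brood_id`,
#'   `ep_group`, `sire_id`, `kin_class`).
#' @export
genBroods <- function(config = synthConfig(), freqs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genos <- list()
  adults <- list()
  rows <- list()
  truth <- list()
  for (season in names(config$nPairs)) {
    nB <- config$nPairs[[season]]
    for (b in seq_len(nB)) {
      bid <- sprintf("B_%s_%02d", season, b)
      mom_id <- sprintf("F_%s_%02d", season, b)
      dad_id <- sprintf("M_%s_%02d", season, b)
      mom <- genGenotypes(1L, freqs, mom_id)
      nCk <- sample.int(5L, 1L, prob = config$cuckoldersPerBroodProbs)
      ck_ids <- sprintf("CK_%s_%02d_%d", season, b, seq_len(nCk))
      related <- stats::runif(1) < config$kinshipProb
      if (related) {
        dy <- genDyads(1L, if (config$kinshipClass == "halfsib") "halfsib"
                           else "fullsib", freqs)
        dad <- dy$a; ck1 <- dy$b
        rownames(dad@allele1) <- rownames(dad@allele2) <- dad_id
        rownames(ck1@allele1) <- rownames(ck1@allele2) <- ck_ids[1L]
        cks <- if (nCk > 1L)
          combineGenotypes(ck1, genGenotypes(nCk - 1L, freqs, ck_ids[-1L]))
        else ck1
      } else {
        dad <- genGenotypes(1L, freqs, dad_id)
        cks <- genGenotypes(nCk, freqs, ck_ids)
      }
      loss <- if (stats::runif(1) < config$zeroPaternityRate) 1
              else stats::rbeta(1, config$paternityLossShape[1L],
                                config$paternityLossShape[2L])
      nFry <- max(2L, stats::rpois(1L, config$fryPerBroodMean))
      sire_idx <- ifelse(stats::runif(nFry) < loss,
                         sample.int(nCk, nFry, replace = TRUE), 0L)
      fry_ids <- sprintf("%s_fry%02d", bid, seq_len(nFry))
      sires_all <- combineGenotypes(dad, cks)
      parents <- combineGenotypes(mom, sires_all)  # 1 = mom, 2 = dad, 3.. = cks
      fry <- .mendelianCross(parents, parents, rep(1L, nFry),
                             ifelse(sire_idx == 0L, 2L, sire_idx + 2L),
                             fry_ids)
      ## relabel EP groups contiguously over cuckolders that sired fry
      used <- sort(unique(sire_idx[sire_idx > 0L]))
      lab <- ifelse(sire_idx == 0L, "WITHIN_PAIR",
                    paste0("EP_", match(sire_idx, used)))
      rows[[bid]] <- data.frame(brood_id = bid, season = season,
                                mother_id = mom_id, paired_male_id = dad_id,
                                offspring_id = fry_ids, sire_label = lab,
                                stringsAsFactors = FALSE)
      if (length(used))
        truth[[bid]] <- data.frame(
          brood_id = bid, ep_group = paste0("EP_", seq_along(used)),
          sire_id = ck_ids[used],
          kin_class = ifelse(used == 1L & related, config$kinshipClass,
                             "unrelated"),
          stringsAsFactors = FALSE)
      genos[[bid]] <- combineGenotypes(combineGenotypes(mom, sires_all), fry)
      adults[[bid]] <- data.frame(
        individual_id = c(mom_id, dad_id, ck_ids),
        role = c("mother", "paired_male", rep("cuckolder", nCk)),
        season = season, stringsAsFactors = FALSE)
    }
  }
  all_g <- Reduce(combineGenotypes, genos)
  if (config$errorRate > 0) all_g <- .injectErrors(all_g, freqs,
                                                   config$errorRate)
  list(genotypes = all_g,
       broods = BroodSet(do.call(rbind, rows)),
       adults = do.call(rbind, c(adults, make.row.names = FALSE)),
       truth = if (length(truth)) do.call(rbind, c(truth,
                                                   make.row.names = FALSE))
               else NULL)
}

## optional per-allele genotyping error: replace with a random population
## allele (stress-tests reconstruction; default rate 0)
.injectErrors <- function(g, freqs, rate) {
  for (l in lociIds(g)) {
    fl <- freqs@freqs[[l]]
    n <- nrow(g@allele1)
    for (sl in c("allele1", "allele2")) {
      hit <- stats::runif(n) < rate
      if (any(hit))
        slot(g, sl)[hit, l] <- sample(names(fl), sum(hit), replace = TRUE,
                                      prob = fl)
    }
  }
  g
}

#' Generate a synthetic territory map
#'
#' Territories (one per paired male) are placed uniformly in the quadrat
#' with a minimum spacing; unpaired males are anchored either uniformly at
#' random (`placement = "uniform"`, the null scenario) or next to a
#' territory lying in a distance band around a designated related paired
#' male's territory (`placement = "band"`, planting a spatial kin signal).
#'
#' @param pairedMaleIds ids of the paired males holding territories.
#' @param unpairedMaleIds ids of the unpaired males to anchor.
#' @param config a [synthConfig()] list (quadrat dimensions).
#' @param placement `"uniform"` or `"band"`.
#' @param relatedTo for `"band"`: character vector naming, for each
#'   unpaired male, the paired male he should settle near.
#' @param band distance band in metres (default 4-6 m).
#' @param minSpacing minimum territory spacing in metres.
#' @param seed optional integer seed.
#' @return A [TerritoryMap-class].
#' @export
genTerritoryMap <- function(pairedMaleIds, unpairedMaleIds = character(0),
                            config = synthConfig(),
                            placement = c("uniform", "band"),
                            relatedTo = NULL, band = c(4, 6),
                            minSpacing = 2, seed = NULL) {
  placement <- match.arg(placement)
  if (!is.null(seed)) set.seed(seed)
  nT <- length(pairedMaleIds)
  xy <- matrix(NA_real_, nT, 2L)
  for (i in seq_len(nT)) {
    for (try in 1:200) {
      cand <- stats::runif(2) * config$quadrat
      if (i == 1L) break
      d <- sqrt(colSums((t(xy[seq_len(i - 1L), , drop = FALSE]) - cand)^2))
      if (min(d) >= minSpacing) break
    }
    xy[i, ] <- cand
  }
  tid <- sprintf("T%03d", seq_len(nT))
  tt <- data.frame(territory_id = tid, x_m = xy[, 1L], y_m = xy[, 2L],
                   paired_male_id = pairedMaleIds, stringsAsFactors = FALSE)
  if (length(unpairedMaleIds) == 0L)
    return(TerritoryMap(tt))
  if (placement == "uniform") {
    an <- data.frame(unpaired_male_id = unpairedMaleIds,
                     territory_id = sample(tid, length(unpairedMaleIds),
                                           replace = TRUE),
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(relatedTo) || length(relatedTo) != length(unpairedMaleIds))
      stop("placement = 'band' needs one relatedTo paired male per unpaired male")
    home <- match(relatedTo, pairedMaleIds)
    if (anyNA(home)) stop("relatedTo names unknown paired males")
    D <- as.matrix(stats::dist(xy))
    an_t <- vapply(home, function(h) {
      d <- D[h, ]
      inband <- which(d >= band[1L] & d <= band[2L])
      if (length(inband)) tid[sample(c(inband, inband), 1L)]
      else tid[which.min(abs(d - mean(band)) + (d == 0) * 1e6)]
    }, "")
    an <- data.frame(unpaired_male_id = unpairedMaleIds, territory_id = an_t,
                     stringsAsFactors = FALSE)
  }
  TerritoryMap(tt, an)
}
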
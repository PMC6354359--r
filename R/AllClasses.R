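#' @import methods
NULL

#' GenotypeSet: diploid multilocus genotypes with explicit unknowns
#'
#' Stores codominant (e.g. microsatellite) genotypes for a set of
#' individuals as two parallel character matrices, one per allele copy,
#' with individuals in rows and loci in columns. Allele labels are opaque
#' strings; `NA` encodes an unknown allele. The allele pair at a locus is
#' unordered: (X,Y) and (Y,X) are the same genotype.
#'
#' @slot allele1 character matrix (individuals x loci), first allele copy.
#' @slot allele2 character matrix of identical shape, second allele copy.
#'
#' @seealso [GenotypeSet()], [readGenotypeTable()], [nLociComplete()]
#' @export
setClass("GenotypeSet",
  representation(allele1 = "matrix", allele2 = "matrix"))

setValidity("GenotypeSet", function(object) {
  a1 <- object@allele1
  a2 <- object@allele2
  if (!is.character(a1) || !is.character(a2))
    return("allele matrices must be character matrices")
  if (!identical(dim(a1), dim(a2)))
    return("allele1 and allele2 must have identical dimensions")
  if ((nrow(a1) > 0L && is.null(rownames(a1))) ||
      (ncol(a1) > 0L && is.null(colnames(a1))))
    return("allele matrices must carry individual (row) and locus (column) names")
  if (!identical(dimnames(a1), dimnames(a2)))
    return("allele1 and allele2 must have identical dimnames")
  if (anyDuplicated(rownames(a1)))
    return(paste0("duplicate individual id: ",
                  rownames(a1)[duplicated(rownames(a1))][1L]))
  if (anyDuplicated(colnames(a1)))
    return("duplicate locus id")
  TRUE
})

#' AlleleFreqTable: per-locus population allele frequencies
#'
#' @slot freqs named list, one element per locus: a named numeric vector
#'   mapping allele label to relative frequency. Frequencies at each locus
#'   sum to 1 within 1e-9.
#' @slot source character, `"pooled"` or `"per_season"` (bookkeeping only).
#'
#' @seealso [computeAlleleFreqs()], [expectedHet()]
#' @export
setClass("AlleleFreqTable",
  representation(freqs = "list", source = "character"))

setValidity("AlleleFreqTable", function(object) {
  if (length(object@freqs) == 0L) return("no loci")
  if (is.null(names(object@freqs)) || anyDuplicated(names(object@freqs)))
    return("freqs must be a uniquely named list (one element per locus)")
  for (l in names(object@freqs)) {
    f <- object@freqs[[l]]
    if (!is.numeric(f) || is.null(names(f)))
      return(sprintf("locus %s: frequencies must be a named numeric vector", l))
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
      return(sprintf("locus %s: frequencies must be nonnegative and sum to 1", l))
  }
  if (!object@source %in% c("pooled", "per_season"))
    return("source must be 'pooled' or 'per_season'")
  TRUE
})

#' BroodSet: brood records in long format
#'
#' One row per offspring, linking it to its brood, season, mother, the
#' socially paired male, and a sire label: `"WITHIN_PAIR"` for offspring
#' sired by the paired male, or an extra-pair full-sib group id of the form
#' `"EP_<k>"` identifying one cuckolder sire within the brood. Sibship
#' inference is assumed done upstream; labels are inputs.
#'
#' @slot table data.frame with columns `brood_id`, `season`, `mother_id`,
#'   `paired_male_id`, `offspring_id`, `sire_label`.
#'
#' @seealso [readBroodTable()], [paternityFraction()], [excludeZeroPaternity()]
#' @export
setClass("BroodSet", representation(table = "data.frame"))

setValidity("BroodSet", function(object) {
  tab <- object@table
  need <- c("brood_id", "season", "mother_id", "paired_male_id",
            "offspring_id", "sire_label")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    return(paste("missing brood table columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(tab$offspring_id))
    return("duplicate offspring_id in brood table")
  bad <- !(tab$sire_label == "WITHIN_PAIR" | grepl("^EP_", tab$sire_label))
  if (any(bad))
    return(sprintf("invalid sire_label '%s' (expect WITHIN_PAIR or EP_<k>)",
                   tab$sire_label[bad][1L]))
  # a brood must have a single season/mother/paired male
  for (col in c("season", "mother_id", "paired_male_id")) {
    n <- tapply(tab[[col]], tab$brood_id, function(x) length(unique(x)))
    if (any(n > 1L))
      return(sprintf("brood %s has inconsistent %s",
                     names(n)[n > 1L][1L], col))
  }
  TRUE
})

#' TerritoryMap: territory coordinates, occupancy, and unpaired-male anchors
#'
#' Territory coordinates are 2-D, in metres. Each unpaired male is anchored
#' to the territory next to which he was captured; anchors stand in for the
#' male's own position in spatial analyses.
#'
#' @slot territories data.frame with columns `territory_id`, `x_m`, `y_m`,
#'   `paired_male_id` (NA when the holder was not genotyped/captured).
#' @slot anchors data.frame with columns `unpaired_male_id`, `territory_id`.
#'
#' @seealso [readTerritoryMap()], [deltaR()], [deltaRSweep()]
#' @export
setClass("TerritoryMap",
  representation(territories = "data.frame", anchors = "data.frame"))

setValidity("TerritoryMap", function(object) {
  tt <- object@territories
  an <- object@anchors
  need <- c("territory_id", "x_m", "y_m", "paired_male_id")
  if (length(setdiff(need, names(tt))))
    return("territories needs columns territory_id, x_m, y_m, paired_male_id")
  if (length(setdiff(c("unpaired_male_id", "territory_id"), names(an))))
    return("anchors needs columns unpaired_male_id, territory_id")
  if (anyDuplicated(tt$territory_id)) return("duplicate territory_id")
  if (!all(is.finite(tt$x_m)) || !all(is.finite(tt$y_m)))
    return("territory coordinates must be finite")
  if (nrow(an)) {
    if (anyDuplicated(an$unpaired_male_id))
      return("an unpaired male may have only one anchor territory")
    bad <- !an$territory_id %in% tt$territory_id
    if (any(bad))
      return(sprintf("anchor references unknown territory '%s'",
                     an$territory_id[bad][1L]))
  }
  TRUE
})

#' GameParams: parameters of the cuckoldry-tolerance game
#'
#' @slot r relatedness coefficient between the paired male and his single
#'   related potential cuckolder, in \[0, 1\].
#' @slot f probability that the related cuckolder attempts to cuckold at a
#'   given spawning event, in \[0, 1\].
#' @slot muC mean number of unrelated potential cuckolders per spawning
#'   event (Poisson mean), >= 0.
#' @slot muD mean number of cuckolders the paired male can drive off
#'   (Poisson mean), >= 0.
#' @slot a cost of discriminate defense: a discriminating male's defense
#'   mean is reduced to (1 - a) * muD; 0 <= a < 1.
#'
#' @seealso [GameParams()], [pairedMaleFitness()], [cuckolderFitness()]
#' @export
setClass("GameParams",
  representation(r = "numeric", f = "numeric", muC = "numeric",
                 muD = "numeric", a = "numeric"))

setValidity("GameParams", function(object) {
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@r) || object@r < 0 || object@r > 1)
    return("r must be a single value in [0, 1]")
  if (!one(object@f) || object@f < 0 || object@f > 1)
    return("f must be a single value in [0, 1]")
  if (!one(object@muC) || object@muC < 0) return("muC must be >= 0")
  if (!one(object@muD) || object@muD < 0) return("muD must be >= 0")
  if (!one(object@a) || object@a < 0 || object@a >= 1)
    return("a must satisfy 0 <= a < 1")
  TRUE
})

#' SireReconstruction: reconstructed cuckolder genotypes plus bookkeeping
#'
#' @slot genotypes [GenotypeSet] of reconstructed sires (unknown alleles as NA).
#' @slot info data.frame with one row per sire: `sire_id`, `brood_id`,
#'   `ep_group`, `n_fry`, `n_loci_complete`, `n_loci_inconsistent`.
#'
#' @seealso [reconstructSire()], [reconstructBroodSires()], [filterReconstructed()]
#' @export
setClass("SireReconstruction",
  representation(genotypes = "GenotypeSet", info = "data.frame"))

setValidity("SireReconstruction", function(object) {
  need <- c("sire_id", "brood_id", "ep_group", "n_fry", "n_loci_complete",
            "n_loci_inconsistent")
  if (length(setdiff(need, names(object@info))))
    return(paste("info needs columns", paste(need, collapse = ", ")))
  ids <- rownames(object@genotypes@allele1)
  if (is.null(ids)) ids <- character(0)
  if (!identical(ids, as.character(object@info$sire_id)))
    return("info rows must match genotype individuals (sire_id order)")
  TRUE
})
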
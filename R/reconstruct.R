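## Reconstruction of cuckolder (extra-pair sire) genotypes from the
## mother's genotype and one extra-pair full-sib group.
##
## Per locus, each fry's paternal allele is the allele left after removing
## one copy of a maternal allele from the fry genotype. When the fry is
## heterozygous with the same two alleles as a heterozygous mother, either
## allele could be paternal (an ambiguous pair). Ambiguities are resolved
## first by the other fry in the group, then by population allele
## frequency; a frequency difference below 1 percentage point leaves the
## allele unknown. A single determined paternal allele X is called X/X when
## the group has at least 8 fry, else X/unknown.

## Paternal-allele extraction for one fry at one locus.
## Returns list(kind = "det"|"amb"|"none"|"bad", alleles)
.paternalAllele <- function(m1, m2, f1, f2) {
  if (is.na(f1) || is.na(f2)) return(list(kind = "none"))
  f1m <- f1 %in% c(m1, m2)
  f2m <- f2 %in% c(m1, m2)
  if (!f1m && !f2m) return(list(kind = "bad"))
  if (f1m && !f2m) return(list(kind = "det", alleles = f2))
  if (!f1m && f2m) return(list(kind = "det", alleles = f1))
  ## both fry alleles are attributable to the mother
  if (f1 == f2)                       # homozygous fry: paternal = that allele
    return(list(kind = "det", alleles = f1))
  if (m1 != m2 && setequal(c(f1, f2), c(m1, m2)))
    return(list(kind = "amb", alleles = c(f1, f2)))  # het fry == het mother
  ## het fry, both alleles maternal, mother homozygous is impossible here;
  ## remaining case: mother het sharing both alleles with fry is the setequal
  ## branch, so anything left means one allele matches each maternal copy
  ## without being the same unordered pair -- treat as ambiguous
  list(kind = "amb", alleles = c(f1, f2))
}

## frequency tie-break: higher-frequency allele, unknown when the absolute
## difference is below `tie` (the "< 1%" rule)
.freqResolve <- function(alleles, fl, tie = 0.01) {
  p <- fl[alleles]
  p[is.na(p)] <- 0
  if (abs(p[1L] - p[2L]) < tie) return(NA_character_)
  alleles[which.max(p)]
}

#' Reconstruct a cuckolder genotype from mother and extra-pair full sibs
#'
#' @param x a [GenotypeSet-class] holding the mother and all fry.
#' @param motherId the mother's individual id.
#' @param fryIds ids of the extra-pair full-sib group sired by the unknown
#'   cuckolder (at least one).
#' @param freqs an [AlleleFreqTable-class] used for ambiguity tie-breaking.
#' @param sireId id to assign to the reconstructed genotype.
#' @param homozygoteMinFry group size from which a single observed paternal
#'   allele is called homozygous rather than allele/unknown (default 8).
#' @param freqTie frequency-difference threshold below which an ambiguous
#'   paternal allele is left unknown (default 0.01).
#' @details Per locus: two distinct determined paternal alleles give a
#'   heterozygous call; more than two flags the locus inconsistent
#'   (an upstream sibship error) and sets it unknown/unknown; a locus where
#'   the mother's genotype is not fully known cannot have maternal alleles
#'   subtracted and is left unknown/unknown (a conservative rule mirroring
#'   the unambiguity requirement). Fry that are
#'   Mendelian-incompatible with the mother raise an error naming fry and
#'   locus.
#' @return list with `genotype` (single-row [GenotypeSet-class]), `nFry`,
#'   `nLociComplete`, and `inconsistentLoci` (character vector of flagged
#'   loci).
#' @export
reconstructSire <- function(x, motherId, fryIds, freqs,
                            sireId = paste0(motherId, "_EP"),
                            homozygoteMinFry = 8L, freqTie = 0.01) {
  if (length(fryIds) == 0L) stop("empty fry list")
  ids <- individualIds(x)
  mi <- match(motherId, ids)
  fi <- match(fryIds, ids)
  if (is.na(mi)) stop("unknown mother id: ", motherId)
  if (anyNA(fi)) stop("unknown fry id: ", fryIds[is.na(fi)][1L])
  loci <- lociIds(x)
  n_fry <- length(fryIds)
  s1 <- s2 <- stats::setNames(rep(NA_character_, length(loci)), loci)
  inconsistent <- character(0)
  for (l in loci) {
    m1 <- x@allele1[mi, l]; m2 <- x@allele2[mi, l]
    ## any maternal unknown: the maternal allele cannot be subtracted
    ## unambiguously, so the sire is left unknown at this locus
    if (is.na(m1) || is.na(m2)) next
    det <- character(0)
    amb <- list()
    for (k in seq_len(n_fry)) {
      pa <- .paternalAllele(m1, m2, x@allele1[fi[k], l], x@allele2[fi[k], l])
      if (pa$kind == "bad")
        stop(sprintf("fry %s incompatible with mother %s at locus %s",
                     fryIds[k], motherId, l))
      if (pa$kind == "det") det <- union(det, pa$alleles)
      if (pa$kind == "amb") amb <- c(amb, list(pa$alleles))
    }
    ## resolve ambiguous fry against the determined set
    unresolved <- Filter(function(a) !any(a %in% det), amb)
    if (length(det) > 2L) {             # sib-group error: flag, set unknown
      inconsistent <- c(inconsistent, l)
      next
    }
    if (length(det) == 2L) {
      s1[l] <- det[1L]; s2[l] <- det[2L]
      next
    }
    fl <- freqs@freqs[[l]]
    if (length(det) == 1L) {
      if (length(unresolved)) {
        ## the sire provably carries det plus one of the ambiguous pair
        second <- .freqResolve(unresolved[[1L]], fl, freqTie)
        s1[l] <- det; s2[l] <- second
      } else {
        s1[l] <- det
        s2[l] <- if (n_fry >= homozygoteMinFry) det else NA_character_
      }
      next
    }
    ## no determined allele: all informative fry were ambiguous
    if (length(unresolved)) {
      one <- .freqResolve(unresolved[[1L]], fl, freqTie)
      if (!is.na(one)) {
        s1[l] <- one
        s2[l] <- if (n_fry >= homozygoteMinFry) one else NA_character_
      }
    }
  }
  a1 <- matrix(s1, 1L, dimnames = list(sireId, loci))
  a2 <- matrix(s2, 1L, dimnames = list(sireId, loci))
  g <- GenotypeSet(a1, a2)
  list(genotype = g, nFry = n_fry,
       nLociComplete = unname(nLociComplete(g)),
       inconsistentLoci = inconsistent)
}

#' Reconstruct all cuckolder genotypes of a brood set
#'
#' Applies [reconstructSire()] to every extra-pair full-sib group.
#'
#' @param x a [GenotypeSet-class] with mothers and offspring.
#' @param broods a [BroodSet-class].
#' @param freqs an [AlleleFreqTable-class].
#' @param ... passed to [reconstructSire()].
#' @return A [SireReconstruction-class]; sire ids are
#'   `"<brood_id>_<ep_group>"`.
#' @export
reconstructBroodSires <- function(x, broods, freqs, ...) {
  gr <- epGroups(broods)
  loci <- lociIds(x)
  if (nrow(gr) == 0L) {
    empty <- matrix(NA_character_, 0L, length(loci),
                    dimnames = list(character(0), loci))
    return(new("SireReconstruction", genotypes = GenotypeSet(empty, empty),
               info = data.frame(sire_id = character(0),
                                 brood_id = character(0),
                                 ep_group = character(0), n_fry = integer(0),
                                 n_loci_complete = integer(0),
                                 n_loci_inconsistent = integer(0))))
  }
  recs <- lapply(seq_len(nrow(gr)), function(i) {
    reconstructSire(x, gr$mother_id[i], gr$offspring_ids[[i]], freqs,
                    sireId = paste(gr$brood_id[i], gr$ep_group[i], sep = "_"),
                    ...)
  })
  a1 <- do.call(rbind, lapply(recs, function(r) r$genotype@allele1))
  a2 <- do.call(rbind, lapply(recs, function(r) r$genotype@allele2))
  info <- data.frame(
    sire_id = rownames(a1),
    brood_id = gr$brood_id,
    ep_group = gr$ep_group,
    n_fry = gr$n_fry,
    n_loci_complete = vapply(recs, `[[`, 0L, "nLociComplete"),
    n_loci_inconsistent = vapply(recs, function(r)
      length(r$inconsistentLoci), 0L),
    stringsAsFactors = FALSE)
  rownames(info) <- NULL
  new("SireReconstruction", genotypes = GenotypeSet(a1, a2), info = info)
}

#' Accessors for SireReconstruction
#'
#' @param x a [SireReconstruction-class].
#' @name SireReconstruction-accessors
#' @aliases sireGenotypes sireInfo
NULL

#' @rdname SireReconstruction-accessors
#' @export
setMethod("sireGenotypes", "SireReconstruction", function(x) x@genotypes)

#' @rdname SireReconstruction-accessors
#' @export
setMethod("sireInfo", "SireReconstruction", function(x) x@info)

#' @export
setMethod("show", "SireReconstruction", function(object) {
  cat(sprintf("SireReconstruction: %d reconstructed sires, median %s complete loci\n",
              nrow(object@info),
              if (nrow(object@info)) stats::median(object@info$n_loci_complete)
              else NA))
})

#' Keep only well-reconstructed cuckolders
#'
#' Retains sires for which both alleles were unambiguously identified at a
#' minimum number of loci (default 10, matching a 14-locus panel).
#'
#' @param x a [SireReconstruction-class].
#' @param minCompleteLoci retention threshold on complete loci.
#' @return A filtered [SireReconstruction-class]; retention is reported via
#'   a message.
#' @export
filterReconstructed <- function(x, minCompleteLoci = 10L) {
  stopifnot(is(x, "SireReconstruction"))
  keep <- x@info$n_loci_complete >= minCompleteLoci
  message(sum(keep), " of ", length(keep), " reconstructed sires retained (>= ",
          minCompleteLoci, " complete loci)")
  new("SireReconstruction",
      genotypes = x@genotypes[which(keep), ],
      info = x@info[keep, , drop = FALSE])
}
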
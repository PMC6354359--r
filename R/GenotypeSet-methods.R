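#' Construct a GenotypeSet
#'
#' @param allele1,allele2 character matrices (individuals x loci) holding the
#'   two allele copies per locus; `NA` marks an unknown allele. Row names are
#'   individual ids, column names locus ids.
#' @return A [GenotypeSet-class] object.
#' @examples
#' a1 <- matrix(c("120", "124"), 2, 1,
#'              dimnames = list(c("M1", "M2"), "L1"))
#' a2 <- matrix(c("124", NA), 2, 1, dimnames = dimnames(a1))
#' gs <- GenotypeSet(a1, a2)
#' nLociComplete(gs)
#' @export
GenotypeSet <- function(allele1, allele2) {
  storage.mode(allele1) <- "character"
  storage.mode(allele2) <- "character"
  new("GenotypeSet", allele1 = allele1, allele2 = allele2)
}

#' Accessors for GenotypeSet
#'
#' `individualIds()` and `lociIds()` return the row/column identifiers;
#' `nLociComplete()` counts, per individual, the loci at which both alleles
#' are named (non-missing).
#'
#' @param x A [GenotypeSet-class].
#' @name GenotypeSet-accessors
#' @aliases individualIds lociIds nLociComplete
NULL

#' @rdname GenotypeSet-accessors
#' @export
setMethod("individualIds", "GenotypeSet", function(x) {
  ids <- rownames(x@allele1)
  if (is.null(ids)) character(0) else ids
})

#' @rdname GenotypeSet-accessors
#' @export
setMethod("lociIds", "GenotypeSet", function(x) colnames(x@allele1))

#' @rdname GenotypeSet-accessors
#' @export
setMethod("nLociComplete", "GenotypeSet", function(x) {
  cnt <- rowSums(!is.na(x@allele1) & !is.na(x@allele2))
  stats::setNames(as.integer(cnt), rownames(x@allele1))
})

#' @export
setMethod("show", "GenotypeSet", function(object) {
  cat(sprintf("GenotypeSet: %d individuals x %d loci\n",
              nrow(object@allele1), ncol(object@allele1)))
  nc <- nLociComplete(object)
  cat(sprintf("  complete loci per individual: median %s (range %s-%s)\n",
              stats::median(nc), min(nc), max(nc)))
})

#' @export
setMethod("[", "GenotypeSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@allele1))
  if (missing(j)) j <- seq_len(ncol(x@allele1))
  GenotypeSet(x@allele1[i, j, drop = FALSE], x@allele2[i, j, drop = FALSE])
})

#' Combine two GenotypeSets over the same loci
#'
#' @param x,y [GenotypeSet-class] objects with identical locus sets.
#' @return A [GenotypeSet-class] with the individuals of both.
#' @export
combineGenotypes <- function(x, y) {
  stopifnot(is(x, "GenotypeSet"), is(y, "GenotypeSet"))
  if (!identical(lociIds(x), lociIds(y)))
    stop("GenotypeSets cover different loci")
  GenotypeSet(rbind(x@allele1, y@allele1), rbind(x@allele2, y@allele2))
}

## ---- I/O --------------------------------------------------------------

#' Read and write genotype tables
#'
#' Reads a delimited text table with one row per individual and either one
#' `"X/Y"`-encoded column per locus or two columns per locus (suffixes `.1`
#' and `.2`). The first column holds individual ids; a header row is
#' mandatory. Missing alleles are encoded by `na` (default `"NA"`).
#' Allele labels are opaque strings: microsatellite fragment lengths are
#' not interpreted numerically.
#'
#' @param path file path of a comma- or tab-delimited table.
#' @param sep field separator; default `","`, use `"\t"` for TSV.
#' @param na missing-allele sentinel string.
#' @return `readGenotypeTable()` returns a [GenotypeSet-class];
#'   `writeGenotypeTable()` writes the `"X/Y"` dialect and returns `path`
#'   invisibly. The round trip preserves all calls including unknowns.
#' @export
readGenotypeTable <- function(path, sep = ",", na = "NA") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), strip.white = TRUE)
  if (nrow(tab) == 0L) {
    warning("empty genotype table: ", path)
    loci <- unique(sub("\\.[12]$", "", names(tab)[-1L]))
    empty <- matrix(NA_character_, 0L, length(loci),
                    dimnames = list(character(0), loci))
    return(GenotypeSet(empty, empty))
  }
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate individual id: ", ids[duplicated(ids)][1L])
  body <- tab[, -1L, drop = FALSE]
  two_col <- all(grepl("\\.[12]$", names(body)))
  if (two_col) {
    loci <- unique(sub("\\.[12]$", "", names(body)))
    a1 <- as.matrix(body[paste0(loci, ".1")])
    a2 <- as.matrix(body[paste0(loci, ".2")])
    colnames(a1) <- colnames(a2) <- loci
  } else {
    loci <- names(body)
    a1 <- a2 <- matrix(NA_character_, nrow(tab), length(loci))
    for (j in seq_along(loci)) {
      cell <- body[[j]]
      parts <- strsplit(cell, "/", fixed = TRUE)
      bad <- lengths(parts) != 2L
      if (any(bad))
        stop(sprintf("malformed genotype '%s' at row %d, locus %s",
                     cell[bad][1L], which(bad)[1L], loci[j]))
      a1[, j] <- vapply(parts, `[`, "", 1L)
      a2[, j] <- vapply(parts, `[`, "", 2L)
    }
    colnames(a1) <- colnames(a2) <- loci
  }
  a1[a1 == na] <- NA
  a2[a2 == na] <- NA
  rownames(a1) <- rownames(a2) <- ids
  GenotypeSet(a1, a2)
}

#' @rdname readGenotypeTable
#' @param x a [GenotypeSet-class] to write.
#' @param id_col name of the individual-id column in the output.
#' @export
writeGenotypeTable <- function(x, path, sep = ",", na = "NA",
                               id_col = "individual_id") {
  a1 <- x@allele1; a2 <- x@allele2
  a1[is.na(a1)] <- na
  a2[is.na(a2)] <- na
  cells <- matrix(paste(a1, a2, sep = "/"), nrow(a1),
                  dimnames = dimnames(a1))
  out <- data.frame(rownames(cells), cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1L] <- id_col
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- allele frequencies ----------------------------------------------

#' Population allele frequencies from a reference set of adults
#'
#' Frequency of allele a at locus l is its count among named (non-missing)
#' calls at l divided by the total named calls at l. Unknown alleles are
#' skipped, not imputed; the number skipped is reported via a message.
#'
#' @param reference a [GenotypeSet-class] of reference individuals
#'   (typically the adults captured in the field).
#' @param source label stored on the table: `"pooled"` (default) or
#'   `"per_season"`; stratified tables are built by subsetting the
#'   reference before the call.
#' @return An [AlleleFreqTable-class].
#' @examples
#' gs <- GenotypeSet(
#'   matrix(c("A", "A"), 2, 1, dimnames = list(c("i1", "i2"), "L1")),
#'   matrix(c("A", "B"), 2, 1, dimnames = list(c("i1", "i2"), "L1")))
#' alleleFreqs(computeAlleleFreqs(gs), "L1")  # A: 0.75, B: 0.25
#' @export
computeAlleleFreqs <- function(reference, source = c("pooled", "per_season")) {
  source <- match.arg(source)
  loci <- lociIds(reference)
  n_skipped <- 0L
  freqs <- lapply(seq_along(loci), function(j) {
    calls <- c(reference@allele1[, j], reference@allele2[, j])
    n_skipped <<- n_skipped + sum(is.na(calls))
    calls <- calls[!is.na(calls)]
    if (length(calls) == 0L)
      stop("no named allele calls at locus ", loci[j])
    tab <- table(calls)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(freqs) <- loci
  if (n_skipped > 0L)
    message(n_skipped, " unknown allele calls skipped in frequency estimation")
  new("AlleleFreqTable", freqs = freqs, source = source)
}

#' Accessors for AlleleFreqTable
#'
#' @param x an [AlleleFreqTable-class].
#' @param locus a locus id.
#' @name AlleleFreqTable-accessors
#' @aliases alleleFreqs
NULL

#' @rdname AlleleFreqTable-accessors
#' @export
setMethod("alleleFreqs", "AlleleFreqTable", function(x, locus) {
  if (!locus %in% names(x@freqs)) stop("unknown locus: ", locus)
  x@freqs[[locus]]
})

#' @rdname AlleleFreqTable-accessors
#' @export
setMethod("lociIds", "AlleleFreqTable", function(x) names(x@freqs))

#' @export
setMethod("show", "AlleleFreqTable", function(object) {
  k <- lengths(object@freqs)
  cat(sprintf("AlleleFreqTable (%s): %d loci, %.1f alleles/locus, mean He %.3f\n",
              object@source, length(k), mean(k), mean(expectedHet(object))))
})

#' Expected heterozygosity per locus
#'
#' He = 1 - sum(p^2) over the allele frequencies p at a locus; the standard
#' marker-polymorphism summary.
#'
#' @param x an [AlleleFreqTable-class].
#' @return named numeric vector of per-locus expected heterozygosities.
#' @export
setMethod("expectedHet", "AlleleFreqTable", function(x) {
  vapply(x@freqs, function(f) 1 - sum(f^2), numeric(1))
})

## ---- Mendelian validation --------------------------------------------

#' Mendelian compatibility of a mother-offspring pair
#'
#' A locus is flagged compatible iff the offspring shares at least one named
#' allele with the mother, or either side carries an unknown allele there
#' (unknowns cannot be contradicted).
#'
#' @param mother,offspring single-individual [GenotypeSet-class] objects
#'   (or larger sets with `mother_id`/`offspring_id` given).
#' @param mother_id,offspring_id ids selecting one individual from each set;
#'   default the first.
#' @return data.frame with columns `locus` and `compatible` (logical).
#' @export
validateMendelian <- function(mother, offspring,
                              mother_id = individualIds(mother)[1L],
                              offspring_id = individualIds(offspring)[1L]) {
  loci <- intersect(lociIds(mother), lociIds(offspring))
  if (length(loci) == 0L) stop("no shared loci between mother and offspring")
  mi <- match(mother_id, individualIds(mother))
  oi <- match(offspring_id, individualIds(offspring))
  if (is.na(mi)) stop("unknown mother id: ", mother_id)
  if (is.na(oi)) stop("unknown offspring id: ", offspring_id)
  m1 <- mother@allele1[mi, loci]; m2 <- mother@allele2[mi, loci]
  o1 <- offspring@allele1[oi, loci]; o2 <- offspring@allele2[oi, loci]
  any_na <- is.na(m1) | is.na(m2) | is.na(o1) | is.na(o2)
  share <- (!is.na(o1) & (o1 == m1 | o1 == m2)) |
           (!is.na(o2) & (o2 == m1 | o2 == m2))
  share[is.na(share)] <- FALSE
  data.frame(locus = loci, compatible = any_na | share, row.names = NULL)
}
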
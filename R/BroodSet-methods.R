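#' Construct a BroodSet
#'
#' @param table data.frame with one row per offspring and columns
#'   `brood_id`, `season`, `mother_id`, `paired_male_id`, `offspring_id`,
#'   `sire_label` (`"WITHIN_PAIR"` or `"EP_<k>"`).
#' @return A [BroodSet-class].
#' @export
BroodSet <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  for (col in names(table))
    if (is.factor(table[[col]])) table[[col]] <- as.character(table[[col]])
  new("BroodSet", table = table)
}

#' Accessors for BroodSet
#'
#' `broodTable()` returns the long-format table; `broodIds()` the brood
#' identifiers; `paternityFraction()` the fraction of each brood's offspring
#' sired by the paired male (number of `WITHIN_PAIR` offspring over brood
#' size).
#'
#' @param x a [BroodSet-class].
#' @name BroodSet-accessors
#' @aliases broodTable broodIds paternityFraction
NULL

#' @rdname BroodSet-accessors
#' @export
setMethod("broodTable", "BroodSet", function(x) x@table)

#' @rdname BroodSet-accessors
#' @export
setMethod("broodIds", "BroodSet", function(x) unique(x@table$brood_id))

#' @rdname BroodSet-accessors
#' @export
setMethod("paternityFraction", "BroodSet", function(x) {
  wp <- tapply(x@table$sire_label == "WITHIN_PAIR", x@table$brood_id, mean)
  frac <- as.numeric(wp)
  stats::setNames(frac, names(wp))[broodIds(x)]
})

#' @export
setMethod("show", "BroodSet", function(object) {
  tab <- object@table
  cat(sprintf("BroodSet: %d broods, %d offspring (%d within-pair, %d extra-pair)\n",
              length(unique(tab$brood_id)), nrow(tab),
              sum(tab$sire_label == "WITHIN_PAIR"),
              sum(tab$sire_label != "WITHIN_PAIR")))
})

#' Read a brood table from CSV
#'
#' @param path CSV with columns `brood_id`, `season`, `mother_id`,
#'   `paired_male_id`, `offspring_id`, `sire_label`.
#' @param sep field separator.
#' @return A [BroodSet-class].
#' @export
readBroodTable <- function(path, sep = ",") {
  BroodSet(utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character", strip.white = TRUE))
}

#' Extra-pair full-sib groups of a BroodSet
#'
#' @param x a [BroodSet-class].
#' @return data.frame with one row per (brood, EP group): `brood_id`,
#'   `ep_group`, `mother_id`, `season`, `n_fry`, and a list-column
#'   `offspring_ids`.
#' @export
epGroups <- function(x) {
  stopifnot(is(x, "BroodSet"))
  tab <- x@table[x@table$sire_label != "WITHIN_PAIR", , drop = FALSE]
  if (nrow(tab) == 0L)
    return(data.frame(brood_id = character(0), ep_group = character(0),
                      mother_id = character(0), season = character(0),
                      n_fry = integer(0)))
  key <- paste(tab$brood_id, tab$sire_label, sep = "\r")
  idx <- split(seq_len(nrow(tab)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(brood_id = tab$brood_id[i[1L]],
               ep_group = tab$sire_label[i[1L]],
               mother_id = tab$mother_id[i[1L]],
               season = tab$season[i[1L]],
               n_fry = length(i), stringsAsFactors = FALSE)
  }))
  out$offspring_ids <- lapply(idx, function(i) tab$offspring_id[i])
  rownames(out) <- NULL
  out[order(out$brood_id, out$ep_group), , drop = FALSE]
}

#' Exclude broods in which the paired male had zero paternity
#'
#' Broods with a paternity fraction of exactly 0 are ambiguous between
#' complete cuckoldry and a territory takeover, so they are dropped from
#' cuckolder-relatedness analyses.
#'
#' @param x a [BroodSet-class].
#' @return A [BroodSet-class] without the zero-paternity broods; the number
#'   removed is reported via a message.
#' @export
excludeZeroPaternity <- function(x) {
  stopifnot(is(x, "BroodSet"))
  frac <- paternityFraction(x)
  drop <- names(frac)[frac == 0]
  if (length(drop))
    message(length(drop), " zero-paternity broods excluded of ", length(frac))
  BroodSet(x@table[!x@table$brood_id %in% drop, , drop = FALSE])
}
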
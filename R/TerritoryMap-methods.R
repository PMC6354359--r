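#' Construct a TerritoryMap
#'
#' @param territories data.frame with columns `territory_id`, `x_m`, `y_m`,
#'   `paired_male_id` (coordinates in metres; `paired_male_id` may be NA).
#' @param anchors data.frame with columns `unpaired_male_id`,
#'   `territory_id`: the territory each unpaired male was captured next to.
#' @return A [TerritoryMap-class].
#' @export
TerritoryMap <- function(territories,
                         anchors = data.frame(unpaired_male_id = character(0),
                                              territory_id = character(0))) {
  territories <- as.data.frame(territories, stringsAsFactors = FALSE)
  anchors <- as.data.frame(anchors, stringsAsFactors = FALSE)
  territories$x_m <- as.numeric(territories$x_m)
  territories$y_m <- as.numeric(territories$y_m)
  new("TerritoryMap", territories = territories, anchors = anchors)
}

#' Accessors for TerritoryMap
#'
#' `territories()` and `anchors()` return the underlying tables;
#' `anchorCounts()` tabulates how many unpaired males were captured next to
#' each territory (zero included), which drives the capacity rule of the
#' spatial permutation test.
#'
#' @param x a [TerritoryMap-class].
#' @name TerritoryMap-accessors
#' @aliases territories anchors anchorCounts
NULL

#' @rdname TerritoryMap-accessors
#' @export
setMethod("territories", "TerritoryMap", function(x) x@territories)

#' @rdname TerritoryMap-accessors
#' @export
setMethod("anchors", "TerritoryMap", function(x) x@anchors)

#' @rdname TerritoryMap-accessors
#' @export
setMethod("anchorCounts", "TerritoryMap", function(x) {
  ids <- x@territories$territory_id
  cnt <- table(factor(x@anchors$territory_id, levels = ids))
  stats::setNames(as.integer(cnt), ids)
})

#' @export
setMethod("show", "TerritoryMap", function(object) {
  cat(sprintf("TerritoryMap: %d territories, %d unpaired-male anchors\n",
              nrow(object@territories), nrow(object@anchors)))
})

#' Read a territory map from CSVs
#'
#' @param territories_path CSV with columns `territory_id`, `x_m`, `y_m`,
#'   `paired_male_id`.
#' @param anchors_path optional CSV with columns `unpaired_male_id`,
#'   `territory_id`.
#' @param sep field separator.
#' @return A [TerritoryMap-class].
#' @export
readTerritoryMap <- function(territories_path, anchors_path = NULL, sep = ",") {
  tt <- utils::read.table(territories_path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  an <- if (is.null(anchors_path))
    data.frame(unpaired_male_id = character(0), territory_id = character(0))
  else
    utils::read.table(anchors_path, header = TRUE, sep = sep,
                      colClasses = "character", strip.white = TRUE)
  TerritoryMap(tt, an)
}
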
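#' @rdname GenotypeSet-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname GenotypeSet-accessors
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))

#' @rdname GenotypeSet-accessors
#' @export
setGeneric("nLociComplete", function(x) standardGeneric("nLociComplete"))

#' @rdname expectedHet
#' @export
setGeneric("expectedHet", function(x) standardGeneric("expectedHet"))

#' @rdname AlleleFreqTable-accessors
#' @export
setGeneric("alleleFreqs", function(x, locus) standardGeneric("alleleFreqs"))

#' @rdname BroodSet-accessors
#' @export
setGeneric("broodTable", function(x) standardGeneric("broodTable"))

#' @rdname BroodSet-accessors
#' @export
setGeneric("broodIds", function(x) standardGeneric("broodIds"))

#' @rdname BroodSet-accessors
#' @export
setGeneric("paternityFraction", function(x) standardGeneric("paternityFraction"))

#' @rdname TerritoryMap-accessors
#' @export
setGeneric("territories", function(x) standardGeneric("territories"))

#' @rdname TerritoryMap-accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname TerritoryMap-accessors
#' @export
setGeneric("anchorCounts", function(x) standardGeneric("anchorCounts"))

#' @rdname SireReconstruction-accessors
#' @export
setGeneric("sireGenotypes", function(x) standardGeneric("sireGenotypes"))

#' @rdname SireReconstruction-accessors
#' @export
setGeneric("sireInfo", function(x) standardGeneric("sireInfo"))
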
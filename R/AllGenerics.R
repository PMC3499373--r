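#' @rdname GenotypeMatrix-class
#' @param object,x a \code{GenotypeMatrix}.
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("empiricalMaf", function(x) standardGeneric("empiricalMaf"))

#' @rdname SelectionRegion-class
#' @param region a \code{SelectionRegion}.
#' @param y numeric trait values.
#' @export
setGeneric("inRegion", function(region, y) standardGeneric("inRegion"))

#' @rdname TestResult-class
#' @param x a \code{TestResult}.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
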
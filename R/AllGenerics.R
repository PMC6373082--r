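#' Accessors for call-set objects
#'
#' \code{callData()} returns the call table as a base \code{data.frame} (with
#' the consensus \code{concordance}, KO-linked \code{reason} or strain
#' \code{origin} column appended where the class carries one);
#' \code{sampleLabel()} the genotype/sample label; \code{nCalls()} the number
#' of calls; \code{siteKeys()} the \code{chrom:pos:ref:alt} key strings.
#'
#' @param x a [GenotypeCalls-class] (or subclass) object.
#' @return \code{callData()}: a data.frame; \code{sampleLabel()}: a string;
#'   \code{nCalls()}: an integer; \code{siteKeys()}: a character vector.
#' @examples
#' gc <- GenotypeCalls("KO", data.frame(
#'   chrom = "chr1", pos = 100L, ref = "A", alt = "G",
#'   genotype = "hom_alt", qual = 50, depth = 20L, sampleId = "ko1"))
#' nCalls(gc)
#' siteKeys(gc)
#' @aliases callData sampleLabel nCalls siteKeys
#' @name call-accessors
NULL

#' @rdname call-accessors
#' @export
setGeneric("callData", function(x) standardGeneric("callData"))

#' @rdname call-accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname call-accessors
#' @export
setGeneric("nCalls", function(x) standardGeneric("nCalls"))

#' @rdname call-accessors
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' @rdname applyHardFilters
#' @export
setGeneric("applyHardFilters",
           function(x, minDepth = 10, minQual = 30, ...)
             standardGeneric("applyHardFilters"))

#' @rdname binVariants
#' @export
setGeneric("binVariants",
           function(x, binSize = 1e7, ...) standardGeneric("binVariants"))

#' @rdname ploidyProfile
#' @export
setGeneric("ploidyProfile",
           function(x, binSize = 1e7, ...) standardGeneric("ploidyProfile"))

#' @rdname subtractReference
#' @export
setGeneric("subtractReference",
           function(x, reference) standardGeneric("subtractReference"))

#' @rdname writeCallsVcf
#' @export
setGeneric("writeCallsVcf",
           function(x, path, ...) standardGeneric("writeCallsVcf"))

#' @rdname writeCallsTsv
#' @export
setGeneric("writeCallsTsv",
           function(x, path) standardGeneric("writeCallsTsv"))

#' @rdname physicalToGenetic
#' @export
setGeneric("physicalToGenetic",
           function(map, chrom, bp) standardGeneric("physicalToGenetic"))
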
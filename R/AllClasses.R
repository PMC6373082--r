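#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.GENOTYPE_STATES <- c("hom_ref", "het", "hom_alt", "missing")
.CALL_COLUMNS <- c("chrom", "pos", "ref", "alt", "genotype", "qual",
                   "depth", "sampleId")

.validCallTable <- function(calls) {
  msg <- NULL
  missing_cols <- setdiff(.CALL_COLUMNS, colnames(calls))
  if (length(missing_cols))
    msg <- c(msg, paste0("calls lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if (is.null(msg) && nrow(calls)) {
    if (any(calls$pos < 1L))
      msg <- c(msg, "pos must be >= 1 (1-based coordinates)")
    if (any(!nzchar(calls$ref)) || any(!nzchar(calls$alt)))
      msg <- c(msg, "ref and alt alleles must be non-empty")
    if (any(grepl(",", calls$alt, fixed = TRUE)))
      msg <- c(msg, "alt must hold a single allele (split multiallelics)")
    if (!all(calls$genotype %in% .GENOTYPE_STATES))
      msg <- c(msg, "genotype must be one of hom_ref/het/hom_alt/missing")
    if (any(calls$qual < 0, na.rm = TRUE))
      msg <- c(msg, "qual must be >= 0")
    if (any(calls$depth < 0, na.rm = TRUE))
      msg <- c(msg, "depth must be >= 0")
    keys <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
    if (anyDuplicated(keys))
      msg <- c(msg, "at most one call per site key (chrom,pos,ref,alt)")
  }
  msg
}

#' Genotype calls for one sample or one consensus genotype
#'
#' The central container: a keyed set of diploid genotype calls, one per
#' (chrom, pos, ref, alt) site key, for a single sample or a genotype-level
#' consensus. Multiallelic records are represented split, one call per ALT
#' allele. Coordinates are 1-based (VCF convention).
#'
#' @slot label genotype or sample label, e.g. \code{"WT"}, \code{"KO"} or a
#'   sample name.
#' @slot calls a \link[S4Vectors]{DataFrame} with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{genotype} (one of
#'   \code{hom_ref}, \code{het}, \code{hom_alt}, \code{missing}),
#'   \code{qual}, \code{depth}, \code{sampleId}.
#'
#' @seealso [readGenotypeVcf()], [applyHardFilters()], [intersectReplicates()]
#' @exportClass GenotypeCalls
setClass("GenotypeCalls",
         representation(label = "character", calls = "DataFrame"))

setValidity("GenotypeCalls", function(object) {
  msg <- NULL
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "label must be a single non-NA string")
  msg <- c(msg, .validCallTable(object@calls))
  if (is.null(msg)) TRUE else msg
})

#' Consensus genotype calls across replicates
#'
#' Result of [intersectReplicates()]: the site keys shared by all replicate
#' call sets of one genotype, with a per-site concordance flag recording
#' whether replicate genotypes agreed.
#'
#' @slot concordance character vector parallel to the calls, each entry
#'   \code{"concordant"} or \code{"discordant_genotype"}.
#' @exportClass ConsensusCalls
setClass("ConsensusCalls", contains = "GenotypeCalls",
         representation(concordance = "character"))

setValidity("ConsensusCalls", function(object) {
  msg <- NULL
  if (length(object@concordance) != nrow(object@calls))
    msg <- c(msg, "concordance must be parallel to the call table")
  if (!all(object@concordance %in% c("concordant", "discordant_genotype")))
    msg <- c(msg, "concordance entries must be concordant/discordant_genotype")
  if (is.null(msg)) TRUE else msg
})

#' KO-linked variant calls
#'
#' Result of [dissectKoLinked()]: the calls of a KO consensus that are either
#' absent from the WT set or present with a different genotype state — the
#' operational congenic-footprint signal.
#'
#' @slot reason character vector parallel to the calls, each entry
#'   \code{"absent_in_wt"} or \code{"genotype_mismatch"}.
#' @exportClass KoLinkedCalls
setClass("KoLinkedCalls", contains = "GenotypeCalls",
         representation(reason = "character"))

setValidity("KoLinkedCalls", function(object) {
  msg <- NULL
  if (length(object@reason) != nrow(object@calls))
    msg <- c(msg, "reason must be parallel to the call table")
  if (!all(object@reason %in% c("absent_in_wt", "genotype_mismatch")))
    msg <- c(msg, "reason entries must be absent_in_wt/genotype_mismatch")
  if (is.null(msg)) TRUE else msg
})

#' Strain-origin annotated calls
#'
#' Result of [annotateStrainOrigin()]: every call of the input set labelled
#' as donor-strain derived (present in the donor reference VCF) or novel.
#'
#' @slot origin character vector parallel to the calls, each entry
#'   \code{"donor_derived"} or \code{"novel"}.
#' @exportClass OriginAnnotatedCalls
setClass("OriginAnnotatedCalls", contains = "GenotypeCalls",
         representation(origin = "character"))

setValidity("OriginAnnotatedCalls", function(object) {
  msg <- NULL
  if (length(object@origin) != nrow(object@calls))
    msg <- c(msg, "origin must be parallel to the call table")
  if (!all(object@origin %in% c("donor_derived", "novel")))
    msg <- c(msg, "origin entries must be donor_derived/novel")
  if (is.null(msg)) TRUE else msg
})

#' Genetic map (physical to genetic coordinates)
#'
#' Per-chromosome anchor lists of (bp, cM) pairs, strictly increasing in
#' both coordinates, used for linear interpolation by [physicalToGenetic()].
#' A constant-rate fallback (cM/Mb) can stand in for chromosomes absent
#' from the map.
#'
#' @slot anchors data.frame with columns \code{chrom}, \code{bp}, \code{cM}.
#' @slot fallbackRate constant rate in cM/Mb used for chromosomes missing
#'   from the anchor table, or \code{NA_real_} to disable the fallback.
#' @exportClass GeneticMap
setClass("GeneticMap",
         representation(anchors = "data.frame", fallbackRate = "numeric"))

setValidity("GeneticMap", function(object) {
  msg <- NULL
  a <- object@anchors
  if (!all(c("chrom", "bp", "cM") %in% colnames(a)))
    msg <- c(msg, "anchors needs columns chrom, bp, cM")
  if (length(object@fallbackRate) != 1L)
    msg <- c(msg, "fallbackRate must be a single number (NA disables it)")
  if (is.null(msg) && nrow(a)) {
    bad <- vapply(split(a, a$chrom), function(d) {
      nrow(d) < 2L || is.unsorted(d$bp, strictly = TRUE) ||
        is.unsorted(d$cM, strictly = TRUE)
    }, logical(1))
    if (any(bad))
      msg <- c(msg, paste0("each chromosome needs >= 2 anchors strictly ",
                           "increasing in bp and cM; offending: ",
                           paste(names(bad)[bad], collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Congenic footprint interval
#'
#' A KO-linked introgressed interval on one chromosome with its genetic-map
#' extent and the backcross-generation estimate from the 200/N rule.
#'
#' @slot chrom chromosome name.
#' @slot startBp,endBp 1-based inclusive physical bounds of the qualifying
#'   KO-linked variants.
#' @slot extentCM genetic-map extent of the interval in centimorgans.
#' @slot estimatedN estimated number of backcross generations (integer,
#'   minimum 1).
#' @exportClass FootprintInterval
setClass("FootprintInterval",
         representation(chrom = "character", startBp = "numeric",
                        endBp = "numeric", extentCM = "numeric",
                        estimatedN = "integer"))

setValidity("FootprintInterval", function(object) {
  msg <- NULL
  if (object@startBp > object@endBp)
    msg <- c(msg, "startBp must be <= endBp")
  if (object@extentCM < 0) msg <- c(msg, "extentCM must be >= 0")
  if (object@estimatedN < 1L) msg <- c(msg, "estimatedN must be >= 1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GenotypeCalls", function(object) {
  cat(sprintf("%s object \"%s\" with %d call(s) on %d chromosome(s)\n",
              class(object), object@label, nrow(object@calls),
              length(unique(object@calls$chrom))))
  gt <- table(factor(object@calls$genotype, levels = .GENOTYPE_STATES))
  cat("  genotypes:", paste(names(gt), gt, sep = "=", collapse = " "), "\n")
})

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d anchor(s) on %d chromosome(s); fallback %s\n",
              nrow(object@anchors), length(unique(object@anchors$chrom)),
              ifelse(is.na(object@fallbackRate), "disabled",
                     paste0(object@fallbackRate, " cM/Mb"))))
})

setMethod("show", "FootprintInterval", function(object) {
  cat(sprintf(
    "FootprintInterval %s:%d-%d  extent %.2f cM  estimated N = %d\n",
    object@chrom, as.integer(object@startBp), as.integer(object@endBp),
    object@extentCM, object@estimatedN))
})
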
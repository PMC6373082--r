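#' Classify the zygosity ("ploidy") of genotype calls
#'
#' Footprint variants are donor alleles, so "homozygous" means hom_alt
#' only; hom_ref and missing calls fall into \code{other}.
#'
#' @param genotype character vector of genotype states (\code{hom_ref},
#'   \code{het}, \code{hom_alt}, \code{missing}), or a
#'   [GenotypeCalls-class] object.
#' @return character vector over \code{homozygous} / \code{heterozygous} /
#'   \code{other}.
#' @examples
#' classifyPloidy(c("hom_alt", "het", "missing"))
#' @export
classifyPloidy <- function(genotype) {
  if (is(genotype, "GenotypeCalls")) genotype <- callData(genotype)$genotype
  stopifnot(all(genotype %in% .GENOTYPE_STATES))
  out <- rep("other", length(genotype))
  out[genotype == "hom_alt"] <- "homozygous"
  out[genotype == "het"] <- "heterozygous"
  out
}

#' Per-bin zygosity profile of a call set
#'
#' For each chromosome and fixed-width bin, counts homozygous (hom_alt) and
#' heterozygous calls — the data behind ploidy-coloured footprint
#' histograms. Run per littermate (before any consensus) to expose
#' replicate-to-replicate ploidy variability. Consistent with
#' [binVariants()]: hom + het + other = total per bin.
#'
#' @param x a [GenotypeCalls-class] (or subclass) object.
#' @param binSize bin width in bp (default 10 Mb).
#' @param chromLengths optional named chromosome lengths for trailing bins.
#' @param ... unused.
#' @return a data.frame with columns \code{sampleId}, \code{chrom},
#'   \code{bin}, \code{start}, \code{end}, \code{hom}, \code{het},
#'   \code{other}, \code{count}.
#' @rdname ploidyProfile
#' @export
setMethod("ploidyProfile", "GenotypeCalls",
          function(x, binSize = 1e7, chromLengths = NULL, ...) {
  stopifnot(binSize > 0)
  d <- callData(x)
  total <- .binTable(d, binSize, chromLengths)
  cls <- classifyPloidy(d$genotype)
  hom <- .binTable(d[cls == "homozygous", , drop = FALSE], binSize)
  het <- .binTable(d[cls == "heterozygous", , drop = FALSE], binSize)
  key <- function(t) paste(t$chrom, t$bin)
  total$hom <- hom$count[match(key(total), key(hom))]
  total$het <- het$count[match(key(total), key(het))]
  total$hom[is.na(total$hom)] <- 0L
  total$het[is.na(total$het)] <- 0L
  total$other <- total$count - total$hom - total$het
  total$sampleId <- rep(if (nrow(d)) d$sampleId[1] else x@label,
                        nrow(total))
  attr(total, "binSize") <- binSize
  total[, c("sampleId", "chrom", "bin", "start", "end", "hom", "het",
            "other", "count")]
})

#' Mendelian annotation of KO-linked variants by a heterozygous littermate
#'
#' If footprint inheritance is Mendelian, a heterozygous littermate carries
#' the introgressed variants as heterozygous calls. The het sample is first
#' reduced to calls whose site keys do not occur in the WT sample, then to
#' heterozygous calls; KO-linked variants whose keys appear in that reduced
#' set are "annotated". Coverage near 1 for footprint-interior variants
#' supports homozygous Mendelian inheritance of the footprint.
#'
#' @param koLinked a [KoLinkedCalls-class] (or any call set) of KO-linked
#'   variants; must be non-empty.
#' @param hetSample a [GenotypeCalls-class] object from the heterozygous
#'   littermate.
#' @param wtSample a [GenotypeCalls-class] object from the WT littermate,
#'   used to pre-subtract shared variants; may be an empty set.
#' @return a list with \code{annotated} (character site keys),
#'   \code{nKoLinked}, \code{nAnnotated} and \code{variantCoverage}
#'   (= nAnnotated / nKoLinked).
#' @examples
#' ko <- GenotypeCalls("KO", data.frame(
#'   chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G",
#'   genotype = "hom_alt", qual = 50, depth = 20L, sampleId = "KO"))
#' het <- GenotypeCalls("HET", data.frame(
#'   chrom = "chr1", pos = 1L, ref = "A", alt = "G", genotype = "het",
#'   qual = 50, depth = 20L, sampleId = "het1"))
#' mendelianAnnotate(ko, het, GenotypeCalls("WT"))$variantCoverage  # 0.5
#' @export
mendelianAnnotate <- function(koLinked, hetSample, wtSample) {
  stopifnot(is(koLinked, "GenotypeCalls"), is(hetSample, "GenotypeCalls"),
            is(wtSample, "GenotypeCalls"))
  if (nCalls(koLinked) == 0L)
    stop("the KO-linked set is empty; nothing to annotate")
  reduced <- subtractReference(hetSample, wtSample)
  hetKeys <- siteKeys(reduced)[callData(reduced)$genotype == "het"]
  koKeys <- siteKeys(koLinked)
  annotated <- koKeys[koKeys %in% hetKeys]
  list(annotated = annotated,
       nKoLinked = length(koKeys),
       nAnnotated = length(annotated),
       variantCoverage = length(annotated) / length(koKeys))
}
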
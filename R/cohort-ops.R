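#' Intersect replicate call sets into a genotype consensus
#'
#' Takes the call sets of biological replicates sharing one genotype label
#' and keeps the site keys present in \emph{all} of them, recording whether
#' the replicate genotypes agreed. Under \code{policy = "strict"} a
#' disagreement yields a \code{discordant_genotype} flag and genotype state
#' \code{missing}; under \code{"majority"} the modal genotype is kept (ties
#' flagged discordant with genotype \code{missing}). Calls with genotype
#' \code{missing} in a replicate are treated as absent from that replicate.
#'
#' @param sets a list of [GenotypeCalls-class] objects with a common label.
#' @param policy \code{"strict"} (default) or \code{"majority"}.
#' @return a [ConsensusCalls-class] object. The representative qual/depth
#'   are the per-site minima across replicates (the weakest evidence).
#' @examples
#' mk <- function(id, pos, gt) GenotypeCalls("KO", data.frame(
#'   chrom = "chr1", pos = pos, ref = "A", alt = "G", genotype = gt,
#'   qual = 50, depth = 20L, sampleId = id))
#' cons <- intersectReplicates(list(
#'   mk("ko1", c(100L, 200L), "hom_alt"),
#'   mk("ko2", c(100L, 300L), "hom_alt")))
#' callData(cons)
#' @export
intersectReplicates <- function(sets, policy = c("strict", "majority")) {
  policy <- match.arg(policy)
  if (!is.list(sets) || length(sets) == 0L)
    stop("need at least one replicate call set")
  stopifnot(all(vapply(sets, is, logical(1), "GenotypeCalls")))
  labels <- unique(vapply(sets, sampleLabel, character(1)))
  if (length(labels) != 1L)
    stop("replicates must share one genotype label; got: ",
         paste(labels, collapse = ", "))

  # missing genotypes are excluded from set operations
  tabs <- lapply(sets, function(s) {
    d <- s@calls[s@calls$genotype != "missing", , drop = FALSE]
    d
  })
  keysList <- lapply(tabs, .keyOf)
  shared <- Reduce(intersect, keysList)
  first <- tabs[[1]][match(shared, keysList[[1]]), , drop = FALSE]
  if (length(shared) == 0L) {
    return(new("ConsensusCalls", label = labels, calls = .emptyCallTable(),
               concordance = character()))
  }
  gts <- vapply(seq_along(tabs), function(i)
    tabs[[i]]$genotype[match(shared, keysList[[i]])], character(length(shared)))
  gts <- matrix(gts, nrow = length(shared))
  quals <- vapply(seq_along(tabs), function(i)
    tabs[[i]]$qual[match(shared, keysList[[i]])], numeric(length(shared)))
  quals <- matrix(quals, nrow = length(shared))
  depths <- vapply(seq_along(tabs), function(i)
    tabs[[i]]$depth[match(shared, keysList[[i]])], integer(length(shared)))
  depths <- matrix(depths, nrow = length(shared))

  agree <- apply(gts, 1L, function(g) length(unique(g)) == 1L)
  genotype <- character(length(shared))
  concord <- ifelse(agree, "concordant", "discordant_genotype")
  if (policy == "strict") {
    genotype <- ifelse(agree, gts[, 1], "missing")
  } else {
    genotype <- apply(gts, 1L, function(g) {
      tt <- sort(table(g), decreasing = TRUE)
      if (length(tt) > 1L && tt[1] == tt[2]) "missing" else names(tt)[1]
    })
  }
  calls <- first
  calls$genotype <- genotype
  calls$qual <- apply(quals, 1L, min)
  calls$depth <- as.integer(apply(depths, 1L, min))
  calls$sampleId <- labels
  ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  new("ConsensusCalls", label = labels, calls = calls,
      concordance = concord[ord])
}

#' Subtract a strain reference from a call set
#'
#' Removes every call whose site key (chrom, pos, ref, alt) appears in the
#' reference set — site-level removal; the reference genotype is ignored.
#' Used to strip recipient-strain (e.g. C57BL/6J) variants before plotting
#' or footprint dissection.
#'
#' @param x a [GenotypeCalls-class] or [ConsensusCalls-class] object.
#' @param reference a [GenotypeCalls-class] object of reference variants.
#' @return the input class with the reference keys removed.
#' @examples
#' a <- GenotypeCalls("KO", data.frame(
#'   chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G",
#'   genotype = "hom_alt", qual = 50, depth = 20L, sampleId = "ko"))
#' b <- GenotypeCalls("ref", data.frame(
#'   chrom = "chr1", pos = 2L, ref = "A", alt = "G",
#'   genotype = "het", qual = 50, depth = 20L, sampleId = "ref"))
#' callData(subtractReference(a, b))$pos
#' @rdname subtractReference
#' @export
setMethod("subtractReference",
          signature(x = "GenotypeCalls", reference = "GenotypeCalls"),
          function(x, reference) {
  keep <- !(.keyOf(x@calls) %in% siteKeys(reference))
  .subsetCalls(x, keep)
})

#' Annotate calls by donor-strain origin
#'
#' Labels every call of \code{x} as \code{donor_derived} if its site key is
#' present in the donor-strain reference VCF (e.g. a Mouse Genomes Project
#' strain release for the ES-cell strain), else \code{novel}. No call is
#' removed.
#'
#' @param x a [GenotypeCalls-class] or [ConsensusCalls-class] object.
#' @param donorReference a [GenotypeCalls-class] object of donor-strain
#'   variants.
#' @return an [OriginAnnotatedCalls-class] object.
#' @export
annotateStrainOrigin <- function(x, donorReference) {
  stopifnot(is(x, "GenotypeCalls"), is(donorReference, "GenotypeCalls"))
  origin <- ifelse(.keyOf(x@calls) %in% siteKeys(donorReference),
                   "donor_derived", "novel")
  new("OriginAnnotatedCalls", label = x@label, calls = x@calls,
      origin = as.character(origin))
}

#' Dissect KO-linked variants against the WT sample
#'
#' The footprint call: a KO-consensus call is KO-linked if its site key is
#' absent from the WT set (\code{absent_in_wt}) or present with a different
#' genotype state (\code{genotype_mismatch}). WT hom-ref and missing
#' genotypes count as absent. Genotype comparison is by state, not phase
#' ("1|1" equals "1/1"). KO calls with genotype \code{missing} (e.g.
#' strict-policy discordances) are excluded before comparison, so the
#' KO-linked set plus the genotype-matching set partitions the non-missing
#' KO calls exactly.
#'
#' @param ko a [ConsensusCalls-class] (or plain [GenotypeCalls-class]) KO
#'   set.
#' @param wt a [GenotypeCalls-class] or [ConsensusCalls-class] WT set
#'   (single littermate or WT consensus).
#' @return a [KoLinkedCalls-class] object.
#' @examples
#' ko <- GenotypeCalls("KO", data.frame(
#'   chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G",
#'   genotype = c("hom_alt", "het"), qual = 50, depth = 20L,
#'   sampleId = "KO"))
#' wt <- GenotypeCalls("WT", data.frame(
#'   chrom = "chr1", pos = 2L, ref = "A", alt = "G", genotype = "het",
#'   qual = 50, depth = 20L, sampleId = "WT"))
#' callData(dissectKoLinked(ko, wt))  # pos 1 retained, absent_in_wt
#' @export
dissectKoLinked <- function(ko, wt) {
  stopifnot(is(ko, "GenotypeCalls"), is(wt, "GenotypeCalls"))
  koCalls <- ko@calls[ko@calls$genotype != "missing", , drop = FALSE]
  wtCalls <- wt@calls
  # hom_ref / missing WT genotypes count as "absent"
  wtCalls <- wtCalls[!(wtCalls$genotype %in% c("hom_ref", "missing")), ,
                     drop = FALSE]
  koKeys <- .keyOf(koCalls)
  m <- match(koKeys, .keyOf(wtCalls))
  inWt <- !is.na(m)
  mismatch <- inWt & koCalls$genotype != wtCalls$genotype[ifelse(inWt, m, 1L)]
  keep <- !inWt | mismatch
  reason <- ifelse(!inWt, "absent_in_wt", "genotype_mismatch")[keep]
  calls <- koCalls[keep, , drop = FALSE]
  rownames(calls) <- NULL
  new("KoLinkedCalls", label = ko@label, calls = calls,
      reason = as.character(reason))
}
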
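#' Construct a GenotypeCalls object from a call table
#'
#' @param label genotype or sample label (e.g. \code{"WT"}, \code{"KO"},
#'   or a sample name).
#' @param calls a data.frame (or DataFrame) with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{genotype}, \code{qual},
#'   \code{depth}; a missing \code{sampleId} column is filled with
#'   \code{label}. Coordinates are 1-based.
#' @return a [GenotypeCalls-class] object, calls sorted by (chrom, pos).
#' @examples
#' GenotypeCalls("WT", data.frame(
#'   chrom = "chr1", pos = 100L, ref = "A", alt = "G",
#'   genotype = "het", qual = 40, depth = 15L, sampleId = "wt1"))
#' @export
GenotypeCalls <- function(label, calls = NULL) {
  calls <- .asCallTable(calls, label)
  new("GenotypeCalls", label = as.character(label), calls = calls)
}

.emptyCallTable <- function() {
  DataFrame(chrom = character(), pos = integer(), ref = character(),
            alt = character(), genotype = character(), qual = numeric(),
            depth = integer(), sampleId = character())
}

.asCallTable <- function(calls, label) {
  if (is.null(calls) || nrow(calls) == 0L) return(.emptyCallTable())
  calls <- as(as.data.frame(calls), "DataFrame")
  if (!"sampleId" %in% colnames(calls))
    calls$sampleId <- as.character(label)
  calls$pos <- as.integer(calls$pos)
  calls$depth <- as.integer(calls$depth)
  calls$qual <- as.numeric(calls$qual)
  for (col in c("chrom", "ref", "alt", "genotype", "sampleId"))
    calls[[col]] <- as.character(calls[[col]])
  calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls[, .CALL_COLUMNS]
}

.keyOf <- function(calls) {
  if (nrow(calls) == 0L) return(character())
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' @rdname call-accessors
setMethod("callData", "GenotypeCalls", function(x) as.data.frame(x@calls))

#' @rdname call-accessors
setMethod("callData", "ConsensusCalls", function(x) {
  d <- as.data.frame(x@calls); d$concordance <- x@concordance; d
})

#' @rdname call-accessors
setMethod("callData", "KoLinkedCalls", function(x) {
  d <- as.data.frame(x@calls); d$reason <- x@reason; d
})

#' @rdname call-accessors
setMethod("callData", "OriginAnnotatedCalls", function(x) {
  d <- as.data.frame(x@calls); d$origin <- x@origin; d
})

#' @rdname call-accessors
setMethod("sampleLabel", "GenotypeCalls", function(x) x@label)

#' @rdname call-accessors
setMethod("nCalls", "GenotypeCalls", function(x) nrow(x@calls))

#' @rdname call-accessors
setMethod("siteKeys", "GenotypeCalls", function(x) .keyOf(x@calls))

.gtToState <- function(gt, altIndex) {
  # gt: vector of GT strings ("0/1", "1|1", "./.", "1", ...); altIndex: the
  # 1-based ALT allele each split call refers to. Phase is ignored.
  alleles <- strsplit(gt, "[/|]")
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (length(a) == 0L || any(a == "." | a == "" | is.na(a)))
      return("missing")
    hits <- sum(a == as.character(altIndex[i]))
    if (hits >= length(a)) "hom_alt" else if (hits >= 1L) "het" else "hom_ref"
  }, character(1))
}

#' Read a VCF file into a GenotypeCalls object
#'
#' Reads one sample of a VCF v4.x file (plain or gzip/bgzip compressed)
#' through \pkg{VariantAnnotation} and maps it to the package's flat call
#' representation. Multiallelic records are split into one call per ALT
#' allele sharing pos/ref; hom-ref and missing genotypes are retained (and
#' flagged by their genotype state). Depth is taken from the sample-level
#' \code{DP} FORMAT field when present, otherwise from INFO \code{DP};
#' calls with neither have depth 0 and so never survive the depth filter.
#' Chromosome names are preserved verbatim; see [renameChromosomes()] for
#' reconciling "chr14" vs "14" dialects.
#'
#' @param path path to a VCF file.
#' @param sampleId name of the sample column to read; may be omitted for a
#'   single-sample file.
#' @param label label for the resulting set (defaults to \code{sampleId}).
#' @return a [GenotypeCalls-class] object.
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' gc0 <- GenotypeCalls("KO", data.frame(
#'   chrom = "chr1", pos = 100L, ref = "A", alt = "G",
#'   genotype = "hom_alt", qual = 45, depth = 20L, sampleId = "ko1"))
#' writeCallsVcf(gc0, vcf)
#' readGenotypeVcf(vcf, "ko1")
#' @export
readGenotypeVcf <- function(path, sampleId = NULL, label = sampleId) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  avail <- colnames(vcf)
  if (is.null(sampleId)) {
    if (length(avail) != 1L)
      stop("sampleId required for multi-sample VCF; available: ",
           paste(avail, collapse = ", "))
    sampleId <- avail
  } else if (!sampleId %in% avail) {
    stop("sample '", sampleId, "' absent from ", path, "; available: ",
         paste(avail, collapse = ", "))
  }
  if (is.null(label)) label <- sampleId
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) return(GenotypeCalls(label))

  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  altList <- rr$ALT
  nAlt <- S4Vectors::elementNROWS(altList)
  qual <- rr$QUAL
  qual[is.na(qual)] <- 0

  gt <- VariantAnnotation::geno(vcf)$GT[, sampleId]
  if ("DP" %in% names(VariantAnnotation::geno(vcf))) {
    dp <- VariantAnnotation::geno(vcf)$DP[, sampleId]
  } else dp <- rep(NA_integer_, n)
  if (anyNA(dp) && "DP" %in% names(VariantAnnotation::info(vcf))) {
    idp <- VariantAnnotation::info(vcf)$DP
    dp[is.na(dp)] <- idp[is.na(dp)]
  }
  dp[is.na(dp)] <- 0L

  idx <- rep.int(seq_len(n), nAlt)
  altIndex <- sequence(nAlt)
  alt <- as.character(unlist(altList, use.names = FALSE))
  keep <- nzchar(alt) & alt != "." & alt != "*"
  calls <- data.frame(
    chrom = chrom[idx], pos = pos[idx], ref = ref[idx], alt = alt,
    genotype = .gtToState(gt[idx], altIndex),
    qual = as.numeric(qual[idx]), depth = as.integer(dp[idx]),
    sampleId = sampleId, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  GenotypeCalls(label, calls)
}

#' Apply the pipeline's hard depth/quality filters
#'
#' Retains only calls with \code{depth > minDepth} and \code{qual > minQual}
#' — both strict inequalities, matching the conventional
#' \code{DP > 10 & QUAL > 30} hard filter applied to caller output before
#' any set operation. Idempotent; the input is not modified.
#'
#' @param x a [GenotypeCalls-class] (or subclass) object.
#' @param minDepth exclusive read-depth threshold (default 10).
#' @param minQual exclusive Phred site-quality threshold (default 30).
#' @param ... unused.
#' @return an object of the same class containing the retained subset.
#' @examples
#' gc <- GenotypeCalls("KO", data.frame(
#'   chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G",
#'   genotype = "hom_alt", qual = c(31, 100), depth = c(11L, 10L),
#'   sampleId = "ko1"))
#' nCalls(applyHardFilters(gc))  # only the DP=11/QUAL=31 call survives
#' @rdname applyHardFilters
#' @export
setMethod("applyHardFilters", "GenotypeCalls",
          function(x, minDepth = 10, minQual = 30, ...) {
  stopifnot(minDepth >= 0, minQual >= 0)
  keep <- x@calls$depth > minDepth & x@calls$qual > minQual
  .subsetCalls(x, keep)
})

# subset any call-set class, keeping parallel slots in step
.subsetCalls <- function(x, keep) {
  out <- x
  out@calls <- x@calls[keep, , drop = FALSE]
  rownames(out@calls) <- NULL
  if (is(x, "ConsensusCalls")) out@concordance <- x@concordance[keep]
  if (is(x, "KoLinkedCalls")) out@reason <- x@reason[keep]
  if (is(x, "OriginAnnotatedCalls")) out@origin <- x@origin[keep]
  validObject(out)
  out
}

#' Reconcile chromosome-name dialects
#'
#' Strain reference VCFs often write "14" where caller output writes
#' "chr14". This applies an explicit mapping (old name -> new name) or, with
#' \code{addPrefix}, prepends a prefix to every chromosome name. No silent
#' auto-renaming is ever performed elsewhere in the package.
#'
#' @param x a [GenotypeCalls-class] (or subclass) object.
#' @param mapping named character vector, \code{c("14" = "chr14")}-style.
#' @param addPrefix prefix to prepend to every chromosome name (applied
#'   before \code{mapping}); default none.
#' @return the renamed object (same class).
#' @examples
#' gc <- GenotypeCalls("ref", data.frame(
#'   chrom = "14", pos = 1L, ref = "A", alt = "G", genotype = "hom_alt",
#'   qual = 50, depth = 20L, sampleId = "ref"))
#' callData(renameChromosomes(gc, addPrefix = "chr"))$chrom
#' @export
renameChromosomes <- function(x, mapping = NULL, addPrefix = NULL) {
  stopifnot(is(x, "GenotypeCalls"))
  chrom <- x@calls$chrom
  if (!is.null(addPrefix)) chrom <- paste0(addPrefix, chrom)
  if (!is.null(mapping)) {
    hit <- chrom %in% names(mapping)
    chrom[hit] <- unname(mapping[chrom[hit]])
  }
  x@calls$chrom <- chrom
  x@calls <- .asCallTable(x@calls, x@label)
  validObject(x)
  x
}

.GT_STRING <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                missing = "./.")

#' Write a call set as a VCF v4.2 file
#'
#' Emits a minimal, deterministic single-sample VCF: CHROM/POS/ID/REF/ALT/
#' QUAL/FILTER/INFO plus GT:DP for the sample. Consensus concordance,
#' KO-linked reason and strain origin are written as
#' \code{CONCORDANCE}/\code{KO_LINKED_REASON}/\code{ORIGIN} INFO tags when
#' the object carries them. Site key, genotype state, qual and depth
#' round-trip through [readGenotypeVcf()].
#'
#' @param x a [GenotypeCalls-class] (or subclass) object.
#' @param path output file path (plain text).
#' @param contigs optional named vector of chromosome lengths for contig
#'   header lines.
#' @param ... unused.
#' @return invisibly, \code{path}.
#' @rdname writeCallsVcf
#' @export
setMethod("writeCallsVcf", "GenotypeCalls",
          function(x, path, contigs = NULL, ...) {
  d <- callData(x)
  sample_id <- if (nrow(d)) d$sampleId[1] else x@label
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=congenicScan",
    '##INFO=<ID=CONCORDANCE,Number=1,Type=String,Description="Replicate genotype concordance">',
    '##INFO=<ID=KO_LINKED_REASON,Number=1,Type=String,Description="Why the call is KO-linked">',
    '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="donor_derived or novel">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_id, sep = "\t"))
  info <- rep(".", nrow(d))
  if ("concordance" %in% colnames(d))
    info <- paste0("CONCORDANCE=", d$concordance)
  if ("reason" %in% colnames(d))
    info <- paste0("KO_LINKED_REASON=", d$reason)
  if ("origin" %in% colnames(d))
    info <- paste0("ORIGIN=", d$origin)
  body <- if (nrow(d)) {
    paste(d$chrom, d$pos, ".", d$ref, d$alt,
          format(d$qual, trim = TRUE, digits = 10, scientific = FALSE),
          ".", info, "GT:DP",
          paste0(.GT_STRING[d$genotype], ":", d$depth), sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
})

#' Write a call set as TSV
#'
#' Columns: chrom, pos, ref, alt, genotype, qual, depth, sampleId, plus the
#' class-specific annotation column (concordance / reason / origin) when
#' present. The layout is VEP-ready (1-based coordinates).
#'
#' @param x a [GenotypeCalls-class] (or subclass) object.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @rdname writeCallsTsv
#' @export
setMethod("writeCallsTsv", "GenotypeCalls", function(x, path) {
  utils::write.table(callData(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
})
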
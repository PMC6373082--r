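#' Bin variant calls along each chromosome
#'
#' Counts calls in fixed-width bins per chromosome. Bins are right-open
#' intervals with breaks at multiples of \code{binSize} applied to the
#' 1-based position (the \code{cut(..., right = FALSE)} convention), i.e. a
#' position lands in bin \code{pos \%/\% binSize}: positions 1 to
#' 9,999,999 fall in bin 0 and position 10,000,000 opens bin 1.
#' Per-chromosome bin counts sum to the chromosome's variant count.
#'
#' @param x a [GenotypeCalls-class] (or subclass) object.
#' @param binSize bin width in bp (default 10 Mb).
#' @param chromLengths optional named vector of chromosome lengths; when
#'   given, trailing empty bins up to the chromosome end are included.
#' @param ... unused.
#' @return a data.frame with columns \code{chrom}, \code{bin} (0-based
#'   index), \code{start}, \code{end} (1-based inclusive bounds),
#'   \code{count} and \code{label}; attribute \code{binSize}.
#' @examples
#' gc <- GenotypeCalls("KO", data.frame(
#'   chrom = "chr1", pos = c(1L, 9999999L, 10000000L), ref = "A",
#'   alt = "G", genotype = "hom_alt", qual = 50, depth = 20L,
#'   sampleId = "KO"))
#' binVariants(gc)$count  # 2 in bin 0, 1 in bin 1
#' @rdname binVariants
#' @export
setMethod("binVariants", "GenotypeCalls",
          function(x, binSize = 1e7, chromLengths = NULL, ...) {
  stopifnot(binSize > 0)
  d <- callData(x)
  out <- .binTable(d, binSize, chromLengths)
  out$label <- rep(x@label, nrow(out))
  attr(out, "binSize") <- binSize
  out
})

.binTable <- function(d, binSize, chromLengths = NULL) {
  if (nrow(d) == 0L)
    return(data.frame(chrom = character(), bin = integer(),
                      start = numeric(), end = numeric(),
                      count = integer()))
  bin <- d$pos %/% binSize
  res <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$chrom), function(i) {
    ch <- d$chrom[i[1]]
    nb <- max(bin[i]) + 1L
    if (!is.null(chromLengths) && ch %in% names(chromLengths))
      nb <- max(nb, chromLengths[[ch]] %/% binSize + 1)
    k <- seq_len(nb) - 1L
    data.frame(chrom = ch, bin = k,
               start = pmax(k * binSize, 1),
               end = (k + 1) * binSize - 1,
               count = tabulate(bin[i] + 1L, nbins = nb))
  }))
  rownames(res) <- NULL
  res
}

#' Cochran-Armitage trend test for a 2 x k count table
#'
#' Tests for a linear trend in the proportion of row-1 (e.g. KO) counts
#' across ordered bins. With per-bin counts \eqn{n_{1i}}, \eqn{n_{2i}},
#' column totals \eqn{c_i}, row totals \eqn{R_1, R_2}, grand total
#' \eqn{N} and scores \eqn{t_i}:
#' \deqn{T = \sum_i t_i (n_{1i} - c_i R_1/N), \quad
#'       Var(T) = \frac{R_1 R_2}{N^2}\left(\sum_i t_i^2 c_i -
#'                \frac{(\sum_i t_i c_i)^2}{N}\right)}
#' and \eqn{z = T/\sqrt{Var(T)}} is referred to the standard normal
#' (two-sided). \code{z} is invariant under positive affine transformations
#' of the scores and flips sign when the rows are swapped.
#'
#' @param row1,row2 non-negative integer count vectors of equal length
#'   (e.g. per-bin KO and WT variant counts).
#' @param scores numeric bin scores; default the 0-based bin index.
#' @return a list with \code{z}, \code{p} (two-sided asymptotic normal) and
#'   \code{degenerate} (TRUE when \code{Var(T) = 0}: all mass in one
#'   column or an empty row; then \code{z = 0}, \code{p = 1}).
#' @examples
#' cochranArmitage(c(0, 5, 10), c(10, 5, 0))  # strong opposite trend
#' cochranArmitage(c(5, 5, 5), c(5, 5, 5))    # z = 0, p = 1
#' @export
cochranArmitage <- function(row1, row2, scores = seq_along(row1) - 1) {
  stopifnot(length(row1) == length(row2), length(scores) == length(row1),
            all(row1 >= 0), all(row2 >= 0))
  cTot <- row1 + row2
  R1 <- sum(row1); R2 <- sum(row2); N <- R1 + R2
  if (N < 2) stop("need a grand total of at least 2")
  Tstat <- sum(scores * (row1 - cTot * R1 / N))
  V <- (R1 * R2 / N^2) * (sum(scores^2 * cTot) - sum(scores * cTot)^2 / N)
  if (!is.finite(V) || V <= 0)
    return(list(z = 0, p = 1, degenerate = TRUE))
  z <- Tstat / sqrt(V)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Trend-test every chromosome shared by two binned sets
#'
#' Builds a 2 x k contingency table per chromosome from the binned KO and
#' WT counts and applies [cochranArmitage()]. A chromosome with a
#' differential KO/WT variant distribution — the congenic-footprint signal
#' — shows a small p-value. The \code{significant} flag uses the raw
#' per-chromosome p (< \code{alpha}); Bonferroni-adjusted p across tested
#' chromosomes is reported alongside.
#'
#' @param binnedKo,binnedWt data.frames from [binVariants()] (same
#'   \code{binSize}); chromosomes are matched by name and a chromosome
#'   present on only one side is skipped with a warning.
#' @param alpha significance level for the raw-p flag (default 0.05).
#' @param scores \code{"bin_index"} (default) or \code{"bin_midpoint_bp"}.
#' @return a data.frame with columns \code{chrom}, \code{z},
#'   \code{p_value}, \code{p_adjusted} (Bonferroni), \code{significant}
#'   and \code{degenerate}, ordered by \code{p_value}.
#' @export
flagChromosomes <- function(binnedKo, binnedWt, alpha = 0.05,
                            scores = c("bin_index", "bin_midpoint_bp")) {
  scores <- match.arg(scores)
  bs1 <- attr(binnedKo, "binSize"); bs2 <- attr(binnedWt, "binSize")
  if (!is.null(bs1) && !is.null(bs2) && bs1 != bs2)
    stop("binned inputs use different bin sizes")
  shared <- intersect(unique(binnedKo$chrom), unique(binnedWt$chrom))
  only <- setdiff(union(unique(binnedKo$chrom), unique(binnedWt$chrom)),
                  shared)
  if (length(only))
    warning("chromosome(s) present in one genotype only, skipped: ",
            paste(only, collapse = ", "))
  if (length(shared) == 0L)
    return(data.frame(chrom = character(), z = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      significant = logical(), degenerate = logical()))
  res <- do.call(rbind, lapply(shared, function(ch) {
    ko <- binnedKo[binnedKo$chrom == ch, ]
    wt <- binnedWt[binnedWt$chrom == ch, ]
    nb <- max(max(ko$bin), max(wt$bin)) + 1L
    r1 <- r2 <- integer(nb)
    r1[ko$bin + 1L] <- ko$count
    r2[wt$bin + 1L] <- wt$count
    sc <- if (scores == "bin_index") seq_len(nb) - 1
          else (seq_len(nb) - 0.5) * if (is.null(bs1)) 1e7 else bs1
    ca <- cochranArmitage(r1, r2, sc)
    data.frame(chrom = ch, z = ca$z, p_value = ca$p,
               degenerate = ca$degenerate)
  }))
  res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$chrom),
             c("chrom", "z", "p_value", "p_adjusted", "significant",
               "degenerate")]
  rownames(res) <- NULL
  res
}

#' Physical extent of the KO-linked footprint on a chromosome
#'
#' The min/max envelope of KO-linked variant positions on the chromosome,
#' by default restricted to homozygous (hom_alt) calls — the donor-derived
#' segment fixed in the line. An optional gap-tolerant mode trims the
#' envelope to bins actually occupied by qualifying variants, allowing at
#' most one empty internal bin, for robustness to isolated outliers.
#'
#' @param koLinked a [KoLinkedCalls-class] object (any call set works).
#' @param chrom chromosome to measure.
#' @param ploidyFilter \code{"homozygous_only"} (default) or \code{"all"}.
#' @param gapTolerant if TRUE, drop leading/trailing empty bins and outlier
#'   variants separated from the main run by more than one empty bin.
#' @param binSize bin width used by the gap-tolerant mode (default 10 Mb).
#' @return numeric vector \code{c(startBp, endBp)} (1-based inclusive).
#' @export
estimateFootprintInterval <- function(koLinked, chrom,
                                      ploidyFilter = c("homozygous_only",
                                                       "all"),
                                      gapTolerant = FALSE, binSize = 1e7) {
  ploidyFilter <- match.arg(ploidyFilter)
  d <- callData(koLinked)
  d <- d[d$chrom == chrom, , drop = FALSE]
  if (ploidyFilter == "homozygous_only")
    d <- d[d$genotype == "hom_alt", , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no qualifying KO-linked variant on ", chrom,
         " under filter '", ploidyFilter, "'")
  if (gapTolerant && nrow(d) > 1L) {
    bins <- sort(unique(d$pos %/% binSize))
    # longest run of occupied bins with internal gaps of <= 1 empty bin
    runs <- split(bins, cumsum(c(1, diff(bins) > 2)))
    best <- runs[[which.max(vapply(runs, length, integer(1)))]]
    d <- d[d$pos %/% binSize %in% seq(min(best), max(best)), ,
           drop = FALSE]
  }
  c(startBp = min(d$pos), endBp = max(d$pos))
}

#' Read a genetic map from TSV
#'
#' Expects a header line \code{chrom bp cM} followed by anchor rows; each
#' chromosome needs at least two anchors strictly increasing in bp and cM.
#'
#' @param path path to the TSV file.
#' @param fallbackRate constant rate in cM/Mb for chromosomes absent from
#'   the map (default 0.5); \code{NA} disables the fallback so that a
#'   missing chromosome is an error in [physicalToGenetic()].
#' @return a [GeneticMap-class] object.
#' @export
readGeneticMap <- function(path, fallbackRate = 0.5) {
  a <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("chrom", "bp", "cM") %in% colnames(a)))
    stop("genetic map needs columns: chrom, bp, cM (got: ",
         paste(colnames(a), collapse = ", "), ")")
  GeneticMap(a, fallbackRate = fallbackRate)
}

#' @rdname GeneticMap-class
#' @param anchors data.frame with columns \code{chrom}, \code{bp},
#'   \code{cM}.
#' @param fallbackRate constant cM/Mb rate for unmapped chromosomes
#'   (\code{NA} to disable).
#' @export
GeneticMap <- function(anchors = NULL, fallbackRate = 0.5) {
  if (is.null(anchors))
    anchors <- data.frame(chrom = character(), bp = numeric(),
                          cM = numeric())
  anchors <- anchors[order(anchors$chrom, anchors$bp), , drop = FALSE]
  rownames(anchors) <- NULL
  new("GeneticMap", anchors = anchors,
      fallbackRate = as.numeric(fallbackRate))
}

#' Convert physical to genetic-map position
#'
#' Linear interpolation between the flanking map anchors; outside the
#' anchor range, linear extrapolation with the terminal segment's slope.
#' For a chromosome absent from the map, the constant fallback rate is
#' used when enabled, otherwise an error is raised. Monotone
#' non-decreasing in bp.
#'
#' @param map a [GeneticMap-class] object.
#' @param chrom chromosome name.
#' @param bp physical position(s), 1-based bp; vectorized.
#' @return genetic position(s) in cM.
#' @examples
#' m <- GeneticMap(data.frame(chrom = "chr1", bp = c(0, 1e7),
#'                            cM = c(0, 5)))
#' physicalToGenetic(m, "chr1", 5e6)  # 2.5
#' @rdname physicalToGenetic
#' @export
setMethod("physicalToGenetic", "GeneticMap", function(map, chrom, bp) {
  a <- map@anchors[map@anchors$chrom == chrom, , drop = FALSE]
  if (nrow(a) < 2L) {
    if (is.na(map@fallbackRate))
      stop("chromosome '", chrom, "' absent from the genetic map and the ",
           "constant-rate fallback is disabled")
    return(bp / 1e6 * map@fallbackRate)
  }
  .interpExtrap(a$bp, a$cM, bp)
})

.interpExtrap <- function(xs, ys, x) {
  y <- stats::approx(xs, ys, xout = x, rule = 2)$y
  n <- length(xs)
  loSlope <- (ys[2] - ys[1]) / (xs[2] - xs[1])
  hiSlope <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
  lo <- x < xs[1]; hi <- x > xs[n]
  y[lo] <- ys[1] + (x[lo] - xs[1]) * loSlope
  y[hi] <- ys[n] + (x[hi] - xs[n]) * hiSlope
  y
}

# inverse of physicalToGenetic, used by the simulator
.geneticToPhysical <- function(map, chrom, cm) {
  a <- map@anchors[map@anchors$chrom == chrom, , drop = FALSE]
  if (nrow(a) < 2L) {
    if (is.na(map@fallbackRate))
      stop("chromosome '", chrom, "' absent from the genetic map")
    return(cm / map@fallbackRate * 1e6)
  }
  .interpExtrap(a$cM, a$bp, cm)
}

#' Estimate the number of backcross generations from footprint extent
#'
#' Inverts the expected-footprint rule cM = 200/N: the expected donor
#' segment retained around a locus selected through N backcross
#' generations spans about 200/N centimorgans, so
#' \code{N = round(200 / extentCM)}, with a minimum of 1. Monotone
#' non-increasing in the extent.
#'
#' @param extentCM footprint extent in centimorgans (> 0); vectorized.
#' @return integer estimate(s) of N.
#' @examples
#' estimateBackcrossGenerations(42.14)  # 5
#' estimateBackcrossGenerations(11.94)  # 17
#' @export
estimateBackcrossGenerations <- function(extentCM) {
  if (any(!is.finite(extentCM)) || any(extentCM <= 0))
    stop("extentCM must be positive and finite")
  pmax(1L, as.integer(round(200 / extentCM)))
}

#' Full footprint summary for one chromosome
#'
#' Convenience wrapper: physical envelope of the homozygous KO-linked
#' variants, genetic-map extent, and the backcross-generation estimate.
#'
#' @inheritParams estimateFootprintInterval
#' @param map a [GeneticMap-class] object.
#' @return a [FootprintInterval-class] object.
#' @export
estimateFootprint <- function(koLinked, chrom, map,
                              ploidyFilter = "homozygous_only",
                              gapTolerant = FALSE, binSize = 1e7) {
  iv <- estimateFootprintInterval(koLinked, chrom, ploidyFilter,
                                  gapTolerant = gapTolerant,
                                  binSize = binSize)
  cm <- physicalToGenetic(map, chrom, iv)
  extent <- abs(cm[2] - cm[1])
  n <- if (extent > 0) estimateBackcrossGenerations(extent) else NA_integer_
  if (is.na(n))
    stop("zero-width footprint on ", chrom,
         ": cannot estimate backcross generations")
  new("FootprintInterval", chrom = chrom, startBp = iv[[1]],
      endBp = iv[[2]], extentCM = extent, estimatedN = n)
}

#' Write footprint intervals as BED and TSV
#'
#' BED uses 0-based half-open coordinates (converted from the 1-based
#' inclusive interval); the TSV report carries extent_cM and estimated_N.
#'
#' @param footprints a list of [FootprintInterval-class] objects.
#' @param bedPath,tsvPath output paths (either may be NULL to skip).
#' @return invisibly, a data.frame of the report rows.
#' @export
writeFootprintReport <- function(footprints, bedPath = NULL,
                                 tsvPath = NULL) {
  if (is(footprints, "FootprintInterval")) footprints <- list(footprints)
  rows <- do.call(rbind, lapply(footprints, function(f)
    data.frame(chrom = f@chrom, start_bp = f@startBp, end_bp = f@endBp,
               extent_cM = f@extentCM, estimated_N = f@estimatedN)))
  if (!is.null(bedPath)) {
    bed <- sprintf("%s\t%d\t%d\tfootprint\t%d", rows$chrom,
                   as.integer(rows$start_bp - 1), as.integer(rows$end_bp),
                   rows$estimated_N)
    writeLines(bed, bedPath)
  }
  if (!is.null(tsvPath))
    utils::write.table(rows, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(rows)
}
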
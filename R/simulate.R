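# --- interval helpers (2-column matrices of [start, end) in cM) ----------

.emptyIv <- matrix(numeric(0), 0, 2)

.ivClip <- function(iv, a, b) {
  if (nrow(iv) == 0L) return(.emptyIv)
  s <- pmax(iv[, 1], a); e <- pmin(iv[, 2], b)
  keep <- s < e
  cbind(s[keep], e[keep])
}

.ivContains <- function(iv, x)
  nrow(iv) > 0L && any(iv[, 1] <= x & x < iv[, 2])

# one meiosis: recombine haplotypes A and B (donor-interval matrices) over
# a chromosome of genetic length L cM; crossovers are a Poisson process at
# 1 per 100 cM (Haldane, no interference); returns the gamete's donor
# intervals
.meiosis <- function(hapA, hapB, L) {
  k <- stats::rpois(1L, L / 100)
  bounds <- c(0, sort(stats::runif(k, 0, L)), L)
  takeA <- (sample.int(2L, 1L) + seq_len(length(bounds) - 1L)) %% 2L == 0L
  segs <- vector("list", length(bounds) - 1L)
  for (i in seq_along(segs)) {
    src <- if (takeA[i]) hapA else hapB
    segs[[i]] <- .ivClip(src, bounds[i], bounds[i + 1L])
  }
  m <- do.call(rbind, segs)
  if (is.null(m) || nrow(m) == 0L) return(.emptyIv)
  m <- m[order(m[, 1]), , drop = FALSE]
  # merge abutting pieces
  keep <- c(TRUE, m[-1L, 1] > m[-nrow(m), 2] + 1e-12)
  out <- list(); cur <- m[1L, ]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1] <= cur[2] + 1e-12) cur[2] <- max(cur[2], m[i, 2])
    else { out[[length(out) + 1L]] <- cur; cur <- m[i, ] }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

# --- configuration --------------------------------------------------------

#' Configure a backcross-breeding simulation
#'
#' Defines the cohort the simulator emulates: a donor-strain (ES-cell)
#' genome introgressed into a recipient inbred background through
#' \code{nBackcross} generations of backcrossing with selection for the
#' targeted allele, followed by an intercross that fixes the carrier
#' footprint haplotype (KO homozygous, het littermate heterozygous, WT
#' recipient-only). Donor variants are a Poisson process along each
#' chromosome; shared recipient-background calls and per-sample novel
#' ("drift") calls model the non-introgressed variation seen in real
#' call sets.
#'
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param targetChrom,targetPos the targeted locus.
#' @param nBackcross number of backcross generations N (>= 1).
#' @param donorDensity donor variant density, variants/Mb (default 1).
#' @param backgroundDensity density of recipient-background variants
#'   shared by every sample, variants/Mb (default 0.1, giving the roughly
#'   ten-fold footprint-to-background bin contrast seen in real cohorts).
#' @param driftDensity density of novel homozygous variants private to
#'   each sample, variants/Mb (default 0.02).
#' @param nWT,nHet,nKO samples per genotype (defaults 1/1/3).
#' @param dropout genotyping dropout rate in [0, 1) (default 0).
#' @param depthMean mean emitted read depth (Poisson; default 30).
#' @param qualMean mean emitted Phred site quality (gamma; default 60).
#' @param rateCMperMb constant genetic-map rate used when \code{map} is
#'   NULL (default 0.5 cM/Mb).
#' @param map optional [GeneticMap-class] overriding the constant rate.
#' @param intercross if TRUE (default) KO samples are homozygous for the
#'   final carrier haplotype; if FALSE they are heterozygous carriers
#'   (no intercross performed).
#' @param seed integer seed; identical seed and config give identical
#'   output.
#' @return a validated config (list of class \code{CongenicSimConfig}).
#' @examples
#' cfg <- simConfig(nBackcross = 10, seed = 1)
#' sim <- simulateCongenicCohort(cfg)
#' sim$truth$footprint
#' @export
simConfig <- function(chromLengths = c(chr1 = 190e6, chr2 = 180e6,
                                       chr3 = 160e6, chr4 = 150e6,
                                       chr14 = 125e6),
                      targetChrom = "chr14", targetPos = 52.3e6,
                      nBackcross = 10L, donorDensity = 1.0,
                      backgroundDensity = 0.1, driftDensity = 0.02,
                      nWT = 1L, nHet = 1L, nKO = 3L, dropout = 0,
                      depthMean = 30, qualMean = 60, rateCMperMb = 0.5,
                      map = NULL, intercross = TRUE, seed = NULL) {
  stopifnot(length(chromLengths) >= 1L, !is.null(names(chromLengths)),
            all(chromLengths > 0))
  if (!targetChrom %in% names(chromLengths))
    stop("targetChrom '", targetChrom, "' not among chromLengths")
  if (targetPos < 1 || targetPos > chromLengths[[targetChrom]])
    stop("targetPos outside ", targetChrom)
  stopifnot(nBackcross >= 1L, donorDensity > 0, backgroundDensity >= 0,
            driftDensity >= 0, nWT >= 0L, nHet >= 0L, nKO >= 0L,
            dropout >= 0, dropout < 1, depthMean > 0, qualMean > 0)
  if (is.null(map)) {
    stopifnot(rateCMperMb > 0)
    anchors <- data.frame(
      chrom = rep(names(chromLengths), each = 2L),
      bp = as.vector(rbind(0, unname(chromLengths))),
      cM = as.vector(rbind(0, unname(chromLengths) / 1e6 * rateCMperMb)))
    map <- GeneticMap(anchors, fallbackRate = rateCMperMb)
  }
  structure(list(chromLengths = chromLengths, targetChrom = targetChrom,
                 targetPos = targetPos, nBackcross = as.integer(nBackcross),
                 donorDensity = donorDensity,
                 backgroundDensity = backgroundDensity,
                 driftDensity = driftDensity, nWT = as.integer(nWT),
                 nHet = as.integer(nHet), nKO = as.integer(nKO),
                 dropout = dropout, depthMean = depthMean,
                 qualMean = qualMean, map = map, intercross = intercross,
                 seed = seed),
            class = "CongenicSimConfig")
}

.NUC <- c("A", "C", "G", "T")

.poissonSites <- function(chromLengths, density) {
  do.call(rbind, lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    n <- stats::rpois(1L, len / 1e6 * density)
    if (n == 0L)
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character()))
    pos <- sort(unique(as.integer(ceiling(stats::runif(n, 0, len)))))
    ref <- sample(.NUC, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(.NUC, r), 1L), "")
    data.frame(chrom = ch, pos = pos, ref = ref, alt = unname(alt))
  }))
}

# concentrated around qualMean (CV ~ 0.22) so that missingness is governed
# by the dropout parameter, not by incidental sub-threshold qualities
.emitQuals <- function(n, qualMean)
  round(stats::rgamma(n, shape = 20, rate = 20 / qualMean), 1)

#' Simulate a congenic cohort with a known footprint
#'
#' Realizes the breeding process summarized by the cM = 200/N rule:
#' starting from an F1 carrying a full donor haplotype, each backcross
#' generation recombines the carrier haplotype against the recipient
#' (crossovers Poisson at 1 per 100 cM on the genetic-map scale) and
#' selects an offspring carrying the targeted allele; after N generations
#' the carrier haplotype is fixed by intercross. Emits one call set per
#' sample plus a ground-truth record, and optionally writes per-sample
#' VCFs, the genetic map and a truth JSON.
#'
#' @param config a config from [simConfig()].
#' @param outDir optional directory; when given, per-sample VCF v4.2
#'   files, \code{genetic_map.tsv} and \code{truth.json} are written.
#' @return a list with \code{samples} (named list of
#'   [GenotypeCalls-class], labels WT/HET/KO), \code{truth} (list:
#'   \code{trueN}, \code{footprint} = chrom/startBp/endBp/extentCM of the
#'   contiguous donor segment containing the target,
#'   \code{envelope} = outermost donor material on the target chromosome,
#'   \code{donorSegments} per chromosome in bp, \code{variants} with true
#'   origin, \code{map}), and \code{files} when \code{outDir} is given.
#' @export
simulateCongenicCohort <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "CongenicSimConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  chroms <- names(config$chromLengths)
  map <- config$map
  Lcm <- vapply(chroms, function(ch)
    physicalToGenetic(map, ch, config$chromLengths[[ch]]), 0)
  targetCM <- physicalToGenetic(map, config$targetChrom, config$targetPos)

  # breeding chain: carrier haplotype per chromosome, cM intervals
  hap <- lapply(chroms, function(ch) matrix(c(0, Lcm[[ch]]), 1, 2))
  names(hap) <- chroms
  for (gen in seq_len(config$nBackcross)) {
    for (ch in chroms) {
      if (ch == config$targetChrom) {
        repeat {
          g <- .meiosis(hap[[ch]], .emptyIv, Lcm[[ch]])
          if (.ivContains(g, targetCM)) break
        }
      } else {
        g <- .meiosis(hap[[ch]], .emptyIv, Lcm[[ch]])
      }
      hap[[ch]] <- g
    }
  }

  donorSegBp <- lapply(chroms, function(ch) {
    iv <- hap[[ch]]
    if (nrow(iv) == 0L) return(data.frame(startBp = numeric(),
                                          endBp = numeric()))
    data.frame(startBp = .geneticToPhysical(map, ch, iv[, 1]),
               endBp = .geneticToPhysical(map, ch, iv[, 2]))
  })
  names(donorSegBp) <- chroms

  # ground-truth footprint: the contiguous donor segment containing the
  # target, plus the envelope of all donor material on the target chrom
  tIv <- hap[[config$targetChrom]]
  hit <- which(tIv[, 1] <= targetCM & targetCM < tIv[, 2])
  segCM <- tIv[hit, ]
  footprint <- list(
    chrom = config$targetChrom,
    startBp = .geneticToPhysical(map, config$targetChrom, segCM[1]),
    endBp = .geneticToPhysical(map, config$targetChrom, segCM[2]),
    startCM = segCM[1], endCM = segCM[2],
    extentCM = segCM[2] - segCM[1])
  envelope <- list(
    startCM = min(tIv[, 1]), endCM = max(tIv[, 2]),
    extentCM = max(tIv[, 2]) - min(tIv[, 1]))

  donor <- .poissonSites(config$chromLengths, config$donorDensity)
  background <- .poissonSites(config$chromLengths,
                              config$backgroundDensity)
  # donor/background collisions at the same position: drop from background
  if (nrow(background))
    background <- background[!paste(background$chrom, background$pos) %in%
                               paste(donor$chrom, donor$pos), , drop = FALSE]
  inHap <- logical(nrow(donor))
  for (ch in chroms) {
    i <- which(donor$chrom == ch)
    if (!length(i)) next
    cm <- physicalToGenetic(map, ch, donor$pos[i])
    iv <- hap[[ch]]
    inHap[i] <- vapply(cm, function(x) .ivContains(iv, x), logical(1))
  }

  sampleDefs <- data.frame(
    id = c(sprintf("wt%d", seq_len(config$nWT)),
           sprintf("het%d", seq_len(config$nHet)),
           sprintf("ko%d", seq_len(config$nKO))),
    label = rep(c("WT", "HET", "KO"),
                c(config$nWT, config$nHet, config$nKO)))

  koCopies <- if (config$intercross) 2L else 1L
  samples <- vector("list", nrow(sampleDefs))
  names(samples) <- sampleDefs$id
  for (i in seq_len(nrow(sampleDefs))) {
    lab <- sampleDefs$label[i]
    copies <- switch(lab, WT = 0L, HET = 1L, KO = koCopies)
    rows <- list()
    if (copies > 0L && any(inHap)) {
      dv <- donor[inHap, , drop = FALSE]
      dv$genotype <- if (copies == 2L) "hom_alt" else "het"
      rows[[length(rows) + 1L]] <- dv
    }
    if (nrow(background)) {
      bg <- background
      bg$genotype <- "hom_alt"
      rows[[length(rows) + 1L]] <- bg
    }
    if (config$driftDensity > 0) {
      dr <- .poissonSites(config$chromLengths, config$driftDensity)
      if (nrow(dr)) {
        dr$genotype <- "hom_alt"
        rows[[length(rows) + 1L]] <- dr
      }
    }
    calls <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), genotype = character())
    # drop duplicate positions (drift may collide with other classes)
    calls <- calls[!duplicated(paste(calls$chrom, calls$pos)), ,
                   drop = FALSE]
    if (config$dropout > 0 && nrow(calls))
      calls <- calls[stats::runif(nrow(calls)) >= config$dropout, ,
                     drop = FALSE]
    n <- nrow(calls)
    calls$qual <- .emitQuals(n, config$qualMean)
    calls$depth <- stats::rpois(n, config$depthMean)
    calls$sampleId <- rep(sampleDefs$id[i], n)
    samples[[i]] <- GenotypeCalls(lab, calls)
  }

  variants <- rbind(
    if (nrow(donor)) cbind(donor, origin = "donor",
                           inFootprintHaplotype = inHap),
    if (nrow(background)) cbind(background, origin = "background",
                                inFootprintHaplotype = FALSE))
  truth <- list(trueN = config$nBackcross, footprint = footprint,
                envelope = envelope, donorSegments = donorSegBp,
                variants = variants, map = map,
                sampleLabels = stats::setNames(sampleDefs$label,
                                               sampleDefs$id))
  out <- list(samples = samples, truth = truth)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (id in names(samples)) {
      f <- file.path(outDir, paste0(id, ".vcf"))
      writeCallsVcf(samples[[id]], f, contigs = config$chromLengths)
      files[id] <- f
    }
    mapFile <- file.path(outDir, "genetic_map.tsv")
    utils::write.table(map@anchors, mapFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truthFile <- file.path(outDir, "truth.json")
    jsonlite::write_json(
      list(trueN = truth$trueN, footprint = truth$footprint,
           envelope = truth$envelope,
           donorSegments = truth$donorSegments,
           variants = truth$variants,
           sampleLabels = as.list(truth$sampleLabels)),
      truthFile, auto_unbox = TRUE, digits = NA)
    out$files <- c(files, map = mapFile, truth = truthFile)
  }
  out
}

#' Simulate a genotype-dependent normalized count table
#'
#' Expression = intercept + slope * genotype code + noise, per gene;
#' Gaussian or log-normal noise. A fixture generator for the eQTL screen
#' with known truth.
#'
#' @param slopes numeric vector of true slopes, one per gene.
#' @param genotypes genotype labels (WT/HET/KO) or numeric codes, one per
#'   sample.
#' @param intercepts per-gene intercepts (default 10).
#' @param sigma noise standard deviation (> 0; default 1).
#' @param noise \code{"gaussian"} (default) or \code{"lognormal"}
#'   (multiplicative: mean * exp(N(0, sigma))).
#' @param seed optional integer seed.
#' @return a list with \code{counts} (genes x samples matrix, floored at
#'   0), \code{genotypes} (codes) and \code{truth} (data.frame of gene,
#'   slope, intercept).
#' @examples
#' tab <- simulateCountTable(c(8, 0), c("WT", "WT", "HET", "KO", "KO"),
#'                           seed = 1)
#' screenEqtl(tab$counts, tab$genotypes)
#' @export
simulateCountTable <- function(slopes, genotypes, intercepts = 10,
                               sigma = 1, noise = c("gaussian",
                                                    "lognormal"),
                               seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(slopes) >= 1L, sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(genotypes)) genotypes <- encodeGenotypes(genotypes)
  g <- length(slopes); n <- length(genotypes)
  intercepts <- rep_len(intercepts, g)
  mu <- outer(slopes, genotypes) + intercepts
  counts <- if (noise == "gaussian") {
    mu + matrix(stats::rnorm(g * n, 0, sigma), g, n)
  } else {
    mu * exp(matrix(stats::rnorm(g * n, 0, sigma), g, n))
  }
  counts <- pmax(counts, 0)
  rownames(counts) <- sprintf("gene%04d", seq_len(g))
  colnames(counts) <- sprintf("s%02d", seq_len(n))
  list(counts = counts, genotypes = genotypes,
       truth = data.frame(gene = rownames(counts), slope = slopes,
                          intercept = intercepts))
}
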
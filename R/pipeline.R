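#' @importFrom ggplot2 .data
NULL

#' Run the full background-characterization pipeline
#'
#' Executes, in order: hard filtering, per-genotype replicate
#' intersection, optional recipient-reference subtraction and donor-origin
#' annotation, KO-linked dissection, 10-Mb binning, per-chromosome
#' Cochran-Armitage scan, footprint interval / cM extent / backcross-N
#' estimation on each significant chromosome, and per-sample ploidy
#' profiles. Writes TSV/BED/VCF outputs, per-chromosome WT-vs-KO and
#' ploidy histograms, and a machine-readable JSON summary. Any stage
#' error aborts with the stage name.
#'
#' @param wtPaths,koPaths VCF paths (or pre-read [GenotypeCalls-class]
#'   objects) for the WT and KO samples; at least one of each.
#' @param hetPaths optional het-littermate VCFs (or objects) used for
#'   Mendelian annotation of the KO-linked set.
#' @param recipientRef,donorRef optional strain reference VCF paths (or
#'   objects): recipient variants are subtracted, donor variants drive
#'   origin annotation.
#' @param map a [GeneticMap-class] object, or a path readable by
#'   [readGeneticMap()]; required for footprint estimation.
#' @param outDir output directory (created if needed).
#' @param binSize bin width in bp (default 10 Mb).
#' @param alpha significance level for the chromosome scan (default 0.05).
#' @param minDepth,minQual hard-filter thresholds (defaults 10 / 30).
#' @param genotypePolicy replicate consensus policy, \code{"strict"} or
#'   \code{"majority"}.
#' @param chromMap optional chromosome-rename mapping applied to the
#'   reference sets (see [renameChromosomes()]).
#' @param plots if TRUE (default) write per-chromosome histogram panels.
#' @return invisibly, a list with the consensus sets, the KO-linked set,
#'   the scan table, the footprint intervals, the ploidy profiles, the
#'   Mendelian annotation (when het samples were given) and the summary
#'   written to \code{summary.json}.
#' @export
runPipeline <- function(wtPaths, koPaths, hetPaths = NULL,
                        recipientRef = NULL, donorRef = NULL, map = NULL,
                        outDir = "congenic-scan-out", binSize = 1e7,
                        alpha = 0.05, minDepth = 10, minQual = 30,
                        genotypePolicy = "strict", chromMap = NULL,
                        plots = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  asSets <- function(x, label) {
    if (is.null(x)) return(NULL)
    if (is(x, "GenotypeCalls")) return(list(x))
    if (is.list(x) && all(vapply(x, is, logical(1), "GenotypeCalls")))
      return(x)
    lapply(x, function(p) {
      s <- readGenotypeVcf(p)
      s@label <- label
      s
    })
  }
  if (length(wtPaths) < 1L || length(koPaths) < 1L)
    stop("need at least one WT and one KO input")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(map)) map <- readGeneticMap(map)

  wt <- stage("read/filter WT", lapply(asSets(wtPaths, "WT"),
                                       applyHardFilters,
                                       minDepth = minDepth,
                                       minQual = minQual))
  ko <- stage("read/filter KO", lapply(asSets(koPaths, "KO"),
                                       applyHardFilters,
                                       minDepth = minDepth,
                                       minQual = minQual))
  het <- stage("read/filter HET",
               lapply(asSets(hetPaths, "HET") %||% list(),
                      applyHardFilters, minDepth = minDepth,
                      minQual = minQual))

  wtCons <- stage("intersect WT", intersectReplicates(wt, genotypePolicy))
  koCons <- stage("intersect KO", intersectReplicates(ko, genotypePolicy))

  refSet <- function(r, label) {
    if (is.null(r)) return(NULL)
    s <- if (is(r, "GenotypeCalls")) r else readGenotypeVcf(r, label = label)
    if (!is.null(chromMap)) s <- renameChromosomes(s, mapping = chromMap)
    s
  }
  rec <- stage("read recipient reference", refSet(recipientRef, "recipient"))
  don <- stage("read donor reference", refSet(donorRef, "donor"))
  if (!is.null(rec)) {
    wtCons <- stage("subtract recipient", subtractReference(wtCons, rec))
    koCons <- stage("subtract recipient", subtractReference(koCons, rec))
  }
  origin <- if (!is.null(don))
    stage("annotate donor origin", annotateStrainOrigin(koCons, don))

  koLinked <- stage("dissect KO-linked", dissectKoLinked(koCons, wtCons))

  binnedWt <- stage("bin WT", binVariants(wtCons, binSize))
  binnedKo <- stage("bin KO", binVariants(koCons, binSize))
  scan <- stage("chromosome scan",
                flagChromosomes(binnedKo, binnedWt, alpha = alpha))

  sigChroms <- scan$chrom[scan$significant]
  footprints <- list()
  if (!is.null(map)) {
    for (ch in sigChroms) {
      fp <- tryCatch(estimateFootprint(koLinked, ch, map),
                     error = function(e) NULL)
      if (!is.null(fp)) footprints[[ch]] <- fp
    }
  }

  ploidy <- stage("ploidy profiles",
                  do.call(rbind, lapply(ko, ploidyProfile,
                                        binSize = binSize)))
  mendel <- NULL
  if (length(het) && nCalls(koLinked) > 0L)
    mendel <- stage("Mendelian annotation",
                    mendelianAnnotate(koLinked, het[[1]], wt[[1]]))

  # --- outputs ---
  stage("write outputs", {
    writeCallsVcf(koLinked, file.path(outDir, "ko_linked.vcf"))
    writeCallsTsv(koLinked, file.path(outDir, "ko_linked.tsv"))
    if (!is.null(origin))
      writeCallsTsv(origin, file.path(outDir, "origin_annotated.tsv"))
    utils::write.table(scan, file.path(outDir, "trend_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ploidy, file.path(outDir, "ploidy_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(footprints))
      writeFootprintReport(footprints,
                           bedPath = file.path(outDir, "footprint.bed"),
                           tsvPath = file.path(outDir, "footprint.tsv"))
    if (!is.null(mendel))
      utils::write.table(
        data.frame(n_ko_linked = mendel$nKoLinked,
                   n_annotated = mendel$nAnnotated,
                   coverage = mendel$variantCoverage),
        file.path(outDir, "mendelian_annotation.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
  })
  if (plots)
    stage("plots", {
      plotGenomeHistograms(binnedKo, binnedWt, outDir = outDir)
      if (nCalls(koLinked) > 0L)
        plotPloidyHistograms(ploidyProfile(koLinked, binSize),
                             outDir = outDir)
    })

  summary <- list(
    n_wt_consensus = nCalls(wtCons), n_ko_consensus = nCalls(koCons),
    n_ko_linked = nCalls(koLinked),
    scan = scan,
    significant_chromosomes = sigChroms,
    footprints = lapply(footprints, function(f)
      list(chrom = f@chrom, start_bp = f@startBp, end_bp = f@endBp,
           extent_cM = f@extentCM, estimated_N = f@estimatedN)),
    mendelian = if (!is.null(mendel))
      mendel[c("nKoLinked", "nAnnotated", "variantCoverage")],
    empty_footprint = nCalls(koLinked) == 0L)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(wtConsensus = wtCons, koConsensus = koCons,
                 koLinked = koLinked, origin = origin, scan = scan,
                 footprints = footprints, ploidy = ploidy,
                 mendelian = mendel, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genome-wide paired variant histograms
#'
#' One panel per chromosome of per-bin variant counts, the two genotypes
#' side by side — the genome-wide view in which a congenic footprint shows
#' as a genotype-specific pile-up. Writes a single faceted figure with a
#' deterministic name.
#'
#' @param binnedKo,binnedWt data.frames from [binVariants()].
#' @param outDir output directory.
#' @param file file name (default \code{genome_histograms.png}).
#' @return invisibly, the ggplot object.
#' @export
plotGenomeHistograms <- function(binnedKo, binnedWt, outDir = ".",
                                 file = "genome_histograms.png") {
  d <- rbind(binnedKo, binnedWt)
  if (nrow(d) == 0L) return(invisible(NULL))
  d$mb <- (d$start + d$end) / 2 / 1e6
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mb, y = .data$count,
                                       fill = .data$label)) +
    ggplot2::geom_col(position = "dodge", width = 8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "variants per bin",
                  fill = "genotype") +
    ggplot2::theme_bw()
  ggplot2::ggsave(file.path(outDir, file), p, width = 10, height = 6,
                  dpi = 120)
  invisible(p)
}

#' Ploidy-coloured footprint histograms
#'
#' Per-chromosome histograms of homozygous vs heterozygous calls from a
#' [ploidyProfile()] table, the view used to read footprint zygosity.
#'
#' @param profile data.frame from [ploidyProfile()].
#' @param outDir output directory.
#' @param file file name (default \code{ploidy_histograms.png}).
#' @return invisibly, the ggplot object.
#' @export
plotPloidyHistograms <- function(profile, outDir = ".",
                                 file = "ploidy_histograms.png") {
  if (nrow(profile) == 0L) return(invisible(NULL))
  long <- rbind(
    data.frame(chrom = profile$chrom, mb = (profile$start +
                 profile$end) / 2 / 1e6, count = profile$hom,
               ploidy = "homozygous"),
    data.frame(chrom = profile$chrom, mb = (profile$start +
                 profile$end) / 2 / 1e6, count = profile$het,
               ploidy = "heterozygous"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mb, y = .data$count,
                                          fill = .data$ploidy)) +
    ggplot2::geom_col(position = "dodge", width = 8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(homozygous = "#c0392b",
                                          heterozygous = "#2980b9")) +
    ggplot2::labs(x = "position (Mb)", y = "variants per bin") +
    ggplot2::theme_bw()
  ggplot2::ggsave(file.path(outDir, file), p, width = 10, height = 6,
                  dpi = 120)
  invisible(p)
}
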
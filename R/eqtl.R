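#' Encode genotype labels as gene-dosage codes
#'
#' The conventional coding for the expression-on-genotype regression:
#' WT = 1, HET = 0.5, KO = 0 (fraction of functional target-gene dose).
#'
#' @param labels character vector over \code{WT}, \code{HET}, \code{KO}.
#' @return numeric codes.
#' @examples
#' encodeGenotypes(c("WT", "HET", "KO"))  # 1.0 0.5 0.0
#' @export
encodeGenotypes <- function(labels) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  codes <- c(WT = 1, HET = 0.5, KO = 0)
  bad <- setdiff(unique(labels), names(codes))
  if (length(bad))
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "),
         " (expected WT/HET/KO)")
  unname(codes[labels])
}

#' Screen genes for linear expression-genotype dependence (eQTL candidates)
#'
#' Per gene, ordinary least squares of normalized expression on the
#' genotype code; the p-value is the two-sided t-test of slope = 0 with
#' n - 2 degrees of freedom. Genes with \code{p < alpha} are selected. A
#' congenic gene whose expression tracks genotype dose is a candidate
#' modifier gene (cis-eQTL within the footprint). The table must already
#' be normalized; no normalization is applied here.
#'
#' @param counts numeric matrix, genes x samples, normalized non-negative
#'   expression; rownames are gene identifiers.
#' @param genotypes genotype labels (WT/HET/KO) or numeric codes, one per
#'   column of \code{counts}. At least two distinct codes and three
#'   samples are required; with only WT/KO samples the regression
#'   degenerates to a two-group comparison (allowed, flagged by the
#'   \code{twoGroup} attribute).
#' @param alpha selection level on the raw p (default 0.05, matching the
#'   both-conditions selection strategy); set \code{adjust = "BH"} for
#'   Benjamini-Hochberg selection instead.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return a data.frame with columns \code{gene}, \code{slope},
#'   \code{intercept}, \code{p_value}, \code{selected} and
#'   \code{perfect_fit} (zero residual variance with nonzero slope: p is
#'   reported as the smallest representable positive value).
#' @examples
#' x <- c("WT", "WT", "HET", "HET", "KO", "KO")
#' m <- rbind(dosage = c(10, 9, 6, 5, 2, 1), flat = rep(3, 6))
#' screenEqtl(m, x)
#' @export
screenEqtl <- function(counts, genotypes, alpha = 0.05,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  counts <- as.matrix(counts)
  if (is.character(genotypes)) genotypes <- encodeGenotypes(genotypes)
  n <- ncol(counts)
  stopifnot(length(genotypes) == n)
  if (n < 3L) stop("need at least 3 samples")
  if (length(unique(genotypes)) < 2L)
    stop("all samples share one genotype code; the slope is undefined")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))

  x <- genotypes - mean(genotypes)
  sxx <- sum(x^2)
  slope <- as.vector(counts %*% x) / sxx
  intercept <- rowMeans(counts) - slope * mean(genotypes)
  fitted <- outer(slope, genotypes) + intercept
  rss <- rowSums((counts - fitted)^2)
  df <- n - 2L
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(tstat), df)
  perfect <- se == 0 & slope != 0
  p[perfect] <- .Machine$double.xmin
  pSel <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  res <- data.frame(gene = rownames(counts), slope = slope,
                    intercept = intercept, p_value = p,
                    selected = pSel < alpha, perfect_fit = perfect,
                    row.names = NULL)
  attr(res, "twoGroup") <- length(unique(genotypes)) == 2L
  res
}

#' Select candidate modifier genes significant in both conditions
#'
#' Intersects the genes selected by [screenEqtl()] in a control and a
#' perturbed condition (e.g. untreated vs genotoxic stress); a gene must
#' be selected in both to be a candidate. Ordered by ascending control
#' p-value.
#'
#' @param control,perturbed data.frames from [screenEqtl()] over the same
#'   gene universe.
#' @return character vector of candidate gene identifiers.
#' @export
selectCandidates <- function(control, perturbed) {
  stopifnot(all(c("gene", "selected", "p_value") %in% colnames(control)),
            all(c("gene", "selected") %in% colnames(perturbed)))
  both <- intersect(control$gene[control$selected],
                    perturbed$gene[perturbed$selected])
  ord <- order(control$p_value[match(both, control$gene)])
  both[ord]
}

#' Read a normalized count table and its sample sheet
#'
#' The count table is TSV with gene identifiers in the first column and a
#' header row of sample identifiers; the sample sheet is TSV with columns
#' \code{sample_id}, \code{genotype} (WT/HET/KO) and optionally
#' \code{condition}.
#'
#' @param countsPath path to the counts TSV.
#' @param sampleSheetPath path to the sample-sheet TSV.
#' @return a list with \code{counts} (matrix, genes x samples) and
#'   \code{samples} (data.frame, ordered as the count columns).
#' @export
readCountTable <- function(countsPath, sampleSheetPath) {
  counts <- utils::read.table(countsPath, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE)
  counts <- as.matrix(counts)
  sheet <- utils::read.table(sampleSheetPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "genotype") %in% colnames(sheet)))
    stop("sample sheet needs columns: sample_id, genotype")
  missing <- setdiff(colnames(counts), sheet$sample_id)
  if (length(missing))
    stop("sample(s) absent from the sample sheet: ",
         paste(missing, collapse = ", "))
  sheet <- sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  list(counts = counts, samples = sheet)
}
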
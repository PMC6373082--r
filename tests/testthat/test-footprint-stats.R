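test_that("binning uses half-open 10-Mb bins and conserves totals", {
  gc <- mkCalls("KO", pos = c(1L, 9999999L, 10000000L))
  b <- binVariants(gc)
  expect_equal(b$count, c(2L, 1L))
  expect_equal(b$bin, c(0L, 1L))

  expect_equal(nrow(binVariants(GenotypeCalls("KO"))), 0L)

  # bin_size = 1: one count per occupied position
  b1 <- binVariants(mkCalls("KO", pos = c(3L, 5L)), binSize = 1)
  expect_equal(sum(b1$count == 1L), 2L)
  expect_equal(sum(b1$count), 2L)
})

test_that("binned counts are conserved per chromosome on random sets", {
  set.seed(41)
  for (rep in 1:5) {
    gc <- randomCalls("KO", 120, chroms = c("chr1", "chr2", "chr3"))
    b <- binVariants(gc, binSize = 123457)
    per <- tapply(b$count, b$chrom, sum)
    truth <- table(callData(gc)$chrom)
    expect_equal(as.integer(per[names(truth)]), as.integer(truth))
  }
})

test_that("trend statistic matches the closed form on worked tables", {
  # symmetric table: no trend
  sym <- cochranArmitage(c(5, 5, 5), c(5, 5, 5))
  expect_equal(sym$z, 0)
  expect_equal(sym$p, 1)

  # opposite gradients: T = 10, Var = 5, z = 10/sqrt(5)
  opp <- cochranArmitage(c(0, 5, 10), c(10, 5, 0), scores = c(0, 1, 2))
  expect_equal(opp$z, 10 / sqrt(5), tolerance = 1e-12)
  expect_equal(opp$z, 4.4721, tolerance = 1e-4)

  # degenerate: one empty row
  deg <- cochranArmitage(c(0, 0), c(3, 4))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("trend z is affine-invariant in scores and antisymmetric in rows", {
  set.seed(51)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    r1 <- rpois(k, 6); r2 <- rpois(k, 6)
    if (sum(r1) == 0 || sum(r2) == 0 || sum(r1 + r2 > 0) < 2) next
    t0 <- 0:(k - 1)
    a <- runif(1, 0.1, 9); b <- runif(1, -5, 5)
    z1 <- cochranArmitage(r1, r2, t0)$z
    z2 <- cochranArmitage(r1, r2, a * t0 + b)$z
    expect_equal(z1, z2, tolerance = 1e-9)
    sw <- cochranArmitage(r2, r1, t0)
    expect_equal(sw$z, -z1, tolerance = 1e-9)
    expect_equal(sw$p, cochranArmitage(r1, r2, t0)$p, tolerance = 1e-12)
  }
})

test_that("trend test agrees with the generic score-test implementation", {
  # independent route: stats::prop.trend.test chi-square equals z^2
  set.seed(61)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    r1 <- rpois(k, 8) + 1; r2 <- rpois(k, 8) + 1
    ca <- cochranArmitage(r1, r2, 0:(k - 1))
    ref <- suppressWarnings(
      stats::prop.trend.test(r1, r1 + r2, score = 0:(k - 1)))
    expect_equal(ca$z^2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ca$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("asymptotic p tracks the fixed-margin permutation mid-p", {
  # moderate tables: the normal tail should sit within a few percent of
  # the discrete permutation mid-p (exact equality is not expected)
  set.seed(71)
  for (rep in 1:4) {
    k <- 4
    r1 <- rpois(k, 5) + 2; r2 <- rpois(k, 5) + 2
    sc <- 0:(k - 1)
    obs <- cochranArmitage(r1, r2, sc)
    tabs <- stats::r2dtable(2e4, c(sum(r1), sum(r2)), r1 + r2)
    zs <- vapply(tabs, function(m) cochranArmitage(m[1, ], m[2, ], sc)$z, 0)
    ge <- mean(abs(zs) >= abs(obs$z) - 1e-9)
    gt <- mean(abs(zs) > abs(obs$z) + 1e-9)
    expect_lt(abs(obs$p - (ge + gt) / 2), 0.06)
  }
})

test_that("chromosome flagging ranks and adjusts per-chromosome tests", {
  wt <- mkCalls("WT", pos = c(1e6, 2e7, 5e7, 9e7), chrom = "chr1")
  identical_scan <- flagChromosomes(binVariants(wt), binVariants(wt))
  expect_false(any(identical_scan$significant))
  expect_true(all(identical_scan$p_adjusted >= identical_scan$p_value))

  # a chromosome present on one side only is skipped with a warning
  ko2 <- mkCalls("KO", pos = c(1e6, 2e6), chrom = "chrY")
  expect_warning(flagChromosomes(binVariants(ko2), binVariants(wt)),
                 "skipped")
})

test_that("footprint interval is the min/max envelope of qualifying calls", {
  kl <- dissectKoLinked(
    mkCalls("KO", pos = c(2e7, 5.5e7, 8e7, 9e7),
            genotype = c("hom_alt", "hom_alt", "hom_alt", "het")),
    GenotypeCalls("WT"))
  iv <- estimateFootprintInterval(kl, "chr1")
  expect_equal(unname(iv), c(2e7, 8e7))  # het at 90 Mb excluded
  ivAll <- estimateFootprintInterval(kl, "chr1", "all")
  expect_equal(unname(ivAll), c(2e7, 9e7))

  single <- estimateFootprintInterval(
    dissectKoLinked(mkCalls("KO", 5e6), GenotypeCalls("WT")), "chr1")
  expect_equal(single[["startBp"]], single[["endBp"]])

  hetOnly <- dissectKoLinked(mkCalls("KO", 1e6, genotype = "het"),
                             GenotypeCalls("WT"))
  expect_error(estimateFootprintInterval(hetOnly, "chr1"),
               "homozygous_only")
})

test_that("gap-tolerant interval drops far outliers but keeps 1-bin gaps", {
  # main run in bins 2-4 with an empty bin inside; outlier in bin 12
  kl <- mkCalls("KO", pos = c(2.1e7, 2.9e7, 4.5e7, 4.9e7, 12.5e7))
  iv <- estimateFootprintInterval(kl, "chr1", gapTolerant = TRUE)
  expect_equal(unname(iv), c(2.1e7, 4.9e7))
  # plain envelope includes the outlier
  expect_equal(unname(estimateFootprintInterval(kl, "chr1"))[2], 12.5e7)
})

test_that("genetic-map interpolation, extrapolation and fallback behave", {
  m <- GeneticMap(data.frame(chrom = "chr1", bp = c(0, 1e7),
                             cM = c(0, 5)))
  expect_equal(physicalToGenetic(m, "chr1", 5e6), 2.5)
  expect_equal(physicalToGenetic(m, "chr1", 1e7), 5)       # anchor exact
  expect_equal(physicalToGenetic(m, "chr1", 2e7), 10)      # extrapolated
  # constant-rate fallback: 0.5 cM/Mb over 20 Mb = 10 cM
  expect_equal(physicalToGenetic(m, "chrX", 2e7), 10)
  strict <- GeneticMap(data.frame(chrom = "chr1", bp = c(0, 1e7),
                                  cM = c(0, 5)), fallbackRate = NA)
  expect_error(physicalToGenetic(strict, "chrX", 1e6), "absent")
  # monotone non-decreasing over a multi-anchor map
  m2 <- GeneticMap(data.frame(chrom = "chr1",
                              bp = c(0, 1e7, 3e7, 6e7),
                              cM = c(0, 8, 9, 30)))
  xs <- seq(0, 7e7, by = 1e6)
  expect_true(all(diff(physicalToGenetic(m2, "chr1", xs)) >= 0))
})

test_that("genetic map TSV round-trips through readGeneticMap", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tbp\tcM", "chr1\t0\t0", "chr1\t10000000\t5"), f)
  m <- readGeneticMap(f)
  expect_equal(physicalToGenetic(m, "chr1", 5e6), 2.5)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), bad)
  expect_error(readGeneticMap(bad), "chrom, bp, cM")
})

test_that("backcross-generation estimate inverts the 200/N rule", {
  expect_identical(estimateBackcrossGenerations(42.14), 5L)
  expect_identical(estimateBackcrossGenerations(11.94), 17L)
  expect_identical(estimateBackcrossGenerations(200), 1L)
  expect_identical(estimateBackcrossGenerations(1000), 1L)  # floor at 1
  expect_error(estimateBackcrossGenerations(0), "positive")
  expect_error(estimateBackcrossGenerations(-3), "positive")
  # monotone non-increasing in the extent
  ext <- seq(1, 120, by = 0.7)
  expect_true(all(diff(estimateBackcrossGenerations(ext)) <= 0))
})

test_that("estimateFootprint combines envelope, map and N estimate", {
  kl <- dissectKoLinked(mkCalls("KO", pos = c(2e7, 8e7)),
                        GenotypeCalls("WT"))
  m <- GeneticMap(data.frame(chrom = "chr1", bp = c(0, 2e8),
                             cM = c(0, 100)))
  fp <- estimateFootprint(kl, "chr1", m)
  expect_s4_class(fp, "FootprintInterval")
  expect_equal(fp@extentCM, 30)          # 60 Mb at 0.5 cM/Mb
  expect_identical(fp@estimatedN, 7L)    # round(200/30)
  rep <- writeFootprintReport(fp, bedPath = tempfile(),
                              tsvPath = tempfile())
  expect_equal(rep$estimated_N, 7L)
})
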
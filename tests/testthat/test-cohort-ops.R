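test_that("replicate intersection keeps shared keys and flags discordance", {
  ko1 <- mkCalls("KO", pos = c(100L, 200L), sampleId = "ko1")
  ko2 <- mkCalls("KO", pos = c(100L, 300L), sampleId = "ko2")
  ko3 <- mkCalls("KO", pos = 100L, sampleId = "ko3")
  cons <- intersectReplicates(list(ko1, ko2, ko3))
  d <- callData(cons)
  expect_equal(d$pos, 100L)
  expect_equal(d$concordance, "concordant")
  expect_equal(d$genotype, "hom_alt")

  # single set is the identity, all concordant
  one <- intersectReplicates(list(ko1))
  expect_equal(callData(one)$pos, c(100L, 200L))
  expect_true(all(callData(one)$concordance == "concordant"))

  expect_error(intersectReplicates(list()), "at least one")
  wt <- mkCalls("WT", pos = 100L)
  expect_error(intersectReplicates(list(ko1, wt)), "share one genotype")
})

test_that("majority policy keeps the modal genotype but flags the site", {
  reps <- list(mkCalls("KO", 100L, "hom_alt", sampleId = "ko1"),
               mkCalls("KO", 100L, "hom_alt", sampleId = "ko2"),
               mkCalls("KO", 100L, "het", sampleId = "ko3"))
  strict <- intersectReplicates(reps, "strict")
  expect_equal(callData(strict)$genotype, "missing")
  expect_equal(callData(strict)$concordance, "discordant_genotype")
  maj <- intersectReplicates(reps, "majority")
  expect_equal(callData(maj)$genotype, "hom_alt")
  expect_equal(callData(maj)$concordance, "discordant_genotype")
  # 1-1 tie under majority degrades to missing
  tie <- intersectReplicates(reps[c(1, 3)], "majority")
  expect_equal(callData(tie)$genotype, "missing")
})

test_that("strict intersection is order-invariant", {
  set.seed(21)
  reps <- replicate(3, randomCalls("KO", 50), simplify = FALSE)
  a <- intersectReplicates(reps, "strict")
  b <- intersectReplicates(rev(reps), "strict")
  expect_equal(callData(a)[, c("chrom", "pos", "genotype", "concordance")],
               callData(b)[, c("chrom", "pos", "genotype", "concordance")])
})

test_that("reference subtraction removes by site key, ignoring genotype", {
  x <- mkCalls("KO", pos = c(1L, 2L), genotype = "hom_alt")
  ref <- mkCalls("ref", pos = 2L, genotype = "het")
  expect_equal(callData(subtractReference(x, ref))$pos, 1L)
  expect_equal(callData(subtractReference(x, GenotypeCalls("ref"))),
               callData(x))
  expect_equal(nCalls(subtractReference(x, x)), 0L)
})

test_that("strain-origin annotation labels membership without removal", {
  x <- mkCalls("KO", pos = c(1L, 2L))
  donor <- mkCalls("129P2", pos = 2L)
  ann <- annotateStrainOrigin(x, donor)
  d <- callData(ann)
  expect_equal(d$origin[d$pos == 2L], "donor_derived")
  expect_equal(d$origin[d$pos == 1L], "novel")
  expect_equal(nrow(d), 2L)
  allNovel <- annotateStrainOrigin(x, GenotypeCalls("empty"))
  expect_true(all(callData(allNovel)$origin == "novel"))
})

test_that("KO-linked dissection retains absences and genotype mismatches", {
  ko <- mkCalls("KO", pos = c(1L, 2L, 3L, 4L),
                genotype = c("hom_alt", "hom_alt", "het", "het"))
  wt <- mkCalls("WT", pos = c(2L, 3L, 4L),
                genotype = c("het", "het", "hom_ref"))
  kl <- dissectKoLinked(ko, wt)
  d <- callData(kl)
  # pos1 absent; pos2 hom_alt vs het mismatch; pos3 het==het excluded;
  # pos4: WT hom_ref counts as absent
  expect_setequal(d$pos, c(1L, 2L, 4L))
  expect_equal(d$reason[d$pos == 1L], "absent_in_wt")
  expect_equal(d$reason[d$pos == 2L], "genotype_mismatch")
  expect_equal(d$reason[d$pos == 4L], "absent_in_wt")
})

test_that("dissection partitions the KO set and never invents keys", {
  set.seed(31)
  for (rep in 1:10) {
    ko <- randomCalls("KO", 80)
    wt <- randomCalls("WT", 80)
    kl <- dissectKoLinked(ko, wt)
    koKeys <- siteKeys(ko)[callData(ko)$genotype != "missing"]
    expect_true(all(siteKeys(kl) %in% koKeys))
    matching <- setdiff(koKeys, siteKeys(kl))
    expect_setequal(c(siteKeys(kl), matching), koKeys)
    # every "matching" key really does match the WT genotype state
    dko <- callData(ko); rownames(dko) <- siteKeys(ko)
    dwt <- callData(wt); rownames(dwt) <- siteKeys(wt)
    shared <- intersect(matching, siteKeys(wt))
    expect_identical(dko[shared, "genotype"], dwt[shared, "genotype"])
  }
})

test_that("on simulated cohorts the dissection recovers the footprint exactly", {
  # no dropout: every donor variant in the fixed haplotype must be called
  # KO-linked, and no shared background variant may be reported
  for (seed in c(101, 202)) {
    cfg <- simConfig(nBackcross = 8, seed = seed, driftDensity = 0)
    sim <- simulateCongenicCohort(cfg)
    koC <- intersectReplicates(sim$samples[grep("^ko", names(sim$samples))])
    kl <- dissectKoLinked(koC, sim$samples$wt1)
    v <- sim$truth$variants
    donorKeys <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")[
      v$origin == "donor" & v$inFootprintHaplotype]
    bgKeys <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")[
      v$origin == "background"]
    expect_setequal(siteKeys(kl), donorKeys)
    expect_length(intersect(siteKeys(kl), bgKeys), 0L)
  }
})

test_that("annotated sets write VCF with reason/origin INFO tags", {
  ko <- mkCalls("KO", pos = c(1L, 2L))
  wt <- mkCalls("WT", pos = 2L, genotype = "het")
  kl <- dissectKoLinked(ko, wt)
  f <- tempfile(fileext = ".vcf")
  writeCallsVcf(kl, f)
  txt <- readLines(f)
  expect_true(any(grepl("KO_LINKED_REASON=absent_in_wt", txt)))
  tsv <- tempfile(fileext = ".tsv")
  writeCallsTsv(kl, tsv)
  d <- read.delim(tsv)
  expect_true("reason" %in% colnames(d))
})
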
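# compact builders for call-set fixtures

mkCalls <- function(label, pos, genotype = "hom_alt", chrom = "chr1",
                    ref = "A", alt = "G", qual = 50, depth = 20L,
                    sampleId = label) {
  GenotypeCalls(label, data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    genotype = genotype, qual = qual, depth = as.integer(depth),
    sampleId = sampleId))
}

# a deliberately awkward hand-written VCF: multi-sample, multiallelic,
# missing genotypes, INFO-only DP on one record
writeFixtureVcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Combined depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    "##contig=<ID=chr1,length=2000000>",
    "##contig=<ID=chr2,length=2000000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    "chr1\t100\t.\tA\tG\t45\t.\t.\tGT:DP\t1/1:20\t0/1:15",
    "chr1\t200\t.\tC\tG,T\t60\t.\t.\tGT:DP\t1/2:30\t0/0:12",
    "chr1\t300\t.\tT\tA\t12\t.\tDP=9\tGT\t0|1\t./.",
    "chr2\t500\t.\tG\tC\t99\t.\t.\tGT:DP\t1/1:40\t1/1:41")
  writeLines(lines, path)
  path
}

# random call set over a small genome, for property-style tests
randomCalls <- function(label, n, chroms = c("chr1", "chr2"),
                        maxPos = 1e6) {
  pos <- sample.int(maxPos, n)
  GenotypeCalls(label, data.frame(
    chrom = sample(chroms, n, replace = TRUE), pos = pos,
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE), alt = "N",
    genotype = sample(c("hom_ref", "het", "hom_alt", "missing"), n,
                      replace = TRUE, prob = c(.1, .3, .5, .1)),
    qual = round(runif(n, 0, 100), 1),
    depth = rpois(n, 20), sampleId = label))
}
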
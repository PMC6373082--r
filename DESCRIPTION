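Package: congenicScan
Title: Congenic Footprint Detection and Strain Introgression Analysis for
    Genetically Engineered Mouse Lines
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the genetic background of genetically engineered
    mouse (GEM) lines from per-sample VCF genotype calls. Detects
    donor-strain introgression by genotype set operations over WT,
    heterozygous and knockout samples, dissects the congenic footprint
    linked to a targeted locus, scans chromosomes with a Cochran-Armitage
    trend test on binned variant counts, converts footprint extent to
    genetic-map distance and estimates the number of backcross generations
    from the 200/N rule, classifies footprint ploidy and cross-validates it
    by Mendelian annotation against a heterozygous littermate, and screens
    congenic genes for linear expression-genotype dependence (candidate
    modifier genes / eQTLs). Includes a backcross-breeding simulator that
    emits per-sample VCFs with a known footprint for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, VariantDetection, Sequencing
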
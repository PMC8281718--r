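Package: haploscope
Title: Haplotype-Resolved Fine-Mapping, Structural-Variant Junction
    Classification and Somatic Filtering for Renal Medullary Carcinoma
    Style Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for haplotype-resolved analysis of a focal risk allele
    in a small cancer cohort: assembly and stitching of phase-set haplotype
    blocks from phased VCF calls, haplotype-level principal component
    analysis of mutant versus wild-type haplotypes against a labeled
    reference panel, fine-mapping by one-sided exact over-representation
    tests on haplotype contingency tables, nucleotide-resolution
    classification of structural-variant fusion junctions (blunt,
    microhomology, untemplated insertion), breakpoint annotation against
    repeat and gene tracks, fusion-transcript orientation calling with
    splice-site flags, germline and somatic filter cascades (panel of
    normals, VAF and population-frequency rules), kataegis detection, and
    read-ratio sex inference.  A synthetic-data module generates phased
    panels with population structure and identity-by-descent cores,
    structural-variant truth sets with designed junction chemistry, and
    somatic call sets, for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    graphics,
    S4Vectors,
    BiocGenerics,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
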
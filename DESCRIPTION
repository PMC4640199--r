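Package: enumapper
Title: Positional Cloning of ENU-Induced Mutations by Pooled Homozygosity and Allele-Frequency Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps recessive phenotype-causing mutations in inbred,
    ENU-mutagenized mouse lines using the induced variants themselves as
    segregating markers. Provides a filtering cascade that extracts
    presumptive ENU-induced SNVs from pooled-sample VCFs, sliding-window
    homozygosity and non-reference allele frequency (NAF) statistics with
    region calling, extraction of candidate causal mutations by functional
    category and zygosity, closed-form genetics of the G1xG2 backcross
    scheme, and a forward simulator of the breeding scheme that produces
    pooled VCFs with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    IRanges,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
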
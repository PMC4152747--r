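Package: karyoploid
Title: Karyotype Parameters, Feulgen Genome Sizes and Polyploid Downsizing
    Analysis for Bimodal Karyotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for plant cytogenetic analyses of bimodal karyotypes
    across ploidy levels: chromosome-measurement tables to averaged
    haploid-complement karyotypes; centromeric indices, Levan morphology
    classes with compound boundary labels, karyotype formula strings and
    the asymmetry indices A1, A2, CV(CL) and M(CA); Feulgen densitometry
    calibration against an internal standard to 2C picogram values and
    1Cx per basic genome; genome downsizing statistics across ploidy;
    weighted least-squares regression of 2C DNA content on ploidy level
    with its hyperbolic 1Cx rearrangement; one-way ANOVA with Fisher LSD
    contrasts and a compact letter display; and synthetic-data generators
    that emulate metaphase measurement and densitometry designs so every
    stage can be tested without external data. Ships a published summary
    table for 18 Hippeastrum accessions (2x-6x) as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
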
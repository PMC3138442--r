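Package: segscan
Title: Segregation Distortion and Two-Point Linkage Scans for F2 and
    Non-Recombinant Backcross Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide segregation distortion analysis for experimental
    crosses between diverged populations, modelled on copepod (Tigriopus
    californicus) interpopulation hybrids. Provides a gene-drop simulator
    for F2 and non-recombinant backcross designs with female achiasmy,
    stage-specific viability selection and genotyping artifacts; two-point
    recombination-fraction estimation by EM with Kosambi map distances,
    linkage grouping, marker ordering, corrected map length and genome
    coverage; single-locus and two-locus chi-square scans for distortion
    and epistasis with Bonferroni significance tiers; and an end-to-end
    simulate/analyze pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
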
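Package: popstruct
Title: Population Structure Analysis of Genome-Wide SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for fine-scale population-structure analysis of
    genome-wide SNP genotypes: merging of multi-study datasets with strand-aware
    allele matching, SNP and sample quality control (per-study call rate,
    Hardy-Weinberg exact test, allele-frequency one-vs-rest comparisons,
    method-of-moments relatedness), windowed r-squared LD pruning, principal
    component analysis with Patterson normalization and projection of external
    samples, pairwise Hudson F_st between geographic groups with translation to
    the expected genomic-control lambda of a fully stratified case-control
    study, detection of runs of homozygosity with Poisson count models over
    geography, and simulation of association-test power loss under genomic
    inflation. Includes a Balding-Nichols synthetic genotype generator with
    planted relatives, admixed samples, batch artifacts and autozygous
    segments, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
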
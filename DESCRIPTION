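Package: lohscan
Title: Homolog-Resolved Genome Instability Analysis in Hybrid Diploid Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies genomic alterations in hybrid diploid
    Saccharomyces cerevisiae from homolog-specific SNP coverage: interstitial
    and terminal loss of heterozygosity, terminal deletions and duplications,
    whole-chromosome aneuploidy and uniparental disomy. Computes relative
    coverage (RC) profiles from allele depths or SNP-microarray hybridization
    ratios, segments homolog copy states, resolves breakpoint intervals,
    pairs terminal copy-number changes into monocentric translocation
    hypotheses, and estimates per-genome per-cell-division event rates under
    a subculture design, together with mutation-spectrum and enrichment
    statistics. Includes a synthetic hybrid-diploid data generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
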
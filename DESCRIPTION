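Package: oriallele
Title: Allele-Specific Analysis of DNA Replication Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-specific analysis of DNA replication origins
    mapped by nascent-strand sequencing in phased diploid genomes.  The
    package calls per-origin allelic bias from phased heterozygous SNP read
    depths (exact binomial test with Benjamini-Hochberg correction),
    annotates sequences for non-B-DNA-forming potential (G-quadruplexes,
    intermolecular G4 patterns, a simplified mirror-repeat triplex
    detector), measures G/C and A/T composition skew around origin summits,
    calls skewed regions and asynchronously replicated timing domains with
    a SICER-style island finder, and quantifies feature enrichment with
    interval-shuffling permutation tests and composition-matched controls.
    A synthetic diploid-genome simulator with a known truth table makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
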
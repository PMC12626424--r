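Package: mexphen
Title: Microexon Splicing Programs and Zebrafish Behavioral Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls tissue-enriched (neural) exon and microexon splicing programs
    from percent-spliced-in (PSI) inclusion tables with coverage-quality codes,
    quantifies zebrafish larval activity, light/dark transition, tap-habituation
    and thigmotaxis phenotypes from 1 Hz activity exports, derives locomotion and
    social metrics (polarization, leadership, neighbor distance) from tracked
    fish-pair trajectories, and analyses cross-line transcriptomic compensation
    (variance-stabilized Del-WT differences, preranked permutation GSEA, Jaccard
    clustering of enriched GO terms). Includes seeded synthetic-data generators
    emulating each input type and shared resampling statistics
    (bootstrap-Wilcoxon median p, permutation tests, exact Fisher).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
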
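Package: insulatr
Title: Mining Insulator-Like Intergenic Elements from Compact Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-mining workflow for discovering candidate insulator-like
    cis-regulatory elements in compact plant genomes. Extracts intergenic
    regions between adjacent gene pairs and classifies them by flanking-gene
    orientation (divergent, convergent, tandem) and expression fold change;
    evaluates microsynteny of the flanking pair across many subject genomes
    and classifies rearrangements (high-quality, insertion/deletion,
    inversion); calls unmethylated regions (UMRs) from per-cytosine bisulfite
    records in 100-bp tiles and intersects them with candidates; ranks
    candidates for in vivo validation; and computes dual-reporter
    (GFP:mCherry) fold-change statistics with ANOVA/Tukey group letters.
    Includes a seeded synthetic-data generator that plants known candidates,
    rearrangements, UMRs and insulator strengths so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
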
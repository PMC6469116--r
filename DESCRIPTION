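Package: spikecontam
Title: Spike-In Anchored Quantification of Contamination in Metagenomic
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and quantifies reagent and environmental contamination
    in metagenomic sequencing count tables using an ERCC spike-in anchor. A
    taxon whose reads-per-million decrease inverse-linearly with sample input
    mass carries a fixed absolute amount of nucleic acid and is classified as
    a contaminant (ordinary least squares on log10 rpm vs log10 mass, adjusted
    R-squared threshold, negative slope). Each contaminant's mass is then
    quantified per sample from the ratio of its reads to the spike-in reads,
    and externally studentized residuals flag samples carrying more of a taxon
    than contamination alone predicts, separating true signal from background
    without censoring the taxon. Includes a synthetic count-table generator
    emulating spike-in dilution-series and serum-batch experiments with known
    injected truths, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
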
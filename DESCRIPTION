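Package: itshybrid
Title: Additive Nucleotide Detection and Hybrid Analysis from Sanger ITS Traces
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Confirms additive nucleotides (heterozygous double peaks) in
    Sanger chromatograms of the nuclear ribosomal internal transcribed
    spacer (ITS) region using secondary-peak (S-value) and background-noise
    (N-value) intensity statistics with a mixed-template calibration series.
    Provides motif-based ITS1/5.8S/ITS2 region extraction, ITS sequence-type
    assignment over variable sites, hybrid-ratio estimation from secondary
    peak intensities, parental-lineage inference under a gamete model
    (single and two-step crosses), and neighbor-joining phylogenies with
    IUPAC-aware p-distances and bootstrap support.  A synthetic chromatogram
    simulator generates four-channel traces and replicate (S, N) statistics
    so the whole pipeline runs without instrument files; a packaged panel of
    46 cultivated Codonopsis specimens supports germplasm hybridization
    analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
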
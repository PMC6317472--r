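Package: gmapsolve
Title: Glycan Deconvolution from Lectin and Exoglycosidase Microarray Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciphering protein glycosylation from on-chip
    glycan-modification-and-probing experiments, in which microspotted
    glycoproteins are treated with panels of exoglycosidases and probed
    with lectins. Candidate glycan structures (condensed IUPAC text) are
    digested in silico via recognition/replace motif substitution, lectin
    binding is predicted from motif binding scores, and the resulting model
    response vectors are fit to observed response vectors by nonnegative
    least squares with recursive alternative-fit sampling. Includes
    mass-spectrometry-informed candidate restriction by monosaccharide
    composition, weighted structural summaries (core types, terminal
    features, per-mass isomer breakdowns), spot-level signal reduction,
    and a seeded synthetic-data generator for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
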
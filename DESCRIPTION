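Package: ntdms
Title: Native Top-Down Mass Spectrometry of Metalloprotein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interprets native top-down mass spectrometry (nTDMS) experiments
    on intact metalloprotein complexes. Deconvolutes native electrospray
    charge-state envelopes into neutral average masses with per-charge-state
    standard deviations, explains intact-mass shifts with a bounded
    combinatorial search over a modification/metal-adduct catalog, generates
    and matches b/y fragment ions at ppm tolerance with a Poisson p-score,
    validates metal-bound fragments by isotopic envelope fitting, localizes
    metal-binding sites to sequence intervals from apo/holo fragment
    constraints, and quantifies proteoform occupancy. A seeded synthetic-data
    generator emulates the three-tier MS1/MS2/MS3 structure of native
    top-down experiments on membrane metalloenzymes so that every stage of
    the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
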
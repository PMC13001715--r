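Package: cuepr
Title: Multi-Site Copper(II) Binding Analysis by Crystal Geometry and EPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising multi-site Cu(2+) binding to serum
    albumin and similar proteins. Detects metal sites and donor spheres in
    PDB/mmCIF coordinate files, tabulates pairwise Cu-Cu distances,
    counts disulfides and computes crystallographic symmetry contacts;
    enumerates site-occupancy configurations and simulates Gaussian
    distance distributions for comparison with pulsed dipolar EPR data;
    simulates field-swept CW EPR powder spectra of axial Cu(2+) species
    with second-order hyperfine corrections and double-integral titration
    analysis; processes 3-pulse ESEEM and HYSCORE time-domain data
    (exponential background division, Hamming window, FFT, quadrant
    folding and symmetrisation); and simulates and inverts RIDME dipolar
    traces by non-negative Tikhonov regularization with bootstrap
    confidence bands, including stretched-exponential and biexponential
    relaxation fits. A synthetic-data module generates a decoy structure
    honouring the published distance envelopes plus CW, ESEEM, HYSCORE
    and RIDME fixtures so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
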
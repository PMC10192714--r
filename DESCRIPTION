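Package: nucleodyn
Title: Nuclear Transcription Factor Dynamics from Fluorescence Fluctuations
    and Replication-Focus Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the dynamical organization of nuclear
    proteins across the cell cycle. Implements a fluorescence correlation
    spectroscopy (FCS) autocorrelation model combining free diffusion
    through a 3D Gaussian confocal volume with binding to two populations
    of fixed chromatin sites, together with weighted least-squares fitting
    and derivation of dissociation rates; a direct and multi-tau
    photon-count correlator with segment-wise error estimation; a Brownian
    dynamics simulator of fluorophores with two classes of immobile binding
    sites emitting Poisson photon counts; generators of synthetic nucleus
    images carrying ground-truth foci and the canonical PCNA replication
    patterns; image metrics (nuclear coefficient of variation excluding
    nucleoli, mean + 2 SD foci segmentation with an optical-resolution
    size filter, relative foci intensity, per-colony DAPI normalization);
    and a rule-based classifier of S-phase stages (early, mid, late) from
    PCNA focal patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    EBImage,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
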
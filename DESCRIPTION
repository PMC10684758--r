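Package: gpcrforecast
Title: Next-Frame Forecasting of GPCR Molecular-Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised next-frame forecasting of coarse-grained G
    protein-coupled receptor (GPCR) molecular-dynamics trajectories.
    Residues are reduced to their centers of mass, frames are min-max
    normalised and windowed into 5-in/1-out supervised samples, and four
    forecaster families (persistence baseline, random forest,
    unidirectional and bidirectional LSTM, and a convolutional LSTM) are
    trained and compared by per-region root-mean-square deviation (RMSD)
    over transmembrane helices and intra/extracellular loops, with a
    resampled five-fold cross-validation protocol and pairwise t-tests.
    A seeded Ornstein-Uhlenbeck trajectory generator with
    region-dependent flexibility makes the whole pipeline testable
    without restricted simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
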
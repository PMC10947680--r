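Package: icflow
Title: Intracardiac Flow Quantification from Time-Resolved Velocity Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies right-ventricular hemodynamics from time-resolved,
    chamber-masked velocity vector fields such as those produced by echo-based
    Doppler velocity reconstruction or 4D flow MRI. Computes vorticity, vortex
    strength, total kinetic energy, viscous energy loss, Navier-Stokes based
    pressure gradients with weighted least-squares relative-pressure
    integration, and the tricuspid-valve-to-apex pressure difference. Includes
    preprocessing (universal outlier detection and median replacement, low-rank
    denoising, cardiac-cycle phase averaging and resampling, plane projection
    of volumetric fields), cross-modality timeseries agreement statistics
    (Pearson correlation, relative L2-norm difference, quartile summaries), and
    a synthetic-flow generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
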
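Package: lapwsim
Title: Point-Cloud Models of the Left Atrial Posterior Wall and Simulated
    Electrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds volumetric electrophysiology models of the left atrial
    posterior wall directly from electroanatomical point-cloud data, without
    image segmentation.  The pipeline downsamples the point cloud,
    reconstructs and cleans a sheet surface, extrudes it to wall thickness,
    and produces a refined tetrahedral mesh.  On that mesh it assigns
    rule-based transmural fiber fields and orthotropic monodomain
    conductivities, optionally inserts percolation-style fibrotic subdomains
    generated from three-dimensional Perlin noise, solves the monodomain
    reaction-diffusion equations with the Courtemanche human atrial ionic
    model by explicit finite-element time stepping, and forward-computes
    unipolar electrograms at virtual electrodes.  Extracted electrogram
    features (activation time, amplitudes, slopes, deflection counts) and
    morphology statistics (Cohen's d, wavelet-PCA-k-means clustering,
    isochrone maps) quantify agreement between simulated and recorded
    signals.  A synthetic-data module generates desk-scale fixtures so the
    whole pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
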
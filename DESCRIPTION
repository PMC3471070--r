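Package: tractem
Title: Template-Based Quantification of White-Matter Tract Damage from
    Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Tractem", "Developers", email = "tractem@example.org",
           role = c("aut", "cre"))
Description: Builds binary mean tract templates from probabilistic
    tractography in healthy controls and uses them to quantify white-matter
    damage in patients as the percentage of voxels whose diffusion metrics
    (fractional anisotropy, mean diffusivity) are Z-score outliers against
    a control cohort.  Includes a ball-and-stick diffusion model with
    residual-bootstrap orientation uncertainty, probabilistic streamline
    tractography with curvature thresholding and exclusion masking,
    TBSS-style white-matter skeleton masking, volume-matched individual
    tract binarization, and a self-contained synthetic diffusion-phantom
    generator (curved tract bundles, graded injury, Rician noise, spatial
    jitter) so the whole pipeline is testable without any acquired data.
    Reads and writes NIfTI-1 volumes and FSL-style bval/bvec tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
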
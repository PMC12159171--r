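Package: glymphalps
Title: Automated DTI-ALPS Glymphatic Function Analysis with Synthetic
    Diffusion Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the diffusion-tensor-imaging analysis along the
    perivascular space (DTI-ALPS) index, a ratio of scanner-axis water
    diffusivities used as a proxy for glymphatic function, with fully
    automated region-of-interest selection: atlas-style tract labels are
    restricted, scored by principal-eigenvector axis purity times
    fractional anisotropy ("color-FA" thresholding), and the
    highest-scoring fraction of voxels is retained per label and
    hemisphere.  Includes a log-linear diffusion tensor fit from
    diffusion-weighted volumes with FSL-dialect gradient tables, synthetic
    phantom and cohort generators with known ground truth (Rician noise,
    planted off-orientation impurity voxels, a sleep-apnea cohort with a
    patient-only ALPS-AHI coupling), and the nonparametric cohort
    statistics battery used in glymphatic studies: Mann-Whitney group
    comparisons, Spearman correlations with Bonferroni correction, and
    ordinary least squares with a group-by-exposure interaction term.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
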
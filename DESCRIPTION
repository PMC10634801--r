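Package: layervn
Title: Layer-Specific fMRI Modelling and Connectivity with Velocity-Nulling Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for layer-dependent functional MRI analysis with
    velocity-nulling (VN) diffusion gradients. Implements the intravoxel
    incoherent motion (IVIM) pseudo-diffusion model of vascular signal
    attenuation, critical-velocity calculations for bipolar gradient pairs,
    and the inverse-square extravascular falloff of pial vessels. A synthetic
    cortical-column generator produces complex-valued (magnitude + phase)
    depth-resolved BOLD time series with draining-vein leakage, pial-vein
    blooming, and laminar network structure, for task and resting-state
    paradigms. Analysis functions cover phase regression, temporal filtering,
    GLM activation with a double-gamma HRF, equidistant cortical layering,
    depth-dependent activation profiles, and layer-specific functional
    connectivity (seed maps, depth-by-depth Fisher-z matrices, laminar
    connectomes) with paired group statistics and FDR correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: signal, RNifti, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
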
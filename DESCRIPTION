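Package: dppmri
Title: Diffusion and Perfusion MRI Measurement Pipeline for Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular measuring system for diffusion- and perfusion-weighted
    MRI abnormalities in multiple sclerosis. Classifies FLAIR-segmented lesions
    into four evolution classes from non-enhanced and gadolinium-enhanced
    T1-weighted intensities, computes apparent diffusion coefficient (ADC) maps
    from b0/b1000 acquisitions, quantifies dynamic susceptibility contrast
    perfusion (CBF, CBV, MTT) by truncated-SVD deconvolution against an
    automatically selected arterial input function, builds normal-appearing
    tissue masks, and extracts per-region statistics into a CSV report with
    full provenance logging. A built-in digital phantom with known ground
    truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
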
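# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# default noiseless 32^3 bundle (the reference phantom for most tests)
default_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- generate_phantom(phantom_spec())
  .fixtures$bundle
}

# lesion-free 32^3 bundle: a pure 3-intensity scene for tissue segmentation
lesionfree_bundle <- function() {
  if (is.null(.fixtures$lf_bundle))
    .fixtures$lf_bundle <- generate_phantom(lesionfree_spec())
  .fixtures$lf_bundle
}

lesionfree_spec <- function(noise_t1 = 0, seed = 1L) {
  phantom_spec(
    lesion_specs = list(),
    noise_sd = c(flair = 0, t1 = noise_t1, gd_t1 = 0, dwi = 0, dsc = 0),
    aif_params = list(t0 = 2, alpha = 1.5, beta = 1.8, amplitude = 1),
    n_timepoints = 12L, seed = seed)
}

# small 16^3 spec without lesions, for perfusion Monte-Carlo sweeps
perf_spec <- function(noise_dsc = 0, seed = 1L) {
  phantom_spec(
    grid_shape = c(16L, 16L, 16L),
    lesion_specs = list(),
    nawm_ref_box = list(corner = c(5L, 5L, 3L), size = c(3L, 3L, 3L)),
    noise_sd = c(flair = 0, t1 = 0, gd_t1 = 0, dwi = 0, dsc = noise_dsc),
    seed = seed)
}

# 32^3 spec with a short DSC acquisition, for structural-only sweeps
structural_spec <- function(noise_t1 = 0, noise_dwi = 0, seed = 1L) {
  phantom_spec(
    noise_sd = c(flair = 0, t1 = noise_t1, gd_t1 = noise_t1,
                 dwi = noise_dwi, dsc = 0),
    aif_params = list(t0 = 2, alpha = 1.5, beta = 1.8, amplitude = 1),
    n_timepoints = 12L, seed = seed)
}

# lesion ROIs taken from the truth label volume (operator-independent)
truth_rois <- function(bundle) {
  lab <- bundle$truth_lesion_labels$data
  ids <- sort(unique(lab[lab > 0]))
  roi_set(lapply(ids, function(i)
    roi(i, which(lab == i, arr.ind = TRUE) - 1L)))
}

# classify the phantom's lesions from truth ROIs; returns class codes
phantom_classes <- function(bundle, mf = 2) {
  rs <- classify_lesions(truth_rois(bundle), bundle$t1, bundle$gd_t1,
                         bundle$nawm_ref_roi, mf = mf)
  les <- Filter(function(r) r$class_code != "NAWM_REF", rs$rois)
  vapply(les, `[[`, character(1), "class_code")
}

# tissue-pure masks of the reference phantom
wm_core_mask <- function(bundle) {
  bundle$truth_tissue_labels$data == 3 &
    bundle$truth_lesion_labels$data == 0 &
    bundle$truth_artery$data == 0 &
    bundle$truth_structure_labels$data == 0
}
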
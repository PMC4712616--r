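#' Gamma-variate arterial bolus curve
#'
#' Standard first-pass bolus model for the arterial input function (AIF):
#' C(t) = amplitude * (t - t0)^alpha * exp(-(t - t0)/beta) for t > t0 and 0
#' before arrival. The mode of the curve lies at t0 + alpha*beta.
#'
#' @param params list with fields `t0` (arrival delay, s), `alpha` (shape,
#'   > 0), `beta` (time scale, s, > 0), `amplitude` (>= 0).
#' @param times nondecreasing numeric vector of sample times (s), starting
#'   at 0.
#' @return numeric concentration curve, one value per time.
#' @export
gamma_variate_aif <- function(params, times) {
  for (f in c("t0", "alpha", "beta", "amplitude")) {
    v <- params[[f]]
    if (is.null(v) || !is.finite(v))
      stop(sprintf("AIF parameter '%s' must be finite", f), call. = FALSE)
  }
  if (params$alpha <= 0 || params$beta <= 0)
    stop("alpha and beta must be > 0", call. = FALSE)
  if (params$amplitude < 0)
    stop("amplitude must be >= 0", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) && (times[1] < 0 || is.unsorted(times)))
    stop("times must be nondecreasing and start at >= 0", call. = FALSE)
  dt <- times - params$t0
  out <- numeric(length(times))
  pos <- dt > 0
  out[pos] <- params$amplitude * dt[pos]^params$alpha * exp(-dt[pos] / params$beta)
  out
}

default_lesion_offsets <- function() {
  # per-class intensity offsets (added to the local tissue mean):
  # flair: always hyperintense; t1: hypo for C2/C4; gd_t1: enhancing for C1/C2
  list(
    C1 = c(flair = 200, t1 = 0,   gd_t1 = 60),
    C2 = c(flair = 200, t1 = -40, gd_t1 = 60),
    C3 = c(flair = 200, t1 = 0,   gd_t1 = 0),
    C4 = c(flair = 200, t1 = -40, gd_t1 = 0)
  )
}

#' Specification of a synthetic multi-modal phantom
#'
#' Defines the geometry, tissue intensities, lesion load, diffusion and
#' perfusion ground truth of a digital phantom that emulates one patient's
#' acquisition set (FLAIR, T1, Gd-T1, DWI b0 + three b=1000 axes, 4D DSC).
#'
#' Default intensities put CSF/GM/WM at typical relative T1 contrasts and
#' make lesions clearly separable from normal-appearing white matter; the
#' perfusion truth uses an exponential residue function so that MTT is the
#' exact exponential time constant (closed-form truth).
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_mm numeric length-3 voxel size (mm).
#' @param tissue_means named list of per-modality intensity per tissue:
#'   `list(flair=c(csf=,gm=,wm=), t1=..., gd_t1=...)`.
#' @param lesion_specs list of lesions, each
#'   `list(center=c(x,y,z) 0-based voxel, radius_mm=, class=, offsets=)`
#'   where `offsets` is a named vector over flair/t1/gd_t1; missing offsets
#'   default per class (see [default_lesion_offsets()]).
#' @param nawm_ref_box `list(corner=c(x,y,z), size=c(nx,ny,nz))`, 0-based,
#'   placed in pure WM; the normal-appearing-white-matter reference region.
#' @param noise_sd named numeric, additive Gaussian noise SD per modality
#'   (`flair`, `t1`, `gd_t1`, `dwi`, `dsc`); all >= 0.
#' @param adc_truth named numeric, ADC (mm^2/s) for `csf`, `gm`, `wm`,
#'   `lesion`.
#' @param perf_truth named list per tissue (`gm`, `wm`, `lesion`) of
#'   `c(cbf_rel=, cbv_rel=, mtt_s=)` with `mtt_s = cbv_rel / cbf_rel`.
#' @param aif_params gamma-variate parameters (see [gamma_variate_aif()]).
#' @param n_timepoints,tr_s,te_s DSC timing; the acquisition must cover the
#'   bolus (`n_timepoints * tr_s > t0 + bolus duration`).
#' @param b_value diffusion weighting, s/mm^2.
#' @param seed integer random seed.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_mm = c(2, 2, 2),
                         tissue_means = list(
                           flair = c(csf = 20, gm = 120, wm = 100),
                           t1    = c(csf = 30, gm = 80,  wm = 100),
                           gd_t1 = c(csf = 30, gm = 80,  wm = 100)),
                         lesion_specs = default_lesion_layout(grid_shape),
                         nawm_ref_box = list(corner = c(4L, 4L, 14L),
                                             size = c(5L, 5L, 4L)),
                         noise_sd = c(flair = 0, t1 = 0, gd_t1 = 0,
                                      dwi = 0, dsc = 0),
                         adc_truth = c(csf = 3.0e-3, gm = 0.8e-3,
                                       wm = 0.7e-3, lesion = 1.0e-3),
                         perf_truth = list(
                           gm     = c(cbf_rel = 0.015, cbv_rel = 0.060, mtt_s = 4),
                           wm     = c(cbf_rel = 0.010, cbv_rel = 0.040, mtt_s = 4),
                           lesion = c(cbf_rel = 0.020, cbv_rel = 0.080, mtt_s = 4)),
                         aif_params = list(t0 = 10, alpha = 1.5, beta = 1.8,
                                           amplitude = 1),
                         n_timepoints = 60L, tr_s = 1, te_s = 0.05,
                         b_value = 1000, seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), voxel_mm = as.numeric(voxel_mm),
               tissue_means = tissue_means, lesion_specs = lesion_specs,
               nawm_ref_box = nawm_ref_box, noise_sd = noise_sd,
               adc_truth = adc_truth, perf_truth = perf_truth,
               aif_params = aif_params, n_timepoints = as.integer(n_timepoints),
               tr_s = tr_s, te_s = te_s, b_value = b_value,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' Default lesion layout: two lesions of each class C1-C4
#'
#' Eight non-overlapping spherical lesions, two per evolution class, placed
#' inside the white matter of the default phantom geometry.
#'
#' @param grid_shape phantom grid (voxels per axis).
#' @return list of lesion specifications for [phantom_spec()].
#' @export
default_lesion_layout <- function(grid_shape = c(32L, 32L, 32L)) {
  sc <- grid_shape / 32  # positions scale with the grid
  pos <- list(c(10, 10, 10), c(22, 10, 10), c(10, 22, 10), c(22, 22, 10),
              c(10, 10, 22), c(22, 10, 22), c(10, 22, 22), c(22, 22, 22))
  cls <- c("C1", "C1", "C2", "C2", "C3", "C3", "C4", "C4")
  mapply(function(p, k) {
    list(center = round(p * sc), radius_mm = 4, class = k,
         offsets = default_lesion_offsets()[[k]])
  }, pos, cls, SIMPLIFY = FALSE)
}

validate_phantom_spec <- function(spec) {
  fail <- function(field, msg)
    stop(sprintf("invalid phantom spec: field '%s' %s", field, msg),
         call. = FALSE)
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 8L))
    fail("grid_shape", "must be 3 axes of at least 8 voxels")
  if (any(spec$voxel_mm <= 0)) fail("voxel_mm", "must be positive")
  if (any(unlist(spec$noise_sd) < 0)) fail("noise_sd", "must be >= 0")
  for (i in seq_along(spec$lesion_specs)) {
    les <- spec$lesion_specs[[i]]
    if (les$radius_mm <= 0) fail("lesion_specs", sprintf("lesion %d radius must be > 0", i))
    r_vox <- les$radius_mm / spec$voxel_mm
    if (any(les$center - r_vox < 0) ||
        any(les$center + r_vox > spec$grid_shape - 1))
      fail("lesion_specs", sprintf("lesion %d sphere leaves the grid", i))
    if (!les$class %in% c("C1", "C2", "C3", "C4"))
      fail("lesion_specs", sprintf("lesion %d class '%s' unknown", i, les$class))
  }
  # lesions must not overlap (keeps truth labels unambiguous)
  if (length(spec$lesion_specs) > 1) {
    for (i in seq_along(spec$lesion_specs)) {
      for (j in seq_len(i - 1)) {
        a <- spec$lesion_specs[[i]]; b <- spec$lesion_specs[[j]]
        d <- sqrt(sum(((a$center - b$center) * spec$voxel_mm)^2))
        if (d < a$radius_mm + b$radius_mm)
          fail("lesion_specs", sprintf("lesions %d and %d overlap", j, i))
      }
    }
  }
  for (tis in names(spec$perf_truth)) {
    p <- spec$perf_truth[[tis]]
    if (abs(p[["mtt_s"]] - p[["cbv_rel"]] / p[["cbf_rel"]]) > 1e-9 * p[["mtt_s"]])
      fail("perf_truth", sprintf("'%s' violates mtt = cbv/cbf", tis))
  }
  bolus_end <- spec$aif_params$t0 + 10 * spec$aif_params$alpha * spec$aif_params$beta / 3
  if (spec$n_timepoints * spec$tr_s <= bolus_end)
    fail("n_timepoints", "acquisition does not cover the bolus")
  box <- spec$nawm_ref_box
  if (any(box$corner < 0) || any(box$corner + box$size > spec$grid_shape))
    fail("nawm_ref_box", "leaves the grid")
  invisible(spec)
}

# concentric-ellipsoid anatomy: CSF ventricle core, WM interior, GM shell
phantom_tissue_labels <- function(spec) {
  d <- spec$grid_shape
  cx <- (d - 1) / 2
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  u <- sweep(idx, 2, cx)
  r <- sweep(u, 2, (d - 1) / 2, "/")      # normalized radius per axis
  rho <- sqrt(rowSums(r^2))
  lab <- integer(nrow(idx))                # 0 = background
  lab[rho <= 1.00] <- 2L                   # GM shell
  lab[rho <= 0.82] <- 3L                   # WM interior
  lab[rho <= 0.12] <- 1L                   # CSF ventricle core
  array(lab, dim = d)
}

# small spheres for deep grey structures (codes 11..18), inside WM
phantom_structure_labels <- function(spec) {
  d <- spec$grid_shape
  sc <- d / 32
  defs <- list(
    caudate_l = c(13, 16, 16), caudate_r = c(19, 16, 16),
    putamen_l = c(12, 19, 16), putamen_r = c(20, 19, 16),
    pallidus_l = c(13, 13, 16), pallidus_r = c(19, 13, 16),
    thalamus_l = c(15, 16, 19), thalamus_r = c(17, 16, 13))
  lab <- array(0L, dim = d)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  for (i in seq_along(defs)) {
    c_vox <- round(defs[[i]] * sc)
    mm <- sweep(idx, 2, c_vox) * rep(spec$voxel_mm, each = nrow(idx))
    inside <- sqrt(rowSums(mm^2)) <= 2.5  # 2.5 mm radius spheres
    lab[idx[inside, , drop = FALSE] + 1] <- 10L + i
  }
  lab
}

#' Code table for phantom label volumes
#' @return named integer vector mapping label names to codes.
#' @export
phantom_label_codes <- function() {
  c(csf = 1L, gm = 2L, wm = 3L,
    caudate_l = 11L, caudate_r = 12L, putamen_l = 13L, putamen_r = 14L,
    pallidus_l = 15L, pallidus_r = 16L, thalamus_l = 17L, thalamus_r = 18L)
}

sphere_mask <- function(grid_shape, voxel_mm, center_vox, radius_mm) {
  d <- grid_shape
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  mm <- sweep(idx, 2, center_vox) * rep(voxel_mm, each = nrow(idx))
  array(sqrt(rowSums(mm^2)) <= radius_mm, dim = d)
}

#' Generate a synthetic multi-modal phantom bundle
#'
#' Builds FLAIR, T1 and Gd-T1 structural volumes (tissue means + lesion
#' offsets + Gaussian noise), DWI channels obeying the Stejskal-Tanner
#' mono-exponential decay S_b = S0 exp(-b ADC), and a 4D DSC series whose
#' signal follows S(t) = S0 exp(-TE C(t)) with tissue concentration
#' C = cbf_rel * (AIF convolved with exp(-t/MTT)) discretized at TR.
#' A designated arterial sphere carries the AIF itself (10x tissue
#' amplitude, earliest peak) for arterial-input-function detection tests.
#' The same seed always yields a bit-identical bundle.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_bundle` list: structural volumes (`flair`, `t1`,
#'   `gd_t1`), diffusion volumes (`dwi_b0`, `dwi_x`, `dwi_y`, `dwi_z`),
#'   `dsc` time series, `brain_mask`, and ground truth: `truth_lesion_labels`,
#'   `truth_classes`, `truth_tissue_labels`, `truth_structure_labels`,
#'   `truth_artery` mask, `truth_maps` (adc/cbf/cbv/mtt), `truth_arrival`
#'   (0-based volume index), `truth_aif` curve, `nawm_ref_roi`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  d <- spec$grid_shape
  vox <- spec$voxel_mm
  aff <- diag(c(vox, 1))
  tis <- phantom_tissue_labels(spec)
  strc <- phantom_structure_labels(spec)
  strc[tis != 3L] <- 0L  # deep structures live in WM only
  brain <- tis > 0L

  # lesion truth labels (one id per lesion); lesions are white-matter
  # lesions by construction: their voxels are embedded in WM before any
  # intensity is laid down, so "offset relative to the WM mean" holds at
  # every lesion voxel even where a sphere would straddle a tissue shell
  les_lab <- array(0L, dim = d)
  classes <- character(length(spec$lesion_specs))
  for (i in seq_along(spec$lesion_specs)) {
    ls <- spec$lesion_specs[[i]]
    m <- sphere_mask(d, vox, ls$center, ls$radius_mm)
    les_lab[m] <- i
    classes[i] <- ls$class
  }
  names(classes) <- as.character(seq_along(classes))
  tis[les_lab > 0L] <- 3L
  strc[les_lab > 0L] <- 0L
  brain <- tis > 0L

  # structural volumes
  make_structural <- function(modality) {
    means <- spec$tissue_means[[modality]]
    img <- array(0, dim = d)
    img[tis == 1L] <- means[["csf"]]
    img[tis == 2L] <- means[["gm"]]
    img[tis == 3L] <- means[["wm"]]
    for (i in seq_along(spec$lesion_specs)) {
      ls <- spec$lesion_specs[[i]]
      off <- ls$offsets
      if (is.null(off)) off <- default_lesion_offsets()[[ls$class]]
      img[les_lab == i] <- img[les_lab == i] + off[[modality]]
    }
    sd <- spec$noise_sd[[modality]]
    if (sd > 0) img <- img + array(stats::rnorm(prod(d), 0, sd), dim = d)
    volume_image(img, vox, aff, space = "flair")
  }
  flair <- make_structural("flair")
  t1 <- make_structural("t1")
  gd_t1 <- make_structural("gd_t1")

  # diffusion: ADC truth volume then forward signal model
  adc <- array(0, dim = d)
  adc[tis == 1L] <- spec$adc_truth[["csf"]]
  adc[tis == 2L] <- spec$adc_truth[["gm"]]
  adc[tis == 3L] <- spec$adc_truth[["wm"]]
  adc[les_lab > 0L] <- spec$adc_truth[["lesion"]]
  s0_level <- 1000
  s0 <- array(0, dim = d); s0[brain] <- s0_level
  sb <- s0 * exp(-spec$b_value * adc)
  add_noise <- function(img, sd) {
    if (sd > 0) img + array(stats::rnorm(prod(d), 0, sd), dim = d) else img
  }
  nd <- spec$noise_sd[["dwi"]]
  dwi_b0 <- volume_image(add_noise(s0, nd), vox, aff, "dwi")
  dwi_x <- volume_image(add_noise(sb, nd), vox, aff, "dwi")
  dwi_y <- volume_image(add_noise(sb, nd), vox, aff, "dwi")
  dwi_z <- volume_image(add_noise(sb, nd), vox, aff, "dwi")

  # perfusion forward model
  nt <- spec$n_timepoints
  times <- (0:(nt - 1)) * spec$tr_s
  aif <- gamma_variate_aif(spec$aif_params, times)
  arrival <- which(times > spec$aif_params$t0)[1] - 1L  # 0-based

  conv_residue <- function(cbf_rel, mtt_s) {
    res <- exp(-times / mtt_s)
    # discrete convolution at TR: C[k] = cbf * TR * sum_j aif[j] res[k-j],
    # the same lower-triangular Toeplitz operator the deconvolution inverts
    cbf_rel * spec$tr_s * stats::convolve(aif, rev(res), type = "open")[1:nt]
  }
  curves <- list(
    gm = conv_residue(spec$perf_truth$gm[["cbf_rel"]], spec$perf_truth$gm[["mtt_s"]]),
    wm = conv_residue(spec$perf_truth$wm[["cbf_rel"]], spec$perf_truth$wm[["mtt_s"]]),
    lesion = conv_residue(spec$perf_truth$lesion[["cbf_rel"]],
                          spec$perf_truth$lesion[["mtt_s"]]))

  # arterial sphere: concentration = AIF itself (amplitude >> tissue curves)
  artery_center <- round(c(16, 26, 16) * d / 32)
  artery <- sphere_mask(d, vox, artery_center, 3) & brain & les_lab == 0L &
    strc == 0L

  s0_dsc <- 800
  dsc_arr <- array(0, dim = c(d, nt))
  conc_vol <- function(k) {
    cv <- array(0, dim = d)
    cv[tis == 2L] <- curves$gm[k]
    cv[tis == 3L] <- curves$wm[k]
    cv[les_lab > 0L] <- curves$lesion[k]
    cv[artery] <- aif[k]
    cv[tis == 1L] <- 0
    cv
  }
  for (k in seq_len(nt)) {
    sig <- array(0, dim = d)
    sig[brain] <- s0_dsc * exp(-spec$te_s * conc_vol(k)[brain])
    dsc_arr[, , , k] <- sig
  }
  nd_dsc <- spec$noise_sd[["dsc"]]
  if (nd_dsc > 0)
    dsc_arr <- dsc_arr + array(stats::rnorm(length(dsc_arr), 0, nd_dsc),
                               dim = dim(dsc_arr))
  dsc <- time_series_image(dsc_arr, spec$tr_s, spec$te_s, vox, aff, "dsc")

  # truth maps
  mk <- function(vals) {
    m <- array(0, dim = d)
    m[tis == 2L] <- vals[["gm"]]; m[tis == 3L] <- vals[["wm"]]
    m[les_lab > 0L] <- vals[["lesion"]]
    volume_image(m, vox, aff, "flair")
  }
  truth_maps <- list(
    adc = volume_image(adc, vox, aff, "flair"),
    cbf = mk(lapply(spec$perf_truth, `[[`, "cbf_rel")),
    cbv = mk(lapply(spec$perf_truth, `[[`, "cbv_rel")),
    mtt = mk(lapply(spec$perf_truth, `[[`, "mtt_s")))

  box <- spec$nawm_ref_box
  nawm_vox <- as.matrix(expand.grid(
    x = box$corner[1]:(box$corner[1] + box$size[1] - 1),
    y = box$corner[2]:(box$corner[2] + box$size[2] - 1),
    z = box$corner[3]:(box$corner[3] + box$size[3] - 1)))
  # keep only pure-WM voxels of the box
  keep <- tis[nawm_vox + 1] == 3L & les_lab[nawm_vox + 1] == 0L
  nawm_roi <- roi(id = 0L, voxels = nawm_vox[keep, , drop = FALSE],
                  class_code = "NAWM_REF", label_text = "NAWM reference")

  structure(list(
    spec = spec,
    flair = flair, t1 = t1, gd_t1 = gd_t1,
    dwi_b0 = dwi_b0, dwi_x = dwi_x, dwi_y = dwi_y, dwi_z = dwi_z,
    dsc = dsc,
    brain_mask = volume_image(array(as.numeric(brain), d), vox, aff, "flair"),
    truth_lesion_labels = volume_image(array(as.numeric(les_lab), d), vox, aff, "flair"),
    truth_classes = classes,
    truth_tissue_labels = volume_image(array(as.numeric(tis), d), vox, aff, "flair"),
    truth_structure_labels = volume_image(array(as.numeric(strc), d), vox, aff, "flair"),
    truth_artery = volume_image(array(as.numeric(artery), d), vox, aff, "flair"),
    truth_maps = truth_maps,
    truth_arrival = arrival,
    truth_aif = aif,
    nawm_ref_roi = nawm_roi
  ), class = "phantom_bundle")
}

#' Write a phantom bundle as NIfTI files plus a JSON truth manifest
#'
#' Filenames mirror the pipeline's canonical sequence names (flair, t1,
#' gd_t1, dwi_b0, dwi_x, dwi_y, dwi_z, dsc).
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vols <- c("flair", "t1", "gd_t1", "dwi_b0", "dwi_x", "dwi_y", "dwi_z")
  for (v in vols) write_volume(bundle[[v]], file.path(dir, paste0(v, ".nii.gz")))
  write_volume(bundle$dsc, file.path(dir, "dsc.nii.gz"))
  write_volume(bundle$brain_mask, file.path(dir, "brain_mask.nii.gz"),
               datatype = "uint8")
  write_volume(bundle$truth_lesion_labels,
               file.path(dir, "truth_lesion_labels.nii.gz"), datatype = "int16")
  write_volume(bundle$truth_tissue_labels,
               file.path(dir, "truth_tissue_labels.nii.gz"), datatype = "int16")
  manifest <- list(
    truth_classes = as.list(bundle$truth_classes),
    truth_arrival = bundle$truth_arrival,
    tr_s = bundle$dsc$tr_s, te_s = bundle$dsc$te_s,
    b_value = bundle$spec$b_value,
    adc_truth = as.list(bundle$spec$adc_truth),
    perf_truth = lapply(bundle$spec$perf_truth, as.list),
    seed = bundle$spec$seed)
  jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
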
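#' Per-volume mean intensity curve of a DSC series
#'
#' Mean signal over the brain mask for each timepoint; the noise-robust
#' summary curve used for contrast-arrival detection.
#'
#' @param dsc `time_series_image`.
#' @param brain_mask binary `volume_image` on the DSC grid.
#' @return numeric vector, one mean per volume.
#' @export
volume_mean_series <- function(dsc, brain_mask) {
  m <- brain_mask$data != 0
  if (!any(m)) stop("brain mask is empty", call. = FALSE)
  nt <- dim(dsc$data)[4]
  vapply(seq_len(nt), function(k) mean(dsc$data[, , , k][m]), numeric(1))
}

#' Detect the contrast arrival volume
#'
#' Walks the mean-intensity curve keeping a running baseline (cumulative
#' mean of all previous volumes, which suppresses noise) and reports the
#' first volume whose absolute deviation from the baseline exceeds an
#' adaptive threshold: `fraction` of the curve's global max-min range.
#' Using a range fraction rather than an absolute value makes the detector
#' independent of the signal's absolute intensity level, and using the
#' absolute deviation makes it agnostic to signal-drop vs signal-rise
#' contrast mechanisms.
#'
#' @param series numeric mean-intensity curve (length >= 4).
#' @param fraction adaptive threshold as a fraction of the curve range,
#'   in (0, 1); default 0.1.
#' @return 0-based arrival volume index.
#' @export
detect_arrival <- function(series, fraction = 0.1) {
  if (length(series) < 4L) stop("series too short (< 4)", call. = FALSE)
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  rng <- max(series) - min(series)
  if (rng == 0)
    stop("flat series: no contrast arrival detectable", call. = FALSE)
  thr <- fraction * rng
  for (k in 2:length(series)) {
    baseline <- mean(series[1:(k - 1)])
    if (abs(series[k] - baseline) > thr) return(k - 1L)  # 0-based
  }
  stop("no arrival found: no volume deviates beyond the threshold",
       call. = FALSE)
}

#' Convert DSC signal to contrast concentration
#'
#' Standard T2* relationship: C(t) = -ln(S(t)/S0)/TE, with S0 the per-voxel
#' mean of the pre-arrival baseline volumes (after discarding the first
#' `skip` non-steady-state volumes). Voxels or timepoints with non-positive
#' signal get concentration 0.
#'
#' @param dsc `time_series_image`.
#' @param arrival_index 0-based contrast arrival volume (>= 2, so at least
#'   one baseline volume remains after the discard).
#' @param skip number of initial volumes discarded from the baseline
#'   (default 1).
#' @return 4D concentration array (same dims as `dsc$data`).
#' @export
signal_to_concentration <- function(dsc, arrival_index, skip = 1L) {
  if (arrival_index < 2L)
    stop("arrival_index must be >= 2 (need baseline volumes)", call. = FALSE)
  nt <- dim(dsc$data)[4]
  base_idx <- (skip + 1):arrival_index  # 1-based volumes [skip .. arrival-1]
  s0 <- apply(dsc$data[, , , base_idx, drop = FALSE], 1:3, mean)
  conc <- array(0, dim(dsc$data))
  pos0 <- s0 > 0
  for (k in seq_len(nt)) {
    s <- dsc$data[, , , k]
    ok <- pos0 & s > 0
    ck <- array(0, dim(s))
    ck[ok] <- -log(s[ok] / s0[ok]) / dsc$te_s
    conc[, , , k] <- ck
  }
  conc
}

curve_fwhm <- function(curve, tr_s) {
  pk <- which.max(curve)
  half <- curve[pk] / 2
  above <- curve >= half
  sum(above) * tr_s  # samples above half maximum; adequate for ranking
}

#' Automatic arterial input function selection
#'
#' Ranks brain voxels by a composite score favouring the hallmarks of
#' arterial voxels: high peak concentration, early time-to-peak and a
#' narrow bolus (small full width at half maximum). Each property is rank
#' normalized and summed. The AIF is the voxelwise mean concentration
#' curve of the top `n_voxels` candidates, reported together with the
#' chosen voxel coordinates for visual verification. A user-supplied ROI
#' bypasses selection entirely (manual override).
#'
#' @param conc 4D concentration array.
#' @param brain_mask binary `volume_image`.
#' @param tr_s sampling interval, seconds.
#' @param arrival_index 0-based arrival volume (candidate peaks before
#'   arrival are impossible and scored out).
#' @param n_voxels number of top candidates averaged (default 10).
#' @param roi optional [roi()]: use its voxels as the AIF region directly.
#' @return list: `aif` (curve), `voxels` (n x 3 matrix of 0-based indices),
#'   `scores` (for the selected voxels).
#' @export
select_aif <- function(conc, brain_mask, tr_s, arrival_index,
                       n_voxels = 10L, roi = NULL) {
  d <- dim(conc)
  nt <- d[4]
  cmat_from <- function(lin) {
    # timepoint curves for linear voxel indices: n x nt matrix
    nvox <- prod(d[1:3])
    m <- vapply(seq_len(nt), function(k) conc[(k - 1) * nvox + lin],
                numeric(length(lin)))
    matrix(m, nrow = length(lin), ncol = nt)
  }
  if (!is.null(roi)) {
    lin <- roi_linear_index(roi, d[1:3])
    curves <- cmat_from(lin)
    return(list(aif = colMeans(curves), voxels = roi$voxels, scores = NULL))
  }
  lin <- which(brain_mask$data != 0)
  curves <- cmat_from(lin)           # n x nt
  peaks <- apply(curves, 1, max)
  if (!any(peaks > 0)) stop("no voxel with positive peak concentration",
                            call. = FALSE)
  ttp <- apply(curves, 1, which.max)
  # physiological candidate gate: a credible arterial bolus peaks at or
  # after contrast arrival and reaches a substantial concentration
  keep <- peaks >= 0.3 * max(peaks) & (ttp - 1) >= arrival_index
  if (!any(keep)) keep <- peaks > 0
  lin <- lin[keep]; curves <- curves[keep, , drop = FALSE]
  peaks <- peaks[keep]; ttp <- ttp[keep]
  fwhm <- apply(curves, 1, curve_fwhm, tr_s = tr_s)
  score <- rank(peaks) - rank(ttp) - rank(fwhm)
  n_sel <- min(n_voxels, length(lin))
  sel <- order(score, decreasing = TRUE)[seq_len(n_sel)]
  idx0 <- arrayInd(lin[sel], d[1:3]) - 1L
  colnames(idx0) <- c("x", "y", "z")
  list(aif = colMeans(curves[sel, , drop = FALSE]),
       voxels = idx0, scores = score[sel])
}

#' Truncated-SVD deconvolution of a tissue curve against the AIF
#'
#' Solves the bolus-tracking convolution C_tissue = A k where A is the
#' lower-triangular Toeplitz matrix of the AIF scaled by the sampling
#' interval (A[i,j] = TR * AIF[i-j+1] for j <= i), via singular value
#' decomposition with singular values below `svd_threshold` times the
#' largest zeroed. k(t) is the CBF-scaled residue function.
#'
#' @param c_tissue tissue concentration curve.
#' @param aif arterial input function curve, same length (>= 8), not all
#'   zero.
#' @param tr_s sampling interval, seconds.
#' @param svd_threshold truncation fraction of the largest singular value
#'   (default 0.2).
#' @return numeric k(t), same length as the inputs.
#' @export
svd_deconvolve <- function(c_tissue, aif, tr_s, svd_threshold = 0.2) {
  n <- length(aif)
  if (length(c_tissue) != n || n < 8L)
    stop("curves must have equal length >= 8", call. = FALSE)
  if (all(aif == 0)) stop("AIF is all-zero", call. = FALSE)
  A <- aif_toeplitz(aif, tr_s)
  dinv <- truncated_inverse_singulars(svd(A), svd_threshold)
  sv <- attr(dinv, "svd")
  as.vector(sv$v %*% (dinv * crossprod(sv$u, c_tissue)))
}

# reciprocal singular values with truncation; numerically-zero singular
# values are always dropped (a bolus AIF with leading zeros makes the
# Toeplitz operator rank-deficient and the pseudoinverse is intended)
truncated_inverse_singulars <- function(sv, svd_threshold) {
  cut <- max(svd_threshold, 1e-10) * sv$d[1]
  keep <- sv$d >= cut & sv$d > 0
  if (!any(keep))
    stop("all singular values fall below the truncation cutoff", call. = FALSE)
  structure(ifelse(keep, 1 / sv$d, 0), svd = sv)
}

aif_toeplitz <- function(aif, tr_s) {
  n <- length(aif)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- aif[1:(n - j + 1)]
  tr_s * A
}

#' Generate CBF, CBV and MTT maps from a DSC concentration series
#'
#' Per masked voxel: CBF is the maximum of the SVD-deconvolved residue
#' k(t); CBV is the ratio of the trapezoidal integrals of the tissue curve
#' and the AIF; MTT = CBV / CBF (central volume theorem) wherever CBF is
#' positive, 0 elsewhere. All maps are relative measurements — no
#' hematocrit or tissue-density constants are applied.
#'
#' @param conc 4D concentration array.
#' @param aif AIF curve.
#' @param tr_s sampling interval, seconds.
#' @param brain_mask binary `volume_image` (also supplies grid metadata).
#' @param svd_threshold truncation fraction for [svd_deconvolve()].
#' @param arrival_index 0-based arrival volume recorded in the result.
#' @param aif_voxels optional matrix of contributing AIF voxels (for the
#'   verification record).
#' @param eps CBF values at or below this are treated as zero-flow
#'   (default 1e-12).
#' @return A `perfusion_result` list: `cbf`, `cbv`, `mtt` (`volume_image`),
#'   `aif`, `aif_voxels`, `arrival_index`, `svd_threshold`, and
#'   `valid_mask` (voxels with positive flow, usable in region stats).
#' @export
perfusion_maps <- function(conc, aif, tr_s, brain_mask, svd_threshold = 0.2,
                           arrival_index = NA_integer_, aif_voxels = NULL,
                           eps = 1e-12) {
  d <- dim(conc)
  nt <- d[4]
  aif_int <- trapz_curve(aif, tr_s)
  if (aif_int <= 0) stop("AIF integral must be > 0", call. = FALSE)
  dinv <- truncated_inverse_singulars(svd(aif_toeplitz(aif, tr_s)),
                                      svd_threshold)
  sv <- attr(dinv, "svd")
  Ainv <- sv$v %*% (as.vector(dinv) * t(sv$u))

  lin <- which(brain_mask$data != 0)
  nvox_all <- prod(d[1:3])
  curves <- vapply(seq_len(nt), function(k) conc[(k - 1) * nvox_all + lin],
                   numeric(length(lin)))          # n x nt
  K <- curves %*% t(Ainv)                          # residue curves, n x nt
  cbf_v <- apply(K, 1, max)
  cbf_v[cbf_v < 0] <- 0
  # trapezoidal integral of each tissue curve
  w <- rep(tr_s, nt); w[c(1, nt)] <- tr_s / 2
  cbv_v <- as.vector(curves %*% w) / aif_int
  cbv_v[cbv_v < 0] <- 0
  mtt_v <- ifelse(cbf_v > eps, cbv_v / cbf_v, 0)

  shape <- function(vals) {
    a <- array(0, d[1:3]); a[lin] <- vals
    volume_image(a, brain_mask$voxel_mm, brain_mask$affine, brain_mask$space)
  }
  valid <- array(FALSE, d[1:3]); valid[lin] <- cbf_v > eps
  structure(list(
    cbf = shape(cbf_v), cbv = shape(cbv_v), mtt = shape(mtt_v),
    aif = aif, aif_voxels = aif_voxels, arrival_index = arrival_index,
    svd_threshold = svd_threshold, valid_mask = valid,
    units = c(cbf = "relative (ml/100g/min scale)",
              cbv = "relative (ml/100g scale)", mtt = "s")),
    class = "perfusion_result")
}

trapz_curve <- function(y, dt) {
  n <- length(y)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

#' Write the AIF curve and contributing voxels to JSON
#'
#' Persists the automatically selected arterial input function for
#' post-processing visual verification.
#'
#' @param result `perfusion_result` (or any list with `aif`, `aif_voxels`,
#'   `arrival_index`, `svd_threshold`).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_aif_json <- function(result, path) {
  vox <- result$aif_voxels
  jsonlite::write_json(list(
    aif = result$aif,
    voxels = if (is.null(vox)) list() else unname(as.matrix(vox)),
    arrival_index = result$arrival_index,
    svd_threshold = result$svd_threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
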
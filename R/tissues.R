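#' Normal-appearing grey and white matter masks
#'
#' Subtracts the registered lesion mask from the grey- and white-matter
#' masks: NAGM = GM AND NOT lesion, NAWM = WM AND NOT lesion. By
#' construction neither output intersects the lesion mask.
#'
#' @param gm_mask,wm_mask binary `volume_image`s on the T1 grid.
#' @param lesion_mask_t1 binary lesion mask registered on the same grid.
#' @return list with binary `volume_image`s `nagm` and `nawm`.
#' @export
make_normal_appearing <- function(gm_mask, wm_mask, lesion_mask_t1) {
  stop_if_grid_mismatch(gm_mask, wm_mask, "tissue masks")
  stop_if_grid_mismatch(gm_mask, lesion_mask_t1, "tissue and lesion masks")
  les <- lesion_mask_t1$data != 0
  mk <- function(m) volume_image((m$data != 0 & !les) + 0, m$voxel_mm,
                                 m$affine, m$space)
  list(nagm = mk(gm_mask), nawm = mk(wm_mask))
}

#' Fallback intensity-based tissue segmentation
#'
#' Three-class clustering of T1 intensities inside the brain mask, mapped
#' by ascending mean intensity to CSF < GM < WM (T1 contrast). The two
#' class boundaries are found as the deepest valleys of the kernel density
#' of the masked intensities (histogram valley thresholding — robust to
#' the strong class imbalance between CSF and the parenchyma, where a
#' within-variance criterion like k-means would rather split white
#' matter), then polished by one-dimensional Lloyd iterations from the
#' valley-defined class means. Deterministic for a given input; the
#' `seed` argument exists for forward compatibility with stochastic
#' refinements. Invariant to positive affine intensity rescaling.
#' This is a simplified stand-alone segmenter for externally unsegmented
#' data and phantoms; atlas- or shape-model-based segmentations can be
#' supplied instead wherever a label volume is accepted.
#'
#' @param t1 `volume_image`, non-enhanced T1.
#' @param brain_mask binary `volume_image`.
#' @param seed integer, reserved (see above).
#' @return A `tissue_labels` list: `labels` (`volume_image` with codes
#'   1=CSF, 2=GM, 3=WM, 0=background) and `code_table` (named codes).
#' @export
fallback_tissue_segmentation <- function(t1, brain_mask, seed = 1L) {
  stop_if_grid_mismatch(t1, brain_mask, "T1 and brain mask")
  inmask <- brain_mask$data != 0
  if (!any(inmask)) stop("brain mask is empty", call. = FALSE)
  v <- t1$data[inmask]
  if (stats::sd(v) == 0)
    stop("constant image inside mask: cannot segment", call. = FALSE)
  thr <- density_valley_thresholds(v, k = 3)
  cls <- findInterval(v, thr) + 1L   # 1..3, ordered by intensity
  # 1-D Lloyd polish: boundaries at midpoints of adjacent class means
  for (it in 1:100) {
    mu <- vapply(1:3, function(k) mean(v[cls == k]), numeric(1))
    bnd <- (mu[-3] + mu[-1]) / 2
    new_cls <- findInterval(v, bnd) + 1L
    if (all(tabulate(new_cls, 3) > 0) && !identical(new_cls, cls))
      cls <- new_cls
    else break
  }
  lab <- array(0, dim(t1$data))
  lab[inmask] <- cls
  list(labels = volume_image(lab, t1$voxel_mm, t1$affine, t1$space),
       code_table = c(csf = 1L, gm = 2L, wm = 3L))
}

# k-1 thresholds separating the k most persistent modes of the kernel
# density of v. Mode persistence (peak height minus the saddle at which
# the mode merges into a taller one) ranks genuine tissue modes far above
# sampling micro-structure, which a deepest-valley or within-variance
# criterion does not. Falls back to quantile boundaries when the density
# carries fewer than k modes.
density_valley_thresholds <- function(v, k = 3) {
  den <- stats::density(v, adjust = 2, n = 512)
  x <- den$x; y <- den$y
  n <- length(y)
  ids <- integer(n)            # grid cell -> component id (its peak index)
  parent <- seq_len(n)         # union-find over peak ids
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  deaths_peak <- integer(0); deaths_saddle <- integer(0)
  deaths_pers <- numeric(0)
  for (i in order(y, decreasing = TRUE)) {
    left <- if (i > 1L && ids[i - 1L] != 0L) find_root(ids[i - 1L]) else 0L
    right <- if (i < n && ids[i + 1L] != 0L) find_root(ids[i + 1L]) else 0L
    if (left == 0L && right == 0L) {
      ids[i] <- i                       # a new mode is born at its peak
    } else if (left != 0L && right != 0L && left != right) {
      dying <- if (y[left] < y[right]) left else right
      surv <- if (dying == left) right else left
      deaths_peak <- c(deaths_peak, dying)
      deaths_saddle <- c(deaths_saddle, i)
      deaths_pers <- c(deaths_pers, y[dying] - y[i])
      parent[dying] <- surv
      ids[i] <- surv
    } else {
      ids[i] <- max(left, right)
    }
  }
  n_sel <- min(k - 1, length(deaths_pers))
  thr <- sort(x[deaths_saddle[order(deaths_pers,
                                    decreasing = TRUE)[seq_len(n_sel)]]])
  ok <- length(thr) == k - 1 &&
    all(tabulate(findInterval(v, thr) + 1L, k) > 0)
  if (!ok)
    thr <- stats::quantile(v, seq_len(k - 1) / k, names = FALSE)
  thr
}

#' Extract a binary mask for one label code
#' @param labels label `volume_image`.
#' @param code integer code to extract.
#' @return binary `volume_image`.
#' @export
label_mask <- function(labels, code) {
  volume_image((labels$data == code) + 0, labels$voxel_mm, labels$affine,
               labels$space)
}

#' Skull-size-normalized volume
#'
#' Multiplies a raw volume by a volumetric scaling factor (as produced by
#' skull-based normalization tools); with the default factor 1 the volume
#' is unchanged.
#'
#' @param volume_mm3 raw volume, mm^3.
#' @param vscale volumetric scaling factor (> 0).
#' @return normalized volume.
#' @export
normalized_volume <- function(volume_mm3, vscale = 1) {
  if (!is.finite(vscale) || vscale <= 0)
    stop("vscale must be > 0", call. = FALSE)
  volume_mm3 * vscale
}

#' Write tissue labels with their JSON code table
#' @param tissue `tissue_labels` list (`labels` + `code_table`).
#' @param path NIfTI output path; the code table goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_tissue_labels <- function(tissue, path) {
  write_volume(tissue$labels, path, datatype = "int16")
  jsonlite::write_json(as.list(tissue$code_table), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
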
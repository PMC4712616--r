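#' Lesion region of interest
#'
#' A labelled voxel region on the FLAIR grid. Class codes: `NAWM_REF` (the
#' manually outlined normal-appearing white matter reference region),
#' `UNCLASSIFIED`, or one of the four evolution classes `C1` (Gd-enhancing,
#' T1-isointense), `C2` (Gd-enhancing, T1-hypointense), `C3` (non-enhancing,
#' T1-isointense), `C4` (non-enhancing, T1-hypointense — "black hole").
#' C1/C2 are considered acute, C3/C4 chronic.
#'
#' @param id integer ROI id.
#' @param voxels n x 3 matrix of 0-based voxel indices (unique rows).
#' @param class_code one of NAWM_REF, UNCLASSIFIED, C1, C2, C3, C4.
#' @param label_text free descriptive text.
#' @param color RGB hex display code; defaults per class.
#' @param flags character vector of warning flags (e.g. "touches_boundary").
#' @return A `roi` object.
#' @export
roi <- function(id, voxels, class_code = "UNCLASSIFIED", label_text = "",
                color = NULL, flags = character()) {
  voxels <- matrix(as.integer(voxels), ncol = 3)
  colnames(voxels) <- c("x", "y", "z")
  if (nrow(voxels) == 0L) stop("roi must contain voxels", call. = FALSE)
  if (anyDuplicated(voxels)) stop("roi voxels must be unique", call. = FALSE)
  valid <- c("NAWM_REF", "UNCLASSIFIED", "C1", "C2", "C3", "C4")
  if (!class_code %in% valid)
    stop("unknown class_code '", class_code, "'", call. = FALSE)
  structure(list(id = as.integer(id), voxels = voxels,
                 class_code = class_code, label_text = label_text,
                 color = color %||% class_color(class_code),
                 flags = flags),
            class = "roi")
}

#' Display colors per lesion class
#' @param class_code class code string.
#' @return RGB hex string.
#' @export
class_color <- function(class_code) {
  c(NAWM_REF = "#00FF00", UNCLASSIFIED = "#AAAAAA",
    C1 = "#FF0000", C2 = "#FF8800", C3 = "#0088FF", C4 = "#000088")[[class_code]]
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi %d> %s, %d voxels%s\n", x$id, x$class_code,
              nrow(x$voxels),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' A set of ROIs
#' @param rois list of [roi()] objects with unique ids.
#' @return A `roi_set` object (list with field `rois`).
#' @export
roi_set <- function(rois = list()) {
  ids <- vapply(rois, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("duplicate roi ids", call. = FALSE)
  structure(list(rois = rois), class = "roi_set")
}

#' @export
length.roi_set <- function(x) length(x$rois)

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d rois\n", length(x$rois)))
  for (r in x$rois) print(r)
  invisible(x)
}

lesion_rois <- function(rs) {
  Filter(function(r) r$class_code != "NAWM_REF", rs$rois)
}

roi_linear_index <- function(r, dims) {
  r$voxels[, 1] + dims[1] * (r$voxels[, 2] + dims[2] * r$voxels[, 3]) + 1
}

roi_values <- function(r, image) image$data[roi_linear_index(r, dim(image$data))]

#' Grow a lesion ROI from a seed voxel on FLAIR
#'
#' Local threshold-based region growing: the threshold is
#' `local_factor` times the peak intensity of the seed's 3x3x3
#' neighbourhood, and the ROI is the 26-connected component containing the
#' seed among voxels at or above threshold. Deterministic. If the region
#' touches the grid boundary the ROI is flagged `"touches_boundary"`.
#'
#' @param flair FLAIR `volume_image`.
#' @param seed length-3 0-based voxel index with positive intensity.
#' @param local_factor fraction in (0, 1] of the local peak.
#' @param id id to assign to the resulting [roi()].
#' @return a [roi()] with class `UNCLASSIFIED`.
#' @export
grow_lesion_roi <- function(flair, seed, local_factor = 0.5, id = 1L) {
  d <- dim(flair$data)
  seed <- as.integer(seed)
  if (any(seed < 0) || any(seed >= d))
    stop("seed outside grid", call. = FALSE)
  if (flair$data[matrix(seed + 1, 1)] <= 0)
    stop("seed intensity must be > 0", call. = FALSE)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb_seed <- sweep(nb, 2, seed, "+")
  inside <- nb_seed[, 1] >= 0 & nb_seed[, 1] < d[1] &
            nb_seed[, 2] >= 0 & nb_seed[, 2] < d[2] &
            nb_seed[, 3] >= 0 & nb_seed[, 3] < d[3]
  peak <- max(flair$data[nb_seed[inside, , drop = FALSE] + 1])
  thr <- local_factor * peak
  eligible <- flair$data >= thr
  # iterative 26-connected dilation from the seed within eligible voxels
  region <- array(FALSE, d)
  region[matrix(seed + 1, 1)] <- TRUE
  offsets <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  repeat {
    grown <- region
    for (k in seq_len(nrow(offsets))) {
      o <- offsets[k, ]
      src <- list(clamp_range(1 - o[1], d[1] - o[1], d[1]),
                  clamp_range(1 - o[2], d[2] - o[2], d[2]),
                  clamp_range(1 - o[3], d[3] - o[3], d[3]))
      dst <- lapply(1:3, function(ax) src[[ax]] + o[ax])
      grown[dst[[1]], dst[[2]], dst[[3]]] <-
        grown[dst[[1]], dst[[2]], dst[[3]]] |
        region[src[[1]], src[[2]], src[[3]]]
    }
    grown <- grown & eligible
    grown[matrix(seed + 1, 1)] <- TRUE
    if (identical(grown, region)) break
    region <- grown
  }
  vox <- which(region, arr.ind = TRUE) - 1L
  flags <- character()
  if (any(vox == 0) || any(sweep(vox, 2, d - 1L) == 0))
    flags <- "touches_boundary"
  roi(id, vox, "UNCLASSIFIED",
      label_text = sprintf("grown from seed (%d,%d,%d), factor %.3f",
                           seed[1], seed[2], seed[3], local_factor),
      flags = flags)
}

clamp_range <- function(from, to, n) max(1, from):min(n, to)

#' Mean and sample SD of an image over the NAWM reference ROI
#'
#' @param image `volume_image`.
#' @param nawm_roi a [roi()] with class `NAWM_REF` and at least 2 voxels.
#' @return named numeric `c(mean=, sd=)` (sample SD, n-1 denominator).
#' @export
nawm_stats <- function(image, nawm_roi) {
  if (nawm_roi$class_code != "NAWM_REF")
    stop("nawm_roi must have class NAWM_REF", call. = FALSE)
  if (nrow(nawm_roi$voxels) < 2L)
    stop("NAWM ROI needs >= 2 voxels (SD undefined)", call. = FALSE)
  v <- roi_values(nawm_roi, image)
  c(mean = mean(v), sd = stats::sd(v))
}

#' Lesion classification thresholds from NAWM statistics
#'
#' The two intensity thresholds separating hypointense, isointense and
#' hyperintense (enhancing) lesions are a configurable multiple of the NAWM
#' standard deviation around the NAWM mean:
#' `thre_high = mean + mf * sd`, `thre_low = mean - mf * sd`.
#'
#' @param mean NAWM mean intensity.
#' @param sd NAWM intensity SD (>= 0).
#' @param mf multiplier factor (>= 0); default 2.
#' @param modality which T1-weighted image the thresholds apply to
#'   ("t1" or "gd_t1").
#' @return A `class_thresholds` object with fields `mean_nawm`, `sd_nawm`,
#'   `mf`, `thre_low`, `thre_high`, `modality`.
#' @export
classification_thresholds <- function(mean, sd, mf = 2, modality = "t1") {
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (!is.finite(mf) || mf < 0) stop("mf must be >= 0", call. = FALSE)
  structure(list(mean_nawm = mean, sd_nawm = sd, mf = mf,
                 thre_low = mean - mf * sd, thre_high = mean + mf * sd,
                 modality = modality),
            class = "class_thresholds")
}

#' @export
print.class_thresholds <- function(x, ...) {
  cat(sprintf("<class_thresholds %s> NAWM %.2f +/- %.2f, Mf=%.2f -> [%.2f, %.2f]\n",
              x$modality, x$mean_nawm, x$sd_nawm, x$mf, x$thre_low, x$thre_high))
  invisible(x)
}

#' Classify lesions into the four evolution classes
#'
#' For each lesion ROI the summary intensity (mean by default, median
#' optionally) is computed on the registered non-enhanced T1 and the
#' registered Gd-enhanced T1, and compared with per-modality thresholds
#' derived independently from the NAWM reference ROI on each image:
#' a lesion is *enhancing* iff its Gd-T1 summary exceeds the Gd-T1 high
#' threshold, and *T1-hypointense* iff its T1 summary falls below the T1
#' low threshold. Classes: C1 enhancing/isointense, C2 enhancing/
#' hypointense, C3 non-enhancing/isointense, C4 non-enhancing/hypointense.
#' Comparisons are strict; equality counts as isointense/non-enhancing.
#' A lesion above the T1 high threshold (T1-hyperintense, outside the
#' four-class scheme) is treated as isointense and flagged
#' `"t1_hyperintense"`.
#'
#' @param rois [roi_set()] of segmented lesions (NAWM_REF entries allowed
#'   and skipped).
#' @param r_t1,r_gd_t1 `volume_image`s registered on the FLAIR grid.
#' @param nawm_roi NAWM reference [roi()], valid on both images.
#' @param mf multiplier factor for [classification_thresholds()].
#' @param stat "mean" (default) or "median" lesion summary statistic.
#' @return A [roi_set()] with class codes, per-class colors and descriptive
#'   labels filled in, plus attributes `thresholds` (per modality) and
#'   `acute_ids` / `chronic_ids`.
#' @export
classify_lesions <- function(rois, r_t1, r_gd_t1, nawm_roi, mf = 2,
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stop_if_grid_mismatch(r_t1, r_gd_t1, "registered T1 images")
  st_t1 <- nawm_stats(r_t1, nawm_roi)
  st_gd <- nawm_stats(r_gd_t1, nawm_roi)
  thr_t1 <- classification_thresholds(st_t1[["mean"]], st_t1[["sd"]], mf, "t1")
  thr_gd <- classification_thresholds(st_gd[["mean"]], st_gd[["sd"]], mf, "gd_t1")
  sumfun <- if (stat == "mean") mean else stats::median
  nawm_lin <- roi_linear_index(nawm_roi, dim(r_t1$data))
  d <- dim(r_t1$data)

  out <- lapply(rois$rois, function(r) {
    if (r$class_code == "NAWM_REF") return(r)
    lin <- roi_linear_index(r, d)
    if (any(lin %in% nawm_lin))
      r$flags <- union(r$flags, "overlaps_nawm_ref")
    if (any(r$voxels < 0) || any(sweep(r$voxels, 2, dim(r_t1$data)) >= 0)) {
      r$class_code <- "UNCLASSIFIED"
      r$label_text <- "unclassified: outside registered image field"
      return(r)
    }
    m_t1 <- sumfun(r_t1$data[lin])
    m_gd <- sumfun(r_gd_t1$data[lin])
    enhancing <- m_gd > thr_gd$thre_high
    hypo <- m_t1 < thr_t1$thre_low
    if (m_t1 > thr_t1$thre_high)
      r$flags <- union(r$flags, "t1_hyperintense")
    code <- if (enhancing && !hypo) "C1"
            else if (enhancing && hypo) "C2"
            else if (!enhancing && !hypo) "C3"
            else "C4"
    r$class_code <- code
    r$color <- class_color(code)
    r$label_text <- sprintf(
      "%s (%s): %s t1=%.3f [low %.3f], gd_t1=%.3f [high %.3f]",
      code, if (code %in% c("C1", "C2")) "acute" else "chronic",
      stat, m_t1, thr_t1$thre_low, m_gd, thr_gd$thre_high)
    r
  })
  res <- roi_set(out)
  ids <- vapply(lesion_rois(res), `[[`, integer(1), "id")
  cls <- vapply(lesion_rois(res), `[[`, character(1), "class_code")
  attr(res, "thresholds") <- list(t1 = thr_t1, gd_t1 = thr_gd)
  attr(res, "acute_ids") <- ids[cls %in% c("C1", "C2")]
  attr(res, "chronic_ids") <- ids[cls %in% c("C3", "C4")]
  res
}

#' Write / read a ROI set as a human-editable text file
#'
#' Plain-text dialect, one block per ROI: a header line
#' `ROI <id> <class_code> <color> | <label>` followed by one `v x y z` line
#' per voxel (0-based indices). The file can be hand-edited between write
#' and read to revise class codes (the manual revision round-trip); reading
#' a written file reproduces the set field-for-field.
#'
#' @param rois [roi_set()].
#' @param path file path.
#' @return `path` invisibly (write); [roi_set()] (read).
#' @export
write_roiset <- function(rois, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# roi set v1", con)
  for (r in rois$rois) {
    writeLines(sprintf("ROI %d %s %s | %s", r$id, r$class_code, r$color,
                       r$label_text), con)
    writeLines(sprintf("v %d %d %d", r$voxels[, 1], r$voxels[, 2],
                       r$voxels[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_roiset
#' @export
read_roiset <- function(path) {
  lines <- readLines(path)
  rois <- list()
  cur <- NULL
  flush_roi <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (length(cur$vox) == 0L)
      stop(sprintf("parse error at line %d: ROI %d has no voxels",
                   cur$line, cur$id), call. = FALSE)
    roi(cur$id, do.call(rbind, cur$vox), cur$class_code, cur$label,
        cur$color)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*(#|$)", ln)) next
    if (grepl("^ROI ", ln)) {
      if (!is.null(cur)) rois[[length(rois) + 1L]] <- flush_roi(cur)
      m <- regmatches(ln, regexec(
        "^ROI\\s+(-?\\d+)\\s+(\\S+)\\s+(\\S+)\\s*\\|\\s?(.*)$", ln))[[1]]
      if (length(m) != 5)
        stop(sprintf("parse error at line %d: malformed ROI header", i),
             call. = FALSE)
      cur <- list(id = as.integer(m[2]), class_code = m[3], color = m[4],
                  label = m[5], vox = list(), line = i)
    } else if (grepl("^v ", ln)) {
      if (is.null(cur))
        stop(sprintf("parse error at line %d: voxel before ROI header", i),
             call. = FALSE)
      xyz <- suppressWarnings(as.integer(strsplit(trimws(ln), "\\s+")[[1]][-1]))
      if (length(xyz) != 3 || anyNA(xyz))
        stop(sprintf("parse error at line %d: expected 'v x y z'", i),
             call. = FALSE)
      cur$vox[[length(cur$vox) + 1L]] <- xyz
    } else {
      stop(sprintf("parse error at line %d: unrecognized line", i),
           call. = FALSE)
    }
  }
  if (!is.null(cur)) rois[[length(rois) + 1L]] <- flush_roi(cur)
  roi_set(rois)
}

#' Binary masks per lesion category
#'
#' Emits the lesion inventory as binary masks on a reference grid: the
#' total lesion mask (union of all lesion ROIs), one mask per class C1-C4
#' (always emitted, possibly empty), and one mask per single lesion.
#' NAWM reference ROIs are excluded throughout.
#'
#' @param rois classified [roi_set()].
#' @param grid `volume_image` defining the output grid.
#' @return list with `total` (`volume_image`), `by_class` (named list
#'   C1..C4) and `by_lesion` (named by roi id).
#' @export
class_masks <- function(rois, grid) {
  d <- dim(grid$data)
  empty <- function() array(0, d)
  les <- lesion_rois(rois)
  by_class <- stats::setNames(
    lapply(c("C1", "C2", "C3", "C4"), function(k) empty()),
    c("C1", "C2", "C3", "C4"))
  by_lesion <- list()
  total <- empty()
  for (r in les) {
    lin <- roi_linear_index(r, d)
    m <- empty(); m[lin] <- 1
    by_lesion[[as.character(r$id)]] <-
      volume_image(m, grid$voxel_mm, grid$affine, grid$space)
    total[lin] <- 1
    if (r$class_code %in% names(by_class))
      by_class[[r$class_code]][lin] <- 1
  }
  list(
    total = volume_image(total, grid$voxel_mm, grid$affine, grid$space),
    by_class = lapply(by_class, volume_image, voxel_mm = grid$voxel_mm,
                      affine = grid$affine, space = grid$space),
    by_lesion = by_lesion)
}
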
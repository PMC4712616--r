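#' Affine transform between two image spaces
#'
#' A 4x4 homogeneous matrix mapping world coordinates (mm) of the source
#' space to world coordinates of the target space.
#'
#' @param matrix 4x4 numeric, last row (0,0,0,1), invertible.
#' @param source_space,target_space space labels.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(matrix, source_space = "unknown",
                             target_space = "unknown") {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4L, 4L)) ||
      max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("transform must be 4x4 with last row (0,0,0,1)", call. = FALSE)
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("transform matrix is singular", call. = FALSE)
  structure(list(matrix = matrix, source_space = source_space,
                 target_space = target_space),
            class = "affine_transform")
}

#' Identity transform
#' @param space space label used for both source and target.
#' @return `affine_transform`.
#' @export
identity_transform <- function(space = "unknown") {
  affine_transform(diag(4), space, space)
}

#' Invert an affine transform
#' @param tf an `affine_transform`.
#' @return the inverse transform (spaces swapped).
#' @export
invert_transform <- function(tf) {
  affine_transform(solve(tf$matrix), tf$target_space, tf$source_space)
}

#' Compose transforms (apply `a` after `b`)
#' @param a,b `affine_transform`s with `b$target_space == a$source_space`.
#' @return composed `affine_transform` mapping b's source to a's target.
#' @export
compose_transforms <- function(a, b) {
  affine_transform(a$matrix %*% b$matrix, b$source_space, a$target_space)
}

#' Build a rigid (6-DOF) world transform
#'
#' Rotations are applied in x, y, z order about `center` (mm), followed by
#' translation.
#'
#' @param angles_rad length-3 rotation angles (radians).
#' @param translation_mm length-3 translation (mm).
#' @param center length-3 rotation center in world mm (default origin).
#' @param source_space,target_space labels.
#' @return `affine_transform`.
#' @export
rigid_transform <- function(angles_rad = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center = c(0, 0, 0),
                            source_space = "unknown",
                            target_space = "unknown") {
  cx <- cos(angles_rad[1]); sx <- sin(angles_rad[1])
  cy <- cos(angles_rad[2]); sy <- sin(angles_rad[2])
  cz <- cos(angles_rad[3]); sz <- sin(angles_rad[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  r <- rz %*% ry %*% rx
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4] <- translation_mm + center - r %*% center
  affine_transform(m, source_space, target_space)
}

# world coordinates of every voxel center of an image grid (n x 3, mm)
grid_world_coords <- function(img) {
  d <- dim(img$data)
  idx <- cbind(
    rep.int(0:(d[1] - 1), d[2] * d[3]),
    rep.int(rep(0:(d[2] - 1), each = d[1]), d[3]),
    rep(0:(d[3] - 1), each = d[1] * d[2]))
  sweep(idx %*% t(img$affine[1:3, 1:3]), 2, img$affine[1:3, 4], "+")
}

# sample img at continuous 0-based voxel coordinates (n x 3)
sample_at_voxels <- function(img, vxyz, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(img$data)
  out <- numeric(nrow(vxyz))
  if (interp == "nearest") {
    ir <- round(vxyz)
    ok <- ir[, 1] >= 0 & ir[, 1] <= d[1] - 1 &
          ir[, 2] >= 0 & ir[, 2] <= d[2] - 1 &
          ir[, 3] >= 0 & ir[, 3] <= d[3] - 1
    lin <- ir[ok, 1] + d[1] * (ir[ok, 2] + d[2] * ir[ok, 3]) + 1
    out[ok] <- img$data[lin]
  } else {
    f <- floor(vxyz)
    w <- vxyz - f
    ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 2 &
          f[, 2] >= 0 & f[, 2] <= d[2] - 2 &
          f[, 3] >= 0 & f[, 3] <= d[3] - 2
    # allow exact upper boundary
    at_edge <- function(ax) f[, ax] == d[ax] - 1 & w[, ax] == 0
    e1 <- at_edge(1); e2 <- at_edge(2); e3 <- at_edge(3)
    f[e1, 1] <- d[1] - 2; w[e1, 1] <- 1
    f[e2, 2] <- d[2] - 2; w[e2, 2] <- 1
    f[e3, 3] <- d[3] - 2; w[e3, 3] <- 1
    ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 2 &
          f[, 2] >= 0 & f[, 2] <= d[2] - 2 &
          f[, 3] >= 0 & f[, 3] <= d[3] - 2
    fi <- f[ok, , drop = FALSE]; wi <- w[ok, , drop = FALSE]
    base <- fi[, 1] + d[1] * (fi[, 2] + d[2] * fi[, 3]) + 1
    acc <- numeric(sum(ok))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) wi[, 1] else 1 - wi[, 1]) *
            (if (dy) wi[, 2] else 1 - wi[, 2]) *
            (if (dz) wi[, 3] else 1 - wi[, 3])
      acc <- acc + wt * img$data[base + dx + d[1] * (dy + d[2] * dz)]
    }
    out[ok] <- acc
  }
  out
}

#' Resample an image through an affine transform onto a target grid
#'
#' The transform maps source-space world coordinates to target-space world
#' coordinates; the output lives on the target's grid and affine.
#' Out-of-field voxels are set to 0. Nearest-neighbour interpolation
#' preserves the input's value set (use it for labels and masks); linear is
#' for quantitative maps.
#'
#' @param image source `volume_image`.
#' @param transform `affine_transform` from `image`'s space to the target
#'   space; use [identity_transform()] when grids share a world frame.
#' @param target `volume_image` defining the output grid.
#' @param interp "linear" or "nearest".
#' @return `volume_image` on the target grid.
#' @export
resample <- function(image, transform, target,
                     interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  # target voxel -> target world -> source world -> source voxel
  wt <- grid_world_coords(target)
  inv <- solve(transform$matrix)
  ws <- sweep(wt %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
  ainv <- solve(image$affine)
  vs <- sweep(ws %*% t(ainv[1:3, 1:3]), 2, ainv[1:3, 4], "+")
  vals <- sample_at_voxels(image, vs, interp)
  volume_image(array(vals, dim(target$data)), target$voxel_mm, target$affine,
               target$space)
}

#' Apply a transform to a binary mask (nearest-neighbour)
#'
#' Reuses an already-estimated transform (e.g. FLAIR to T1) on a lesion
#' mask without re-estimation; output is guaranteed binary.
#'
#' @param mask binary `volume_image` (values in \{0, 1\}).
#' @param transform `affine_transform`.
#' @param target `volume_image` grid definition.
#' @return binary `volume_image`.
#' @export
apply_to_mask <- function(mask, transform, target) {
  vals <- unique(as.vector(mask$data))
  if (!all(vals %in% c(0, 1)))
    stop("mask must be binary (values in {0,1})", call. = FALSE)
  out <- resample(mask, transform, target, interp = "nearest")
  out$data <- (out$data != 0) + 0
  out
}

# joint-histogram normalized mutual information; higher is better
nmi_metric <- function(a, b, bins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 16) return(-Inf)
  cut1 <- pmin(pmax(findInterval(a, seq(min(a), max(a),
                                        length.out = bins + 1),
                                 all.inside = TRUE), 1L), bins)
  cut2 <- pmin(pmax(findInterval(b, seq(min(b), max(b),
                                        length.out = bins + 1),
                                 all.inside = TRUE), 1L), bins)
  joint <- tabulate(cut1 + bins * (cut2 - 1L), bins * bins) / length(a)
  px <- rowSums(matrix(joint, bins)); py <- colSums(matrix(joint, bins))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (h(px) + h(py)) / h(joint)
}

registration_metric <- function(moving, fixed, params, center, bins = 32L) {
  tf <- rigid_transform(params[1:3], params[4:6], center,
                        moving$space, fixed$space)
  res <- resample(moving, tf, fixed, "linear")
  nmi_metric(as.vector(res$data), as.vector(fixed$data), bins)
}

#' Estimate a rigid transform between two volumes
#'
#' Built-in 6-degree-of-freedom (rotation + translation) registration that
#' maximizes a normalized mutual information metric over a joint intensity
#' histogram. The search is multi-stage: an integer-voxel translation scan
#' followed by Nelder-Mead refinement of all six parameters. Deterministic
#' given inputs and options. Intensity-based backends used in clinical
#' pipelines (SPM, FSL FLIRT) are interchangeable with this estimator at the
#' interface level: any function returning an `affine_transform` can stand
#' in.
#'
#' @param moving `volume_image` to be mapped into the fixed space.
#' @param fixed reference `volume_image`.
#' @param opts list: `bins` histogram bins (default 32), `search_vox`
#'   integer translation search radius in voxels (default 4),
#'   `search_deg` coarse rotation scan points in degrees (default
#'   `c(-6, -3, 0, 3, 6)`), `maxit` Nelder-Mead iteration cap (default
#'   400), `smooth` logical: pre-smooth both images with a 3x3x3 mean
#'   filter (default TRUE).
#' @return `affine_transform` mapping moving-space world coordinates to
#'   fixed-space world coordinates.
#' @export
estimate_rigid <- function(moving, fixed, opts = list()) {
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0)
    stop("degenerate (constant) image: registration metric undefined",
         call. = FALSE)
  bins <- opts$bins %||% 32L
  search_vox <- opts$search_vox %||% 4L
  search_deg <- opts$search_deg %||% c(-6, -3, 0, 3, 6)
  maxit <- opts$maxit %||% 400L
  do_smooth <- opts$smooth %||% TRUE
  d <- dim(fixed$data)
  center <- as.numeric(fixed$affine %*% c((d - 1) / 2, 1))[1:3]

  # smoothing both images symmetrizes interpolation blur so that the
  # metric peaks at true alignment rather than at zero resampling
  if (do_smooth) {
    moving$data <- box_smooth3(moving$data)
    fixed$data <- box_smooth3(fixed$data)
  }

  # stage 1a: integer-voxel translation scan at half resolution
  mov_lo <- downsample2(moving)
  fix_lo <- downsample2(fixed)
  steps <- -search_vox:search_vox
  best <- c(0, 0, 0); best_val <- -Inf
  for (tz in steps) for (ty in steps) for (tx in steps) {
    tr <- c(tx, ty, tz) * moving$voxel_mm
    val <- registration_metric(mov_lo, fix_lo, c(0, 0, 0, tr), center, bins)
    if (val > best_val) { best_val <- val; best <- tr }
  }
  # stage 1b: coarse rotation scan around the best translation, at full
  # resolution (fine rotational structure does not survive decimation)
  angs <- search_deg * pi / 180
  best_ang <- c(0, 0, 0); best_val <- -Inf
  for (az in angs) for (ay in angs) for (ax in angs) {
    val <- registration_metric(moving, fixed, c(ax, ay, az, best),
                               center, bins)
    if (val > best_val) { best_val <- val; best_ang <- c(ax, ay, az) }
  }

  # stage 2: full-resolution pattern search over all 6 parameters with
  # shrinking steps (robust on the piecewise-flat histogram metric, and
  # deterministic)
  p <- c(best_ang, best)
  p_val <- registration_metric(moving, fixed, p, center, bins)
  ang_steps <- c(2, 1, 0.5, 0.25, 0.1, 0.05) * pi / 180
  mm_steps <- c(2, 1, 0.5, 0.25, 0.1, 0.05) * min(moving$voxel_mm)
  n_eval <- 0L
  for (lev in seq_along(ang_steps)) {
    step6 <- c(rep(ang_steps[lev], 3), rep(mm_steps[lev], 3))
    repeat {
      improved <- FALSE
      for (i in 1:6) for (sgn in c(1, -1)) {
        cand <- p
        cand[i] <- cand[i] + sgn * step6[i]
        val <- registration_metric(moving, fixed, cand, center, bins)
        n_eval <- n_eval + 1L
        if (val > p_val) { p <- cand; p_val <- val; improved <- TRUE }
      }
      if (!improved || n_eval > maxit * 3) break
    }
    if (n_eval > maxit * 3) break
  }
  rigid_transform(p[1:3], p[4:6], center, moving$space, fixed$space)
}

# 3x3x3 mean filter with edge replication
box_smooth3 <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sx <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    sy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    sz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- out + a[sx, sy, sz]
  }
  out / 27
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# decimate by 2 along each axis (keeps world positions of kept voxels)
downsample2 <- function(img) {
  d <- dim(img$data)
  ix <- seq(1, d[1], by = 2); iy <- seq(1, d[2], by = 2)
  iz <- seq(1, d[3], by = 2)
  aff <- img$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * 2
  volume_image(img$data[ix, iy, iz, drop = FALSE], img$voxel_mm * 2, aff,
               img$space)
}

#' Write / read an affine transform as plain text + JSON sidecar
#'
#' The matrix is stored row-major in a 4-line whitespace-separated text
#' file; source and target space labels go to `<path>.json`.
#'
#' @param tf `affine_transform`.
#' @param path text file path.
#' @return `path` (write) or the `affine_transform` (read).
#' @export
write_transform <- function(tf, path) {
  utils::write.table(tf$matrix, path, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(source_space = tf$source_space,
                            target_space = tf$target_space),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"))
  affine_transform(m, side$source_space, side$target_space)
}
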
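region_stats_columns <- c(
  "patient_id", "region", "map", "n_voxels", "volume_mm3",
  "normalized_volume", "mean", "sd", "median", "iqr_low", "iqr_high",
  "min", "max")

#' Quantitative statistics of a map over a masked region
#'
#' Masks a quantitative map (or no map, for pure volumetry) with a binary
#' region mask and reports voxel count, volume, normalized volume and
#' intensity statistics (mean, SD, median, IQR, range). Voxels flagged
#' invalid upstream (clamped ADC, zero-flow perfusion) are excluded from
#' the intensity statistics but still counted in the region volume. An
#' empty region yields n_voxels 0 with missing (NA) statistics, never
#' zeros.
#'
#' @param map `volume_image` to summarize, or `NULL` for volumetry-only
#'   rows (map name "none").
#' @param mask binary `volume_image` on the same grid.
#' @param patient_id,region,map_name identifiers for the output row.
#' @param vscale volumetric scaling factor for [normalized_volume()].
#' @param valid_mask optional logical array marking voxels whose map value
#'   is usable; defaults to the map's own `valid_mask` attribute, else all.
#' @return one-row data.frame with the standard report schema.
#' @export
region_stats <- function(map, mask, patient_id = "phantom",
                         region = "region", map_name = "none", vscale = 1,
                         valid_mask = NULL) {
  if (!all(mask$data %in% c(0, 1)))
    stop("mask must be binary", call. = FALSE)
  if (!is.null(map)) {
    stop_if_grid_mismatch(map, mask, "map and mask")
    if (is.null(valid_mask))
      valid_mask <- attr(map, "valid_mask") %||% array(TRUE, dim(map$data))
  }
  inmask <- mask$data != 0
  n <- sum(inmask)
  vol <- n * voxel_volume_mm3(mask)
  row <- data.frame(patient_id = patient_id, region = region, map = map_name,
                    n_voxels = n, volume_mm3 = vol,
                    normalized_volume = normalized_volume(vol, vscale),
                    mean = NA_real_, sd = NA_real_, median = NA_real_,
                    iqr_low = NA_real_, iqr_high = NA_real_,
                    min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(map) && n > 0) {
    v <- map$data[inmask & valid_mask]
    if (length(v) > 0) {
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
      row$mean <- mean(v)
      row$sd <- if (length(v) > 1) stats::sd(v) else NA_real_
      row$median <- stats::median(v)
      row$iqr_low <- q[1]; row$iqr_high <- q[2]
      row$min <- min(v); row$max <- max(v)
    }
  }
  row[, region_stats_columns]
}

#' Write / read the region-statistics CSV
#'
#' Stable column order, header row, missing values as empty fields;
#' re-reading reproduces the table.
#'
#' @param rows data.frame of [region_stats()] rows.
#' @param path CSV path.
#' @return `path` invisibly (write) or the data.frame (read).
#' @export
write_region_csv <- function(rows, path) {
  if (nrow(rows) > 0 && !identical(names(rows), region_stats_columns))
    stop("rows do not follow the report schema", call. = FALSE)
  if (nrow(rows) == 0)
    rows <- stats::setNames(
      data.frame(matrix(ncol = length(region_stats_columns), nrow = 0)),
      region_stats_columns)
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_region_csv
#' @export
read_region_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       region = "character",
                                       map = "character"))
  df[df == ""] <- NA
  df
}

#' Create an empty provenance log
#'
#' Append-only record of every pipeline step: parameters, content hashes
#' of inputs and outputs, software version and timestamps. Serialized as
#' JSON-lines so each step is one self-contained record.
#'
#' @return a `provenance_log` object.
#' @export
provenance_log <- function() {
  structure(list(steps = list(),
                 version = as.character(utils::packageVersion("dppmri"))),
            class = "provenance_log")
}

file_hash <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(list())
  h <- tools::md5sum(paths)
  stats::setNames(as.list(unname(h)), basename(paths))
}

#' Append one step record to a provenance log
#'
#' Records are immutable once appended: re-appending a record under an
#' existing step name with different content is rejected; rerunning a step
#' must instead write its outputs under a new versioned directory (see
#' [versioned_dir()]).
#'
#' @param log a [provenance_log()].
#' @param step step name (unique per run).
#' @param params named list of parameters used.
#' @param inputs,outputs character vectors of file paths; content hashes
#'   (md5) are captured at call time.
#' @param tool_output captured console/tool output (character).
#' @param start,end POSIXct timestamps (defaults: now).
#' @return the grown `provenance_log`.
#' @export
append_step <- function(log, step, params = list(), inputs = character(),
                        outputs = character(), tool_output = character(),
                        start = Sys.time(), end = Sys.time()) {
  if (step %in% vapply(log$steps, `[[`, character(1), "step"))
    stop(sprintf("step '%s' already recorded; provenance records are immutable",
                 step), call. = FALSE)
  rec <- list(step = step, params = params,
              input_hashes = file_hash(inputs),
              output_hashes = file_hash(outputs),
              software_version = log$version,
              start = format(start, "%Y-%m-%dT%H:%M:%OS3%z"),
              end = format(end, "%Y-%m-%dT%H:%M:%OS3%z"),
              tool_output = tool_output)
  log$steps[[length(log$steps) + 1L]] <- rec
  log
}

#' Verify recorded output hashes against current file content
#' @param log a [provenance_log()].
#' @param dir directory holding the output files.
#' @return data.frame of mismatches (zero rows when everything verifies).
#' @export
verify_provenance <- function(log, dir) {
  bad <- list()
  for (rec in log$steps) {
    for (nm in names(rec$output_hashes)) {
      p <- file.path(dir, nm)
      cur <- if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
      if (!identical(cur, rec$output_hashes[[nm]]))
        bad[[length(bad) + 1L]] <- data.frame(
          step = rec$step, file = nm,
          recorded = rec$output_hashes[[nm]],
          current = cur, stringsAsFactors = FALSE)
    }
  }
  if (length(bad) == 0)
    data.frame(step = character(), file = character(),
               recorded = character(), current = character())
  else do.call(rbind, bad)
}

#' Write a provenance log as JSON-lines
#' @param log a [provenance_log()].
#' @param path output path (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(log, path) {
  lines <- vapply(log$steps, function(rec)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Next free versioned output directory for a step
#'
#' Rerunning a step never overwrites prior outputs: each run gets
#' `<root>/<step>_v<k>` with the smallest unused k.
#'
#' @param root run output root.
#' @param step step name.
#' @return created directory path.
#' @export
versioned_dir <- function(root, step) {
  k <- 1L
  repeat {
    p <- file.path(root, sprintf("%s_v%d", step, k))
    if (!dir.exists(p)) { dir.create(p, recursive = TRUE); return(p) }
    k <- k + 1L
  }
}

#' Snapshot-copy files before a step modifies them
#'
#' Copy-before-modify contract: inputs of a step are copied into a
#' snapshot directory before the step runs, so every intermediate state
#' can be reconstructed.
#'
#' @param files character vector of existing files.
#' @param snapshot_dir destination directory (created).
#' @return invisible character vector of snapshot paths.
#' @export
snapshot_inputs <- function(files, snapshot_dir) {
  dir.create(snapshot_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(snapshot_dir, basename(files))
  ok <- file.copy(files, dest, overwrite = FALSE)
  if (!all(ok)) stop("snapshot copy failed", call. = FALSE)
  invisible(dest)
}
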
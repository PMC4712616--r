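#' De-identification tag policy
#'
#' Controls which DICOM header tags the anonymizer blanks, replaces with a
#' fixed value, re-hashes (UIDs), or preserves. The default profile is
#' conservative: names, IDs, dates, institution and physician tags are
#' blanked, and study/series/SOP instance UIDs are re-hashed
#' deterministically under a per-run salt so that file relationships
#' survive while original identifiers do not.
#'
#' @param remove_tags tag names to blank (zero-length value).
#' @param replace_map named list/vector: tag name to fixed replacement.
#' @param rehash_uids UID tag names re-hashed under `salt`.
#' @param preserve_tags tags exempt from removal (must not intersect
#'   `remove_tags`).
#' @param salt character salt for deterministic UID re-hashing.
#' @return a `tag_policy` object.
#' @export
tag_policy <- function(remove_tags = c("PatientName", "PatientBirthDate",
                                       "PatientSex", "PatientAge",
                                       "PatientWeight", "InstitutionName",
                                       "InstitutionAddress",
                                       "ReferringPhysicianName",
                                       "PerformingPhysicianName",
                                       "OperatorsName", "StationName",
                                       "DeviceSerialNumber", "StudyDate",
                                       "SeriesDate", "AcquisitionDate",
                                       "AccessionNumber", "StudyID"),
                       replace_map = list(),
                       rehash_uids = c("StudyInstanceUID",
                                       "SeriesInstanceUID",
                                       "SOPInstanceUID",
                                       "MediaStorageSOPInstanceUID"),
                       preserve_tags = character(),
                       salt = "dppmri") {
  if (length(intersect(remove_tags, preserve_tags)))
    stop("remove_tags and preserve_tags must be disjoint", call. = FALSE)
  structure(list(remove_tags = setdiff(remove_tags, names(replace_map)),
                 replace_map = as.list(replace_map),
                 rehash_uids = rehash_uids,
                 preserve_tags = preserve_tags, salt = salt),
            class = "tag_policy")
}

md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(x, tf, eos = NULL)
  unname(tools::md5sum(tf))
}

# deterministic pseudonymous UID under root 2.25 with a fixed 24-digit
# body; that signature marks already-rehashed UIDs, making re-anonymization
# a no-op (idempotence)
rehash_uid <- function(uid, salt) {
  if (grepl("^2\\.25\\.[0-9]{24}$", uid)) return(uid)
  h <- md5_string(paste0(salt, "|", uid))
  digits <- vapply(strsplit(substr(h, 1, 24), "")[[1]],
                   function(ch) strtoi(ch, 16L) %% 10L, integer(1))
  paste0("2.25.", paste(digits, collapse = ""))
}

#' Anonymize a directory of DICOM files
#'
#' Copy-before-modify: reads every DICOM file in `in_dir`, applies the
#' [tag_policy()] to the header (blank removed tags, apply replacements,
#' re-hash UIDs) and writes the result to `out_dir`; pixel data is passed
#' through byte-identical and the input directory is never touched.
#' The original-to-pseudonym identity mapping is written only to a
#' separate protected file (`identity_map.json`, mode 0600) in
#' `map_dir` — never into image headers. Unreadable files are logged,
#' skipped and counted.
#'
#' @param in_dir input directory of DICOM files.
#' @param out_dir output directory; must differ from `in_dir`.
#' @param policy a [tag_policy()].
#' @param map_dir directory for the identity mapping file (default
#'   `out_dir`'s parent, kept apart from the images).
#' @return an anonymization report: list with `n_processed`, `n_skipped`,
#'   `skipped` (file names), `tags_altered` (per-file list),
#'   `identity_map_path`.
#' @export
anonymize_dicom_dir <- function(in_dir, out_dir, policy = tag_policy(),
                                map_dir = dirname(out_dir)) {
  if (normalizePath(in_dir, mustWork = TRUE) ==
      suppressWarnings(normalizePath(out_dir, mustWork = FALSE)))
    stop("out_dir must differ from in_dir (copy-before-modify contract)",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(in_dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  skipped <- character()
  altered <- list()
  id_map <- list()
  n_done <- 0L
  for (f in files) {
    dcm <- tryCatch(read_dicom(f), error = function(e) NULL)
    if (is.null(dcm)) { skipped <- c(skipped, basename(f)); next }
    changed <- character()
    for (nm in setdiff(policy$remove_tags, policy$preserve_tags)) {
      row <- dicom_lookup(nm)
      i <- dicom_find(dcm, row$group, row$element)
      if (!is.na(i) && length(dcm[[i]]$bytes) > 0) {
        old <- dcm[[i]]$value
        dcm[[i]]$bytes <- raw(); dcm[[i]]$value <- ""
        changed <- c(changed, nm)
        if (nm %in% c("PatientName", "PatientID"))
          id_map[[nm]] <- unique(c(id_map[[nm]], old))
      }
    }
    for (nm in names(policy$replace_map)) {
      old <- dicom_value(dcm, nm)
      new <- policy$replace_map[[nm]]
      if (!identical(old, new)) {
        if (!is.null(old) && nm %in% c("PatientName", "PatientID"))
          id_map[[paste0(nm, ":", old)]] <- new
        dcm <- dicom_set(dcm, nm, new)
        changed <- c(changed, nm)
      }
    }
    for (nm in policy$rehash_uids) {
      old <- dicom_value(dcm, nm)
      if (!is.null(old) && nzchar(old)) {
        new <- rehash_uid(old, policy$salt)
        if (!identical(old, new)) {
          id_map[[paste0(nm, ":", old)]] <- new
          dcm <- dicom_set(dcm, nm, new)
          changed <- c(changed, nm)
        }
      }
    }
    write_dicom_elements(file.path(out_dir, basename(f)), dcm)
    altered[[basename(f)]] <- changed
    n_done <- n_done + 1L
  }
  map_path <- file.path(map_dir, "identity_map.json")
  jsonlite::write_json(id_map, map_path, auto_unbox = TRUE)
  Sys.chmod(map_path, "0600")
  list(n_processed = n_done, n_skipped = length(skipped), skipped = skipped,
       tags_altered = altered, identity_map_path = map_path)
}

#' Canonical sequence names expected per patient
#' @return character vector of canonical names.
#' @export
canonical_sequences <- function() {
  c("flair", "t1", "gd_t1", "dwi_b0", "dwi_x", "dwi_y", "dwi_z", "dsc")
}

strip_image_ext <- function(x) sub("\\.nii(\\.gz)?$|\\.dcm$", "", x)

#' Check patient directories for required sequences
#'
#' One checklist entry per patient: which required sequences are present
#' (matched on canonical file stems), whether the patient conforms, and —
#' for each non-conforming patient — a per-patient JSON report file listing
#' the missing sequences. Non-conforming patients are excluded from the
#' returned run list.
#'
#' @param patient_dirs character vector of per-patient directories.
#' @param required non-empty character vector of required sequence names.
#' @param report_dir where per-patient non-conformance reports are written
#'   (`NULL` disables report files).
#' @return an `inventory_report`: list with `patients` (per patient: named
#'   logical presence vector and `conforming` flag), `run_list` (conforming
#'   patient dirs), `report_files`.
#' @export
inventory_check <- function(patient_dirs, required = canonical_sequences(),
                            report_dir = NULL) {
  if (length(required) == 0) stop("`required` must be non-empty",
                                  call. = FALSE)
  patients <- list()
  run_list <- character()
  report_files <- character()
  for (p in patient_dirs) {
    stems <- strip_image_ext(list.files(p))
    present <- stats::setNames(required %in% stems, required)
    conforming <- all(present)
    patients[[basename(p)]] <- list(present = present,
                                    conforming = conforming)
    if (conforming) {
      run_list <- c(run_list, p)
    } else if (!is.null(report_dir)) {
      dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
      rf <- file.path(report_dir,
                      paste0(basename(p), "_missing_sequences.json"))
      jsonlite::write_json(list(patient = basename(p),
                                missing = names(present)[!present]),
                           rf, auto_unbox = TRUE)
      report_files <- c(report_files, rf)
    }
  }
  structure(list(patients = patients, run_list = run_list,
                 report_files = report_files, required = required),
            class = "inventory_report")
}

#' Normalize a patient's raw files into the canonical layout
#'
#' Copies (never moves) raw files into `out_dir` under scanner-independent
#' canonical names; information content is byte-identical. Files whose
#' stems are not in the naming map are copied untouched under `extra/`.
#' Re-running on the same input is idempotent. Two raw files mapping to
#' the same canonical name is an error naming both sources.
#'
#' @param raw_dir patient source directory.
#' @param out_dir destination (created).
#' @param naming named character vector: raw file stem to canonical
#'   sequence name.
#' @return `out_dir`, invisibly.
#' @export
normalize_layout <- function(raw_dir, out_dir, naming) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(raw_dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  targets <- character()
  for (f in files) {
    stem <- strip_image_ext(basename(f))
    ext <- sub(stem, "", basename(f), fixed = TRUE)
    if (stem %in% names(naming)) {
      dest <- file.path(out_dir, paste0(naming[[stem]], ext))
    } else {
      dir.create(file.path(out_dir, "extra"), showWarnings = FALSE)
      dest <- file.path(out_dir, "extra", basename(f))
    }
    if (dest %in% names(targets))
      stop(sprintf("name collision: '%s' and '%s' both map to '%s'",
                   targets[[dest]], basename(f), basename(dest)),
           call. = FALSE)
    targets[dest] <- basename(f)
    file.copy(f, dest, overwrite = TRUE, copy.date = TRUE)
  }
  invisible(out_dir)
}
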
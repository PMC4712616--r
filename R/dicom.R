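# Minimal DICOM Part-10 codec: explicit VR little endian, defined element
# lengths. Covers tag-level header editing with pixel data passed through
# byte-identical; not a general-purpose DICOM implementation (undefined
# lengths / encapsulated transfer syntaxes are rejected).

dicom_vr_long <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
dicom_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                      "PN", "SH", "ST", "TM", "UC", "UI", "UR", "UT")

#' Dictionary of DICOM tags known to the anonymizer
#'
#' Maps symbolic names to group/element/VR for the tags handled by the
#' de-identification policy and the fixture writer.
#'
#' @return data.frame with columns name, group, element, vr.
#' @export
dicom_dictionary <- function() {
  d <- rbind(
    c("FileMetaInformationGroupLength", 0x0002, 0x0000, "UL"),
    c("MediaStorageSOPClassUID",  0x0002, 0x0002, "UI"),
    c("MediaStorageSOPInstanceUID", 0x0002, 0x0003, "UI"),
    c("TransferSyntaxUID",        0x0002, 0x0010, "UI"),
    c("ImplementationClassUID",   0x0002, 0x0012, "UI"),
    c("SOPClassUID",       0x0008, 0x0016, "UI"),
    c("SOPInstanceUID",    0x0008, 0x0018, "UI"),
    c("StudyDate",         0x0008, 0x0020, "DA"),
    c("SeriesDate",        0x0008, 0x0021, "DA"),
    c("AcquisitionDate",   0x0008, 0x0022, "DA"),
    c("StudyTime",         0x0008, 0x0030, "TM"),
    c("AccessionNumber",   0x0008, 0x0050, "SH"),
    c("Modality",          0x0008, 0x0060, "CS"),
    c("InstitutionName",   0x0008, 0x0080, "LO"),
    c("InstitutionAddress", 0x0008, 0x0081, "ST"),
    c("ReferringPhysicianName", 0x0008, 0x0090, "PN"),
    c("StationName",       0x0008, 0x1010, "SH"),
    c("SeriesDescription", 0x0008, 0x103E, "LO"),
    c("PerformingPhysicianName", 0x0008, 0x1050, "PN"),
    c("OperatorsName",     0x0008, 0x1070, "PN"),
    c("PatientName",       0x0010, 0x0010, "PN"),
    c("PatientID",         0x0010, 0x0020, "LO"),
    c("PatientBirthDate",  0x0010, 0x0030, "DA"),
    c("PatientSex",        0x0010, 0x0040, "CS"),
    c("PatientAge",        0x0010, 0x1010, "AS"),
    c("PatientWeight",     0x0010, 0x1030, "DS"),
    c("DeviceSerialNumber", 0x0018, 0x1000, "LO"),
    c("StudyInstanceUID",  0x0020, 0x000D, "UI"),
    c("SeriesInstanceUID", 0x0020, 0x000E, "UI"),
    c("StudyID",           0x0020, 0x0010, "SH"),
    c("Rows",              0x0028, 0x0010, "US"),
    c("Columns",           0x0028, 0x0011, "US"),
    c("BitsAllocated",     0x0028, 0x0100, "US"),
    c("PixelData",         0x7FE0, 0x0010, "OW"))
  data.frame(name = d[, 1], group = strtoi(d[, 2]),
             element = strtoi(d[, 3]), vr = d[, 4],
             stringsAsFactors = FALSE)
}

dicom_lookup <- function(name) {
  dict <- dicom_dictionary()
  row <- dict[dict$name == name, ]
  if (nrow(row) != 1)
    stop("unknown DICOM tag name '", name, "'", call. = FALSE)
  row
}

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
u32le <- function(x) {
  # avoid 32-bit integer overflow for lengths >= 2^31
  lo <- x %% 65536; hi <- x %/% 65536
  c(u16le(lo), u16le(hi))
}
read_u16 <- function(r, at) sum(as.integer(r[at:(at + 1)]) * c(1, 256))
read_u32 <- function(r, at) sum(as.integer(r[at:(at + 3)]) * c(1, 256, 65536, 16777216))

encode_value <- function(vr, value) {
  if (is.raw(value)) {
    v <- value
  } else if (vr %in% dicom_string_vrs) {
    v <- charToRaw(as.character(value))
  } else if (vr %in% c("US")) {
    v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr %in% c("UL")) {
    v <- u32le(as.numeric(value))
  } else {
    stop("cannot encode VR ", vr, call. = FALSE)
  }
  if (length(v) %% 2 == 1)
    v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  v
}

decode_value <- function(vr, bytes) {
  if (vr %in% dicom_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    sub("\\s+$", "", s)
  } else if (vr == "US") {
    readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
            endian = "little", signed = FALSE)
  } else if (vr == "UL") {
    readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
            endian = "little")
  } else bytes
}

encode_element <- function(group, element, vr, bytes) {
  head <- c(u16le(group), u16le(element), charToRaw(vr))
  if (vr %in% dicom_vr_long) {
    c(head, as.raw(c(0, 0)), u32le(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534) stop("value too long for short VR",
                                    call. = FALSE)
    c(head, u16le(length(bytes)), bytes)
  }
}

#' Write a minimal DICOM file
#'
#' Explicit VR little endian Part-10 file with a standard file meta group.
#' Intended for constructing small synthetic fixtures and for re-emitting
#' anonymized datasets.
#'
#' @param path output path.
#' @param elements named list: tag name (see [dicom_dictionary()]) to
#'   value. `PixelData` takes a raw vector or an integer matrix (16-bit).
#' @return `path`, invisibly.
#' @export
write_dicom <- function(path, elements) {
  dict <- dicom_dictionary()
  if (!is.null(elements$PixelData) && is.matrix(elements$PixelData)) {
    px <- elements$PixelData
    elements$Rows <- elements$Rows %||% nrow(px)
    elements$Columns <- elements$Columns %||% ncol(px)
    elements$BitsAllocated <- elements$BitsAllocated %||% 16L
    elements$PixelData <- writeBin(as.integer(t(px)), raw(), size = 2,
                                   endian = "little")
  }
  meta_defaults <- list(
    MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.4",
    MediaStorageSOPInstanceUID = elements$SOPInstanceUID %||% "1.2.3.4",
    TransferSyntaxUID = "1.2.840.10008.1.2.1",
    ImplementationClassUID = "2.25.424242")
  for (nm in names(meta_defaults))
    if (is.null(elements[[nm]])) elements[[nm]] <- meta_defaults[[nm]]

  rows <- lapply(names(elements), function(nm) {
    row <- dicom_lookup(nm)
    list(group = row$group, element = row$element, vr = row$vr,
         bytes = encode_value(row$vr, elements[[nm]]))
  })
  ord <- order(vapply(rows, function(r) r$group * 2^16 + r$element,
                      numeric(1)))
  rows <- rows[ord]
  meta <- rows[vapply(rows, function(r) r$group == 2L, logical(1))]
  body <- rows[vapply(rows, function(r) r$group != 2L, logical(1))]
  meta_bytes <- do.call(c, lapply(meta, function(r)
    encode_element(r$group, r$element, r$vr, r$bytes)))
  group_len <- encode_element(0x0002, 0x0000, "UL",
                              encode_value("UL", length(meta_bytes)))
  body_bytes <- if (length(body))
    do.call(c, lapply(body, function(r)
      encode_element(r$group, r$element, r$vr, r$bytes))) else raw()
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), group_len, meta_bytes, body_bytes),
           con)
  invisible(path)
}

#' Read a minimal DICOM file
#'
#' Parses an explicit VR little endian Part-10 file into a flat element
#' list. Undefined-length elements are rejected.
#'
#' @param path DICOM file path.
#' @return list of elements, each `list(group, element, vr, bytes, value)`,
#'   in file order; class `dicom_data`.
#' @export
read_dicom <- function(path) {
  r <- readBin(path, raw(), file.size(path))
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path, call. = FALSE)
  at <- 133
  out <- list()
  while (at + 7 <= length(r) + 1 && at <= length(r)) {
    group <- read_u16(r, at); element <- read_u16(r, at + 2)
    vr <- rawToChar(r[(at + 4):(at + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or corrupt element at byte ", at, call. = FALSE)
    if (vr %in% dicom_vr_long) {
      len <- read_u32(r, at + 8)
      if (len == 4294967295)
        stop("undefined-length element (", vr, ") not supported",
             call. = FALSE)
      val_at <- at + 12
    } else {
      len <- read_u16(r, at + 6)
      val_at <- at + 8
    }
    bytes <- if (len > 0) r[val_at:(val_at + len - 1)] else raw()
    out[[length(out) + 1L]] <- list(group = group, element = element,
                                    vr = vr, bytes = bytes,
                                    value = decode_value(vr, bytes))
    at <- val_at + len
  }
  structure(out, class = "dicom_data")
}

dicom_find <- function(dcm, group, element) {
  for (i in seq_along(dcm))
    if (dcm[[i]]$group == group && dcm[[i]]$element == element) return(i)
  NA_integer_
}

#' Get a DICOM element value by tag name
#' @param dcm `dicom_data` from [read_dicom()].
#' @param name tag name in [dicom_dictionary()].
#' @return decoded value, or `NULL` if absent.
#' @export
dicom_value <- function(dcm, name) {
  row <- dicom_lookup(name)
  i <- dicom_find(dcm, row$group, row$element)
  if (is.na(i)) NULL else dcm[[i]]$value
}

dicom_set <- function(dcm, name, value) {
  row <- dicom_lookup(name)
  i <- dicom_find(dcm, row$group, row$element)
  bytes <- encode_value(row$vr, value)
  el <- list(group = row$group, element = row$element, vr = row$vr,
             bytes = bytes, value = decode_value(row$vr, bytes))
  if (is.na(i)) dcm[[length(dcm) + 1L]] <- el else dcm[[i]] <- el
  dcm
}

write_dicom_elements <- function(path, dcm) {
  ord <- order(vapply(dcm, function(e) e$group * 2^16 + e$element,
                      numeric(1)))
  dcm <- dcm[ord]
  # recompute the file meta group length
  meta <- Filter(function(e) e$group == 2L && e$element != 0L, dcm)
  body <- Filter(function(e) e$group != 2L, dcm)
  meta_bytes <- if (length(meta))
    do.call(c, lapply(meta, function(e)
      encode_element(e$group, e$element, e$vr, e$bytes))) else raw()
  group_len <- encode_element(0x0002, 0x0000, "UL",
                              encode_value("UL", length(meta_bytes)))
  body_bytes <- if (length(body))
    do.call(c, lapply(body, function(e)
      encode_element(e$group, e$element, e$vr, e$bytes))) else raw()
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), group_len, meta_bytes, body_bytes),
           con)
  invisible(path)
}

#' Checksum of the pixel data payload of a DICOM file
#' @param path DICOM file path.
#' @return md5 hex string of the PixelData bytes ("" if absent).
#' @export
dicom_pixel_checksum <- function(path) {
  dcm <- read_dicom(path)
  i <- dicom_find(dcm, 0x7FE0, 0x0010)
  if (is.na(i)) return("")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(dcm[[i]]$bytes, tf)
  unname(tools::md5sum(tf))
}
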
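# synthetic DICOM fixtures, written by the package's own codec

write_fixture_dicoms <- function(dir, n = 3, patient = "DOE^JANE",
                                 pid = "PAT001") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(7)
  for (i in seq_len(n)) {
    px <- matrix(sample.int(4096, 64, replace = TRUE), 8, 8)
    write_dicom(file.path(dir, sprintf("img%03d.dcm", i)), list(
      SOPInstanceUID = sprintf("1.2.826.0.1.%d", i),
      StudyDate = "20240102", Modality = "MR",
      InstitutionName = "General Hospital",
      ReferringPhysicianName = "SMITH^JOHN",
      PatientName = patient, PatientID = pid,
      PatientBirthDate = "19800101", PatientSex = "F",
      StudyInstanceUID = "1.2.826.0.1.999",
      SeriesInstanceUID = sprintf("1.2.826.0.1.999.%d", i),
      SeriesDescription = "AX FLAIR",
      PixelData = px))
  }
  invisible(dir)
}

make_patient_dir <- function(root, name, sequences) {
  p <- file.path(root, name)
  dir.create(p, recursive = TRUE)
  for (s in sequences) writeLines(s, file.path(p, paste0(s, ".nii.gz")))
  p
}
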
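test_that("region statistics report exact volumetry and intensity summaries", {
  d <- c(8, 8, 8)
  map <- volume_image(array(5, d), c(2, 2, 2), space = "flair")
  mask <- volume_image(array(0, d), c(2, 2, 2), space = "flair")
  mask$data[1:2, 1:2, 1:2] <- 1  # 8 voxels
  row <- region_stats(map, mask, "p1", "NAWM", "adc")
  expect_equal(row$n_voxels, 8)
  expect_equal(row$volume_mm3, 8 * 8)  # 8 voxels x 8 mm^3
  expect_equal(row$mean, 5); expect_equal(row$sd, 0)
  expect_equal(row$median, 5)
  # volume always equals n_voxels times the voxel volume
  expect_equal(row$volume_mm3 / row$n_voxels, prod(mask$voxel_mm))
  # empty region: zero count, missing statistics (never zeros)
  empty <- volume_image(array(0, d), c(2, 2, 2), space = "flair")
  row0 <- region_stats(map, empty, "p1", "lesion_C1", "adc")
  expect_equal(row0$n_voxels, 0)
  expect_true(is.na(row0$mean) && is.na(row0$median) && is.na(row0$sd))
  # mean within [min, max] of masked values
  set.seed(9)
  map$data <- array(stats::rnorm(prod(d), 10, 3), d)
  rowr <- region_stats(map, mask, "p1", "r", "cbf")
  vals <- map$data[mask$data == 1]
  expect_gte(rowr$mean, min(vals)); expect_lte(rowr$mean, max(vals))
  expect_error(region_stats(map, volume_image(array(2, d))), "binary")
})

test_that("upstream-invalid voxels are excluded from statistics but not volume", {
  d <- c(6, 6, 6)
  map <- volume_image(array(1, d), space = "flair")
  valid <- array(TRUE, d); valid[1, 1, 1] <- FALSE
  map$data[1, 1, 1] <- 999
  attr(map, "valid_mask") <- valid
  mask <- volume_image(array(0, d), space = "flair")
  mask$data[1:2, 1, 1] <- 1
  row <- region_stats(map, mask, region = "r", map_name = "adc")
  expect_equal(row$n_voxels, 2)       # volume counts all masked voxels
  expect_equal(row$mean, 1)           # stats skip the invalid one
})

test_that("phantom lesion masks over truth maps recover the planted values", {
  b <- default_bundle()
  c4 <- which(b$truth_classes == "C4")[1]
  mask <- volume_image((b$truth_lesion_labels$data == c4) + 0,
                       b$flair$voxel_mm, b$flair$affine, b$flair$space)
  row <- region_stats(b$truth_maps$adc, mask, region = "lesion_C4",
                      map_name = "adc")
  expect_equal(row$mean, b$spec$adc_truth[["lesion"]], tolerance = 1e-12)
  expect_equal(row$sd, 0)
})

test_that("the region CSV round-trips, including the empty table", {
  b <- default_bundle()
  mask <- volume_image((b$truth_lesion_labels$data > 0) + 0,
                       b$flair$voxel_mm, b$flair$affine, b$flair$space)
  rows <- rbind(
    region_stats(b$truth_maps$adc, mask, "p1", "lesion_total", "adc"),
    region_stats(NULL, mask, "p1", "lesion_total", "none"),
    region_stats(b$truth_maps$cbf, volume_image(array(0, dim(mask$data)),
                                                mask$voxel_mm, mask$affine,
                                                mask$space),
                 "p1", "lesion_C1", "cbf"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_csv(rows, path)
  back <- read_region_csv(path)
  expect_equal(names(back), names(rows))
  expect_equal(back$n_voxels, rows$n_voxels)
  expect_equal(back$mean, rows$mean, tolerance = 1e-12)
  expect_true(is.na(back$mean[2]) && is.na(back$mean[3]))
  # empty table: header-only file that reads back with the schema
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_region_csv(rows[0, ], p0)
  expect_equal(length(readLines(p0)), 1L)
  expect_equal(names(read_region_csv(p0)), names(rows))
})

test_that("a full phantom run emits every expected region/map row", {
  b <- default_bundle()
  res <- run_phantom_pipeline(b)
  df <- res$stats
  lesion_ids <- names(b$truth_classes)
  expected_regions <- c("NAGM", "NAWM", "lesion_total",
                        paste0("lesion_", c("C1", "C2", "C3", "C4")),
                        paste0("lesion_", lesion_ids),
                        paste0("basal_ganglia_",
                               names(phantom_label_codes()[
                                 phantom_label_codes() >= 10])))
  for (rg in expected_regions)
    for (mp in c("none", "adc", "cbf", "cbv", "mtt"))
      expect_true(any(df$region == rg & df$map == mp),
                  label = paste(rg, mp))
  # stats computed where regions are non-empty
  expect_false(any(is.na(df$mean[df$region == "NAWM" & df$map == "adc"])))
})

test_that("same-seed end-to-end phantom runs produce bit-identical CSVs", {
  spec <- phantom_spec(noise_sd = c(flair = 2, t1 = 3, gd_t1 = 3, dwi = 4,
                                    dsc = 1), seed = 77L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_phantom_pipeline(generate_phantom(spec), d1)
  run_phantom_pipeline(generate_phantom(spec), d2)
  expect_identical(
    unname(tools::md5sum(file.path(d1, "region_stats.csv"))),
    unname(tools::md5sum(file.path(d2, "region_stats.csv"))))
})

test_that("provenance log is append-only, ordered, versioned and verifiable", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.txt"); writeLines("input-a", f1)
  log <- provenance_log()
  log <- append_step(log, "lesions", params = list(mf = 2), inputs = f1)
  f2 <- file.path(dir, "out.csv"); writeLines("x,y", f2)
  log <- append_step(log, "analysis", outputs = f2)
  expect_length(log$steps, 2)
  expect_equal(vapply(log$steps, `[[`, character(1), "step"),
               c("lesions", "analysis"))
  expect_false(is.null(log$steps[[1]]$input_hashes[["a.txt"]]))
  # records are immutable: the same step cannot be recorded twice
  expect_error(append_step(log, "analysis"), "immutable")
  # verification detects tampered outputs
  expect_equal(nrow(verify_provenance(log, dir)), 0)
  writeLines("x,y,tampered", f2)
  bad <- verify_provenance(log, dir)
  expect_equal(bad$file, "out.csv")
  # JSON-lines serialization: one record per line
  pl <- file.path(dir, "prov.jsonl")
  write_provenance(log, pl)
  lines <- readLines(pl)
  expect_length(lines, 2)
  expect_equal(jsonlite::fromJSON(lines[1])$step, "lesions")
  # versioned rerun directories never collide
  v1 <- versioned_dir(dir, "maps"); v2 <- versioned_dir(dir, "maps")
  expect_false(v1 == v2)
  expect_true(dir.exists(v1) && dir.exists(v2))
  # snapshot-copy before modification
  snap <- snapshot_inputs(f1, file.path(dir, "snap"))
  writeLines("modified", f1)
  expect_equal(readLines(snap), "input-a")
})
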
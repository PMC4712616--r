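test_that("volume mean series summarizes each DSC volume over the mask", {
  d <- c(6, 6, 6, 10)
  arr <- array(100, d)
  dsc <- time_series_image(arr, tr_s = 1, te_s = 0.05)
  mask <- volume_image(array(1, d[1:3]))
  expect_equal(volume_mean_series(dsc, mask), rep(100, 10))
  # single-voxel mask returns that voxel's series
  arr[2, 3, 4, ] <- seq(10, 100, by = 10)
  dsc2 <- time_series_image(arr, 1, 0.05)
  m1 <- volume_image(array(0, d[1:3])); m1$data[2, 3, 4] <- 1
  expect_equal(volume_mean_series(dsc2, m1), seq(10, 100, by = 10))
  expect_error(volume_mean_series(dsc, volume_image(array(0, d[1:3]))),
               "empty")
})

test_that("arrival detection fires on the first above-threshold deviation", {
  series <- c(rep(100, 10), 60, 55, 70, 90, 100)
  expect_identical(detect_arrival(series, 0.5), 10L)
  expect_error(detect_arrival(rep(5, 20), 0.1), "flat")
  expect_error(detect_arrival(c(1, 2), 0.1), "short")
  expect_error(detect_arrival(series, 0), "fraction")
  # a rise triggers the same as a drop (absolute deviation)
  rise <- c(rep(100, 10), 140, 150, 120, 100, 100)
  expect_identical(detect_arrival(rise, 0.5), 10L)
})

test_that("phantom mean curve yields the true arrival volume", {
  b <- default_bundle()
  series <- volume_mean_series(b$dsc, b$brain_mask)
  expect_identical(detect_arrival(series, 0.1), b$truth_arrival)
})

test_that("signal-to-concentration inverts the T2* signal model", {
  d <- c(4, 4, 4, 12)
  s0 <- 800
  arr <- array(s0, d)
  arr[, , , 7] <- s0 * exp(-1)
  dsc <- time_series_image(arr, tr_s = 1, te_s = 0.05)
  conc <- signal_to_concentration(dsc, arrival_index = 5L)
  expect_equal(conc[2, 2, 2, 7], 1 / 0.05, tolerance = 1e-12)  # C = 20
  expect_equal(conc[2, 2, 2, 3], 0)
  # S identical to baseline everywhere gives zero concentration
  flat <- time_series_image(array(s0, d), 1, 0.05)
  expect_true(all(signal_to_concentration(flat, 5L) == 0))
  expect_error(signal_to_concentration(dsc, 1L), "arrival_index")
  # noiseless phantom: recovered concentration matches the forward model
  b <- default_bundle()
  conc_b <- signal_to_concentration(b$dsc, b$truth_arrival)
  art <- which(b$truth_artery$data != 0)[1]
  idx <- arrayInd(art, dim(b$truth_artery$data))
  got <- conc_b[idx[1], idx[2], idx[3], ]
  expect_equal(got, b$truth_aif, tolerance = 1e-9)
})

test_that("automatic AIF selection finds the arterial region", {
  b <- default_bundle()
  conc <- signal_to_concentration(b$dsc, b$truth_arrival)
  sel <- select_aif(conc, b$brain_mask, b$dsc$tr_s, b$truth_arrival,
                    n_voxels = 10)
  in_artery <- b$truth_artery$data[sel$voxels + 1] != 0
  expect_gte(mean(in_artery), 0.9)
  expect_equal(sel$aif, b$truth_aif, tolerance = 1e-6)
  # N = 1 returns the single best voxel's curve
  sel1 <- select_aif(conc, b$brain_mask, b$dsc$tr_s, b$truth_arrival,
                     n_voxels = 1)
  expect_equal(nrow(sel1$voxels), 1L)
  v <- sel1$voxels[1, ] + 1
  expect_equal(sel1$aif, conc[v[1], v[2], v[3], ], tolerance = 1e-12)
  # manual override: AIF is the mean curve over the supplied ROI
  man <- roi(99L, which(b$truth_artery$data != 0, arr.ind = TRUE) - 1L)
  selm <- select_aif(conc, b$brain_mask, b$dsc$tr_s, b$truth_arrival,
                     roi = man)
  expect_equal(selm$aif, b$truth_aif, tolerance = 1e-9)
})

test_that("SVD deconvolution inverts its own forward convolution", {
  nt <- 40
  times <- 0:(nt - 1)
  aif <- gamma_variate_aif(list(t0 = 5, alpha = 1.5, beta = 1.8,
                                amplitude = 1), times)
  A <- dppmri:::aif_toeplitz(aif, 1)
  # impulse residue
  delta <- c(1, rep(0, nt - 1))
  k <- svd_deconvolve(as.vector(A %*% delta), aif, 1, svd_threshold = 0)
  expect_lt(max(abs(k - delta)), 1e-6)
  expect_identical(which.max(k), 1L)
  # exponential residue at small truncation
  res <- 0.01 * exp(-times / 4)
  k2 <- svd_deconvolve(as.vector(A %*% res), aif, 1, svd_threshold = 0.01)
  expect_lt(abs(max(k2) / max(res) - 1), 0.05)
  # zero tissue curve gives zero residue
  expect_equal(svd_deconvolve(rep(0, nt), aif, 1, 0.1), rep(0, nt))
  expect_error(svd_deconvolve(rep(0, nt), rep(0, nt), 1, 0.1), "all-zero")
  expect_error(svd_deconvolve(rep(0, nt), aif, 1, 1.5), "cutoff")
  expect_error(svd_deconvolve(rep(0, 5), aif[1:5], 1, 0.1), "length")
})

test_that("perfusion maps satisfy the central volume theorem and CBV ratio", {
  b <- default_bundle()
  conc <- signal_to_concentration(b$dsc, b$truth_arrival)
  # plant a shift-free voxel with C = 0.04 * AIF
  idx <- c(3, 3, 3)
  conc[idx[1], idx[2], idx[3], ] <- 0.04 * b$truth_aif
  mask <- b$brain_mask
  mask$data[idx[1], idx[2], idx[3]] <- 1
  perf <- perfusion_maps(conc, b$truth_aif, b$dsc$tr_s, mask,
                         svd_threshold = 0.05,
                         arrival_index = b$truth_arrival)
  expect_equal(perf$cbv$data[idx[1], idx[2], idx[3]], 0.04,
               tolerance = 1e-12)
  # MTT == CBV/CBF wherever CBF > 0, to 1e-6 relative
  flow <- perf$cbf$data > 1e-12
  ratio <- perf$cbv$data[flow] / perf$cbf$data[flow]
  expect_lt(max(abs(perf$mtt$data[flow] / ratio - 1)), 1e-6)
  expect_true(all(perf$cbf$data >= 0) && all(perf$cbv$data >= 0) &&
                all(perf$mtt$data >= 0))
  expect_error(perfusion_maps(conc, rep(0, length(b$truth_aif)),
                              b$dsc$tr_s, mask), "AIF integral")
})

test_that("linear scalings of concentration and AIF propagate correctly", {
  nt <- 40
  times <- 0:(nt - 1)
  aif <- gamma_variate_aif(list(t0 = 5, alpha = 1.5, beta = 1.8,
                                amplitude = 1), times)
  A <- dppmri:::aif_toeplitz(aif, 1)
  ct <- as.vector(A %*% (0.01 * exp(-times / 4)))
  d <- c(2, 2, 2)
  conc <- array(rep(ct, each = prod(d)), c(d, nt))
  mask <- volume_image(array(1, d))
  base <- perfusion_maps(conc, aif, 1, mask, 0.05)
  # tissue scaling by c scales CBF and CBV by c, leaves MTT unchanged
  sc <- perfusion_maps(3 * conc, aif, 1, mask, 0.05)
  expect_equal(sc$cbf$data, 3 * base$cbf$data, tolerance = 1e-6)
  expect_equal(sc$cbv$data, 3 * base$cbv$data, tolerance = 1e-6)
  expect_equal(sc$mtt$data, base$mtt$data, tolerance = 1e-6)
  # AIF scaling by c scales CBF and CBV by 1/c
  sa <- perfusion_maps(conc, 2 * aif, 1, mask, 0.05)
  expect_equal(sa$cbf$data, base$cbf$data / 2, tolerance = 1e-6)
  expect_equal(sa$cbv$data, base$cbv$data / 2, tolerance = 1e-6)
})

test_that("parameter-recovery bias shrinks as DSC noise vanishes", {
  bias_at <- function(noise) {
    median(vapply(1:20, function(s) {
      bb <- generate_phantom(perf_spec(noise_dsc = noise, seed = 100 + s))
      # condition on the true arrival: this sweep isolates map recovery
      arr <- bb$truth_arrival
      conc <- signal_to_concentration(bb$dsc, arr)
      sel <- select_aif(conc, bb$brain_mask, bb$dsc$tr_s, arr, 10)
      perf <- perfusion_maps(conc, sel$aif, bb$dsc$tr_s, bb$brain_mask,
                             0.05, arr)
      wm <- bb$truth_tissue_labels$data == 3 & bb$truth_artery$data == 0 &
        bb$truth_structure_labels$data == 0
      abs(median(perf$cbf$data[wm]) / 0.01 - 1)
    }, numeric(1)))
  }
  errs <- vapply(c(4, 1, 0), bias_at, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("the AIF verification record serializes to JSON", {
  b <- default_bundle()
  conc <- signal_to_concentration(b$dsc, b$truth_arrival)
  sel <- select_aif(conc, b$brain_mask, b$dsc$tr_s, b$truth_arrival, 5)
  perf <- perfusion_maps(conc, sel$aif, b$dsc$tr_s, b$brain_mask, 0.2,
                         arrival_index = b$truth_arrival,
                         aif_voxels = sel$voxels)
  path <- withr::local_tempfile(fileext = ".json")
  write_aif_json(perf, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$aif, perf$aif, tolerance = 1e-12)
  expect_equal(back$arrival_index, b$truth_arrival)
  expect_equal(nrow(back$voxels), nrow(sel$voxels))
})
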
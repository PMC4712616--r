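test_that("region growing recovers a hyperintense sphere exactly", {
  b <- default_bundle()
  ls <- b$spec$lesion_specs[[1]]
  r <- grow_lesion_roi(b$flair, ls$center, local_factor = 0.5, id = 1L)
  truth_n <- sum(b$truth_lesion_labels$data == 1)
  expect_equal(nrow(r$voxels), truth_n)
  # grown voxels are exactly the truth voxels
  lab <- array(0L, dim(b$flair$data))
  lab[r$voxels + 1] <- 1L
  expect_identical(lab == 1L, b$truth_lesion_labels$data == 1)
  # growing from lesion 1 never reaches lesion 2 (disjoint components)
  expect_true(all(b$truth_lesion_labels$data[r$voxels + 1] == 1))
})

test_that("region growing degenerate cases: strict peak, boundary flag", {
  a <- array(10, c(9, 9, 9))
  a[5, 5, 5] <- 100  # strict peak
  img <- volume_image(a, c(1, 1, 1), space = "flair")
  r <- grow_lesion_roi(img, c(4, 4, 4), local_factor = 1.0)
  expect_equal(nrow(r$voxels), 1L)
  expect_equal(r$voxels[1, ], c(x = 4L, y = 4L, z = 4L))
  # a region reaching the grid edge is flagged
  a2 <- array(100, c(9, 9, 9))
  img2 <- volume_image(a2, c(1, 1, 1), space = "flair")
  r2 <- grow_lesion_roi(img2, c(4, 4, 4), local_factor = 0.5)
  expect_true("touches_boundary" %in% r2$flags)
  expect_error(grow_lesion_roi(img, c(20, 0, 0), 0.5), "outside")
})

test_that("NAWM statistics are the arithmetic mean and sample SD", {
  img <- volume_image(array(100, c(6, 6, 6)), space = "t1")
  box <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  nr <- roi(0L, box, "NAWM_REF")
  expect_equal(nawm_stats(img, nr), c(mean = 100, sd = 0))
  img$data[2, 2, 2] <- 90; img$data[3, 2, 2] <- 110
  two <- roi(0L, rbind(c(1, 1, 1), c(2, 1, 1)), "NAWM_REF")
  st <- nawm_stats(img, two)
  expect_equal(st[["mean"]], 100)
  expect_equal(st[["sd"]], sqrt(200), tolerance = 1e-12)  # 14.142...
  expect_error(nawm_stats(img, roi(0L, rbind(c(1, 1, 1)), "NAWM_REF")),
               ">= 2")
  expect_error(nawm_stats(img, roi(1L, box, "C1")), "NAWM_REF")
  # noiseless phantom WM box gives (100, 0)
  b <- default_bundle()
  expect_equal(nawm_stats(b$t1, b$nawm_ref_roi), c(mean = 100, sd = 0))
})

test_that("classification thresholds follow the mean +/- Mf*SD rule", {
  th <- classification_thresholds(100, 5, 2)
  expect_equal(th$thre_low, 90)
  expect_equal(th$thre_high, 110)
  expect_equal(classification_thresholds(100, 0, 7)$thre_low, 100)
  expect_equal(classification_thresholds(100, 0, 7)$thre_high, 100)
  expect_equal(classification_thresholds(100, 5, 0)$thre_low, 100)
  # randomized triples against independent arithmetic
  set.seed(42)
  for (i in 1:200) {
    m <- stats::runif(1, -500, 500)
    s <- stats::runif(1, 0, 80)
    f <- stats::runif(1, 0, 6)
    th <- classification_thresholds(m, s, f)
    expect_identical(th$thre_high, m + f * s)
    expect_identical(th$thre_low, m - f * s)
    expect_lte(th$thre_low, th$thre_high)
  }
  expect_error(classification_thresholds(0, -1, 1), "sd")
  expect_error(classification_thresholds(0, 1, -1), "mf")
})

# synthetic classification scene: one WM background image pair with a NAWM
# box and lesions whose means are set exactly
classification_scene <- function(t1_lesion, gd_lesion, nawm_mean = 100,
                                 nawm_sd_pattern = c(95, 105)) {
  d <- c(16, 16, 16)
  t1 <- array(nawm_mean, d); gd <- array(nawm_mean, d)
  box <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  vals <- rep_len(nawm_sd_pattern, nrow(box))
  t1[box + 12] <- vals; gd[box + 12] <- vals  # NAWM box at (12..15)^3
  nawm <- roi(0L, box + 11L, "NAWM_REF")
  les <- as.matrix(expand.grid(5:7, 5:7, 5:7))
  t1[les + 1] <- t1_lesion; gd[les + 1] <- gd_lesion
  list(t1 = volume_image(t1, space = "flair"),
       gd = volume_image(gd, space = "flair"),
       nawm = nawm, lesion = roi(1L, les))
}

test_that("the four-class rule assigns C1-C4 from the two thresholds", {
  # NAWM (100, ~5) on both modalities, mf = 2 -> [90, 110]
  cases <- list(list(99, 130, "C1"), list(70, 130, "C2"),
                list(99, 95, "C3"), list(70, 95, "C4"))
  for (cs in cases) {
    sc <- classification_scene(cs[[1]], cs[[2]])
    rs <- classify_lesions(roi_set(list(sc$lesion)), sc$t1, sc$gd,
                           sc$nawm, mf = 2)
    expect_equal(rs$rois[[1]]$class_code, cs[[3]])
  }
  # boundary equality counts as isointense / non-enhancing: constant NAWM
  # makes both thresholds exactly 100, and a lesion mean of exactly 100
  # sits on both boundaries
  sc <- classification_scene(100, 100, nawm_sd_pattern = 100)
  rs <- classify_lesions(roi_set(list(sc$lesion)), sc$t1, sc$gd, sc$nawm, 2)
  expect_equal(rs$rois[[1]]$class_code, "C3")
  # T1-hyperintense lesions map to isointense with a flag
  sc2 <- classification_scene(150, 130)
  rs2 <- classify_lesions(roi_set(list(sc2$lesion)), sc2$t1, sc2$gd,
                          sc2$nawm, 2)
  expect_equal(rs2$rois[[1]]$class_code, "C1")
  expect_true("t1_hyperintense" %in% rs2$rois[[1]]$flags)
})

test_that("noiseless phantom lesions classify to the true classes", {
  b <- default_bundle()
  got <- phantom_classes(b)
  expect_identical(unname(got), unname(b$truth_classes))
  # exactly one class per lesion; acute/chronic split matches C1/C2 vs C3/C4
  rs <- classify_lesions(truth_rois(b), b$t1, b$gd_t1, b$nawm_ref_roi, 2)
  expect_setequal(c(attr(rs, "acute_ids"), attr(rs, "chronic_ids")),
                  as.integer(names(b$truth_classes)))
})

test_that("classification is invariant to global affine intensity rescaling", {
  b <- default_bundle()
  base <- phantom_classes(b)
  resc <- function(img, a, off) {
    img$data <- a * img$data + off
    img
  }
  b2 <- b
  b2$t1 <- resc(b$t1, 3.7, 55)
  b2$gd_t1 <- resc(b$gd_t1, 0.013, -4)
  expect_identical(phantom_classes(b2), base)
})

test_that("misclassification rate is nondecreasing in structural noise", {
  sds <- c(5, 25, 60)
  err <- vapply(sds, function(s) {
    mean(vapply(21:40, function(sd_seed) {
      bb <- generate_phantom(structural_spec(noise_t1 = s, seed = sd_seed))
      mean(phantom_classes(bb) != bb$truth_classes)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) >= 0))
})

test_that("ROI files round-trip and support manual class revision", {
  b <- default_bundle()
  rs <- classify_lesions(truth_rois(b), b$t1, b$gd_t1, b$nawm_ref_roi, 2)
  path <- withr::local_tempfile(fileext = ".roi")
  write_roiset(rs, path)
  back <- read_roiset(path)
  expect_equal(length(back), length(rs))
  for (i in seq_along(rs$rois)) {
    expect_identical(back$rois[[i]]$id, rs$rois[[i]]$id)
    expect_identical(back$rois[[i]]$voxels, rs$rois[[i]]$voxels)
    expect_identical(back$rois[[i]]$class_code, rs$rois[[i]]$class_code)
    expect_identical(back$rois[[i]]$label_text, rs$rois[[i]]$label_text)
    expect_identical(back$rois[[i]]$color, rs$rois[[i]]$color)
  }
  # operator flips one C3 to C4 in the text file; reload differs only there
  lines <- readLines(path)
  i_c3 <- grep("^ROI 5 C3", lines)[1]
  lines[i_c3] <- sub(" C3 ", " C4 ", lines[i_c3])
  writeLines(lines, path)
  revised <- read_roiset(path)
  codes0 <- vapply(back$rois, `[[`, character(1), "class_code")
  codes1 <- vapply(revised$rois, `[[`, character(1), "class_code")
  expect_equal(sum(codes0 != codes1), 1L)
  expect_equal(codes1[codes0 != codes1], "C4")
  # empty set round-trips
  p0 <- withr::local_tempfile(fileext = ".roi")
  write_roiset(roi_set(), p0)
  expect_length(read_roiset(p0), 0)
  # malformed line reports its number
  writeLines(c("# roi set v1", "ROI 1 C1 #FF0000 | ok", "v 1 2 3",
               "v nonsense"), p0)
  expect_error(read_roiset(p0), "line 4")
})

test_that("class masks partition the lesion set", {
  b <- default_bundle()
  rs <- classify_lesions(truth_rois(b), b$t1, b$gd_t1, b$nawm_ref_roi, 2)
  cm <- class_masks(rs, b$flair)
  union_classes <- cm$by_class$C1$data + cm$by_class$C2$data +
    cm$by_class$C3$data + cm$by_class$C4$data
  expect_identical(cm$total$data, (union_classes > 0) + 0)
  expect_true(all(union_classes <= 1))  # one class per voxel
  per_lesion_sum <- Reduce(`+`, lapply(cm$by_lesion, function(m)
    sum(m$data)))
  expect_equal(sum(cm$total$data), per_lesion_sum)
  # a class absent from the set still yields an (all-zero) mask
  rs2 <- roi_set(list(rs$rois[[which(vapply(rs$rois, `[[`, character(1),
                                            "class_code") == "C3")[1]]]))
  cm2 <- class_masks(rs2, b$flair)
  expect_equal(sum(cm2$by_class$C1$data), 0)
  expect_named(cm2$by_class, c("C1", "C2", "C3", "C4"))
})
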
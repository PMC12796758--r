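# Preprocessing: eligibility flow, labelling, splitting, slice selection,
# alignment, masking, stacking, resizing, augmentation.

make_manifest <- function() {
  generate_cohort(181, 9, c(CR = 20, PR = 129, SD = 23, PD = 0), seed = 7)
}

test_that("inclusion/exclusion retains exactly the eligible records in order", {
  m <- make_manifest()
  kept <- apply_inclusion_exclusion(m)
  expect_equal(nrow(kept), 172)
  expect_true(all(kept$received_nact & kept$mri_complete))
  expect_identical(kept$patient_id,
                   m$patient_id[m$received_nact & m$mri_complete])
  all_ok <- kept
  expect_identical(apply_inclusion_exclusion(all_ok), all_ok)
  none <- dplyr::mutate(m, mri_complete = FALSE)
  expect_equal(nrow(apply_inclusion_exclusion(none)), 0)
})

test_that("labels map CR/PR to 1 and SD/PD to 0", {
  m <- assign_labels(apply_inclusion_exclusion(make_manifest()))
  expect_equal(sum(m$label == 1), 149)
  expect_equal(sum(m$label == 0), 23)
  one <- tibble::tibble(patient_id = "X", response_category = "PD",
                        received_nact = TRUE, mri_complete = TRUE)
  expect_equal(assign_labels(one)$label, 0L)
  expect_equal(nrow(assign_labels(one[0, ])), 0)
  bad <- dplyr::mutate(one, response_category = NA_character_)
  expect_error(assign_labels(bad), class = "nactresp_validation_error")
})

test_that("3:1:1 split reproduces 103/34/35 and partitions patients", {
  m <- assign_labels(apply_inclusion_exclusion(make_manifest()))
  sp <- split_dataset(m, stratify = TRUE, seed = 42)
  expect_equal(unname(table(sp$split)), c(103, 34, 35), ignore_attr = TRUE)
  # partition: every eligible patient in exactly one split
  expect_setequal(sp$patient_id, m$patient_id)
  expect_equal(anyDuplicated(sp$patient_id), 0)
  # stratification preserves the class ratio within rounding
  merged <- dplyr::left_join(sp, m[, c("patient_id", "label")], by = "patient_id")
  frac <- tapply(merged$label, merged$split, mean)
  expect_true(all(abs(frac - 149 / 172) < 0.03))
  # determinism and seed sensitivity
  expect_identical(split_dataset(m, stratify = TRUE, seed = 42), sp)
  expect_false(identical(split_dataset(m, stratify = TRUE, seed = 43), sp))
  # exact ratio at n = 5
  m5 <- m[1:5, ]
  expect_equal(unname(table(split_dataset(m5, seed = 1)$split)), c(3, 1, 1),
               ignore_attr = TRUE)
  expect_error(split_dataset(m[1:4, ], seed = 1),
               class = "nactresp_validation_error")
})

test_that("slice selection centres on the largest diameter within +/- 20 mm", {
  # thickness 2.0 + gap 0.5 => 2.5 mm spacing => +/- 8 slices
  d <- c(rep(1, 10), 9, rep(1, 10))
  idx <- select_slices(d, 2.0, 0.5, 20)
  expect_equal(idx, 3:19)  # centre 11 +/- 8
  # clamping at the volume edge: one-sided selection, no invalid indices
  idx_edge <- select_slices(c(9, rep(1, 5)), 2.0, 0.5, 20)
  expect_equal(idx_edge, 1:6)
  # argmax with ties to the lowest index
  expect_true(2 %in% select_slices(c(1, 9, 3), 2.0, 0.5, 0.1))
  expect_equal(select_slices(c(1, 9, 9), 2.0, 0.5, 0.1), 2)
  expect_error(select_slices(c(0, 0)), class = "nactresp_validation_error")
})

test_that("rigid alignment recovers injected transforms on phantoms", {
  ser <- simulate_dce_series(lesion_params(25), c(48, 48), noise_sd = 0,
                             seed = 4)
  img <- ser$phases[[3]]
  res0 <- rigid_align(img, img)
  expect_equal(res0$transform, c(0, 0, 0))
  # injected translation (+3, -2): recovered inverse within half a pixel
  shifted <- nactresp:::shift_image(img, 3, -2)
  res <- rigid_align(img, shifted, max_angle = 2)
  expect_lte(max(abs(res$transform[1:2] - c(-3, 2))), 0.5)
  # injected rotation of 5 degrees: recovered within one degree
  rotated <- nactresp:::rotate_image(img, 5)
  res_rot <- rigid_align(img, rotated, max_shift = 2)
  expect_lte(abs(res_rot$transform[3] + 5), 1)
  expect_error(rigid_align(matrix(0, 0, 0), matrix(0, 0, 0)),
               class = "nactresp_validation_error")
})

test_that("breast mask excludes skin and chest wall and covers the lesion", {
  ser <- simulate_dce_series(lesion_params(24, amplitude = 0.8), c(64, 64),
                             noise_sd = 0.02, seed = 8)
  mask <- segment_breast(ser$phases[[2]])
  expect_true(is.logical(mask))
  expect_equal(dim(mask), dim(ser$phases[[2]]))
  gt <- ser$masks$breast
  dice <- 2 * sum(mask & gt) / (sum(mask) + sum(gt))
  expect_gte(dice, 0.95)
  expect_gte(sum(mask & ser$masks$lesion) / sum(ser$masks$lesion), 0.99)
  expect_lt(sum(mask & ser$masks$chest) / sum(ser$masks$chest), 0.05)
  expect_equal(segment_breast(matrix(0, 16, 16)), matrix(FALSE, 16, 16))
})

test_that("phase stacking preserves order and validates input", {
  phases <- lapply(1:6, function(i) matrix(i * seq_len(16) / 2, 4, 4))
  x <- stack_phases(phases)
  expect_equal(dim(x), c(4, 4, 6))
  expect_identical(x[, , 4], phases[[4]])  # channel p+1 is phase S_p
  rev_x <- stack_phases(rev(phases))
  expect_identical(rev_x[, , 1], phases[[6]])
  expect_error(stack_phases(phases[1:5]), class = "nactresp_validation_error")
  bad <- phases; bad[[2]] <- matrix(0, 3, 3)
  expect_error(stack_phases(bad), class = "nactresp_validation_error")
})

test_that("resizing is bilinear, shape-correct and constant-preserving", {
  img <- array(runif(320 * 320 * 6), c(320, 320, 6))
  out <- resize_image(img, 224)
  expect_equal(dim(out), c(224, 224, 6))
  const <- array(7, c(32, 32, 6))
  expect_equal(resize_image(const, 16), array(7, c(16, 16, 6)),
               tolerance = 1e-10)
  same <- array(runif(24 * 24 * 6), c(24, 24, 6))
  expect_identical(resize_image(same, 24), same)
  expect_error(resize_image(const, 4), class = "nactresp_validation_error")
})

test_that("uniform4 augmentation yields five pairs per input, applied jointly", {
  pairs <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:103),
    label = rep(c(1L, 0L), length.out = 103),
    pre = lapply(1:103, function(i) random_image(16, i)),
    post = lapply(1:103, function(i) random_image(16, i + 500)))
  aug <- augment_training_set(pairs, "uniform4", seed = 3)
  expect_equal(nrow(aug), 515)
  expect_equal(unname(table(aug$patient_id)), rep(5L, 103),
               ignore_attr = TRUE)
  # pre and post of a pair receive the identical transform
  one <- aug[aug$patient_id == "P001", ]
  hf <- one[one$variant == "hflip", ]
  expect_identical(hf$pre[[1]], nactresp:::apply_variant(pairs$pre[[1]], "hflip"))
  expect_identical(hf$post[[1]], nactresp:::apply_variant(pairs$post[[1]], "hflip"))
  # horizontal flip is an involution
  img <- pairs$pre[[1]]
  expect_identical(nactresp:::apply_variant(
    nactresp:::apply_variant(img, "hflip"), "hflip"), img)
  # determinism; empty input
  expect_identical(augment_training_set(pairs[1:4, ], "uniform4", seed = 9),
                   augment_training_set(pairs[1:4, ], "uniform4", seed = 9))
  expect_equal(nrow(augment_training_set(pairs[0, ], "uniform4")), 0)
  expect_error(augment_training_set(pairs[1:2, ], "bogus"),
               class = "nactresp_validation_error")
})

test_that("class-balanced augmentation approaches parity within 1.1:1", {
  pairs <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:103),
    label = rep(c(1L, 0L), times = c(89, 14)),
    pre = lapply(1:103, function(i) random_image(8, i)),
    post = lapply(1:103, function(i) random_image(8, i + 500)))
  aug <- augment_training_set(pairs, "class_balanced", seed = 5)
  counts <- table(aug$label)
  ratio <- max(counts) / min(counts)
  expect_lte(ratio, 1.1)
})

test_that("processed pairs round-trip to disk with their manifest", {
  dir <- withr::local_tempdir()
  pairs <- tibble::tibble(
    patient_id = c("A1", "A2"),
    label = c(1L, 0L),
    split = c("train", "test"),
    pre = lapply(1:2, function(i) random_image(16, i)),
    post = lapply(3:4, function(i) random_image(16, i)))
  man <- write_processed_pairs(pairs, dir)
  expect_equal(nrow(man), 2)
  expect_equal(length(list.files(dir, pattern = "nii.gz$")), 4)
  csv <- readr::read_csv(file.path(dir, "processed_manifest.csv"),
                         show_col_types = FALSE)
  expect_identical(names(csv), c("patient_id", "split", "label", "n_slices"))
  back <- read_dce_series(file.path(dir, "A1_pre.nii.gz"))
  expect_equal(back$phases[[2]], pairs$pre[[1]][, , 2], tolerance = 1e-6)
  # augmented sets log their variants
  aug <- augment_training_set(pairs[, c("patient_id", "label", "pre", "post")],
                              "uniform4", seed = 1)
  dir2 <- withr::local_tempdir()
  write_processed_pairs(aug, dir2)
  expect_true(file.exists(file.path(dir2, "augmentation_log.json")))
})
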
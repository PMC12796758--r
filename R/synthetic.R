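#' Synthetic paired DCE-MRI phantom cohorts
#'
#' The generator produces cohorts of paired pre-treatment / post-first-cycle
#' six-phase DCE-MRI phantom slices whose lesion-size dynamics encode the
#' RECIST response label. It emulates the statistical structure the pipeline
#' assumes — an eligibility flow (patients without NACT or with incomplete
#' MRI are excluded), exact response-category allocation, lesion enhancement
#' kinetics over phases S0–S5, and diameter change by response class — so
#' that the whole system is testable with no patient data.
#'
#' @name synthetic-cohort
NULL

CATEGORIES <- c("CR", "PR", "SD", "PD")

abort_validation <- function(field, msg) {
  rlang::abort(paste0(field, ": ", msg), class = "nactresp_validation_error",
               field = field)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a synthetic cohort manifest
#'
#' Builds a patient manifest with exact response-category allocation. Records
#' flagged as MRI-incomplete (drop-outs whose response was never assessed)
#' carry an `NA` response category; records without NACT carry neither a
#' category nor a label downstream. Lesion parameters for each patient are
#' drawn here so that the cohort is fully reproducible from its seed.
#'
#' @param n_patients Total number of patient records.
#' @param n_incomplete Number of records with incomplete MRI (excluded later).
#' @param category_counts Named integer vector or list with entries CR, PR,
#'   SD, PD; must sum to `n_patients - n_incomplete - n_no_nact`.
#' @param seed Integer seed; the manifest is deterministic given the seed.
#' @param n_no_nact Number of records that did not receive NACT (default 0).
#' @param diameter_range Pre-treatment lesion diameter range in mm.
#' @param amplitude_range Lesion enhancement amplitude range (dimensionless).
#' @return A tibble with one row per patient: `patient_id`,
#'   `response_category`, `received_nact`, `mri_complete`, `pre_path`,
#'   `post_path` (paths are `NA` until [write_cohort()]), plus lesion
#'   parameter columns used by the image simulator.
#' @examples
#' m <- generate_cohort(181, 9, c(CR = 20, PR = 129, SD = 23, PD = 0), seed = 7)
#' sum(m$received_nact & m$mri_complete)  # 172 eligible
#' @export
generate_cohort <- function(n_patients, n_incomplete, category_counts,
                            seed, n_no_nact = 0,
                            diameter_range = c(12, 45),
                            amplitude_range = c(0.5, 1.2)) {
  if (n_patients < 0) abort_validation("n_patients", "must be non-negative")
  if (n_incomplete > n_patients) {
    abort_validation("n_incomplete", "exceeds n_patients")
  }
  cc <- stats::setNames(rep(0L, 4L), CATEGORIES)
  if (length(category_counts)) {
    bad <- setdiff(names(category_counts), CATEGORIES)
    if (length(bad)) abort_validation("category_counts",
                                      paste("unknown category", bad[1]))
    cc[names(category_counts)] <- as.integer(unlist(category_counts))
  }
  n_eligible <- n_patients - n_incomplete - n_no_nact
  if (sum(cc) != n_eligible) {
    abort_validation("category_counts", sprintf(
      "must sum to n_patients - n_incomplete - n_no_nact = %d (got %d)",
      n_eligible, sum(cc)))
  }
  if (n_patients == 0L) {
    return(tibble::tibble(patient_id = character(),
                          response_category = character(),
                          received_nact = logical(),
                          mri_complete = logical(),
                          pre_path = character(), post_path = character(),
                          lesion_diameter_mm = double(),
                          lesion_amplitude = double(),
                          washin_rate = double(), washout_rate = double(),
                          seed = integer()))
  }
  with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n_patients))
    no_nact <- rep(FALSE, n_patients)
    if (n_no_nact > 0) no_nact[sample.int(n_patients, n_no_nact)] <- TRUE
    incomplete <- rep(FALSE, n_patients)
    pool <- which(!no_nact)
    if (n_incomplete > 0) {
      incomplete[sample(pool, n_incomplete)] <- TRUE
    }
    eligible <- which(!no_nact & !incomplete)
    cats <- rep(NA_character_, n_patients)
    alloc <- sample(rep(CATEGORIES, times = cc))
    cats[eligible] <- alloc
    manifest <- tibble::tibble(
      patient_id = ids,
      response_category = cats,
      received_nact = !no_nact,
      mri_complete = !incomplete,
      pre_path = NA_character_,
      post_path = NA_character_,
      lesion_diameter_mm = stats::runif(n_patients, diameter_range[1],
                                        diameter_range[2]),
      lesion_amplitude = stats::runif(n_patients, amplitude_range[1],
                                      amplitude_range[2]),
      washin_rate = stats::runif(n_patients, 0.8, 1.6),
      washout_rate = stats::runif(n_patients, 0.05, 0.25),
      seed = derive_seed(seed, seq_len(n_patients))
    )
    manifest
  })
}

#' Lesion parameters for the phantom simulator
#'
#' @param diameter Lesion diameter in mm (0 means no lesion).
#' @param center Lesion centre as (row, col) pixel coordinates (1-based);
#'   `NULL` places the lesion at the phantom breast centre.
#' @param amplitude Peak enhancement amplitude added on top of the lesion
#'   baseline intensity (dimensionless, >= 0).
#' @param washin_rate,washout_rate Rates (per phase) of the wash-in /
#'   wash-out enhancement curve, both >= 0.
#' @export
lesion_params <- function(diameter, center = NULL, amplitude = 0.8,
                          washin_rate = 1.2, washout_rate = 0.15) {
  if (diameter < 0) abort_validation("diameter", "must be >= 0")
  if (amplitude < 0) abort_validation("amplitude", "must be >= 0")
  if (washin_rate < 0 || washout_rate < 0) {
    abort_validation("rates", "must be >= 0")
  }
  structure(list(diameter = diameter, center = center, amplitude = amplitude,
                 washin_rate = washin_rate, washout_rate = washout_rate),
            class = "lesion_params")
}

#' Lesion enhancement kinetics
#'
#' Analytic wash-in/wash-out curve evaluated at phase `p` (S0 = 0 ... S5 = 5):
#' `u(p) = (1 - exp(-washin * p)) * exp(-washout * max(0, p - 3))`.
#' The curve satisfies `u(0) = 0` and is monotone non-decreasing through the
#' wash-in phases; a positive washout rate produces late-phase decline.
#'
#' @param p Phase index (vectorised), 0 to 5.
#' @inheritParams lesion_params
#' @return Numeric vector of enhancement fractions.
#' @export
enhancement_curve <- function(p, washin_rate = 1.2, washout_rate = 0.15) {
  (1 - exp(-washin_rate * p)) * exp(-washout_rate * pmax(0, p - 3))
}

#' Simulate one six-phase DCE-MRI phantom slice
#'
#' Renders an axial breast phantom: an air background, a chest-wall band at
#' the left edge, a circular breast with a thin bright skin rim, mild static
#' fibroglandular texture, and a circular enhancing lesion. Phase `p`
#' intensity inside the lesion is `baseline + amplitude * u(p) + noise` with
#' `u(p)` from [enhancement_curve()]; all other structures are static, so
#' with `noise_sd = 0` the lesion mean reproduces the analytic curve exactly.
#'
#' @param lesion A [lesion_params()] object.
#' @param image_size Integer (H, W), both >= 16.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed for the noise.
#' @param pixel_spacing mm per pixel (default 1.125, a 360 mm field of view
#'   on a 320 matrix).
#' @param slice_thickness,interslice_gap Slice geometry metadata in mm.
#' @return A `dce_series` object: a list with `phases` (six H x W matrices,
#'   S0..S5), spacing metadata, and ground-truth `masks` (breast interior,
#'   lesion, skin, chest wall) used as oracles for segmentation tests.
#' @export
simulate_dce_series <- function(lesion, image_size = c(64, 64), noise_sd = 0.02,
                                seed = 1, pixel_spacing = 1.125,
                                slice_thickness = 2.0, interslice_gap = 0.5) {
  H <- image_size[1]; W <- image_size[2]
  if (H < 16 || W < 16) abort_validation("image_size", "H and W must be >= 16")
  if (noise_sd < 0) abort_validation("noise_sd", "must be >= 0")
  if (pixel_spacing <= 0) abort_validation("pixel_spacing", "must be > 0")
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)

  chest_w <- max(2L, round(0.05 * W))
  chest <- cols <= chest_w

  bc <- c(H / 2, chest_w + 2 + (W - chest_w - 2) / 2)
  br <- 0.40 * min(H, W - chest_w - 2)
  dist_b <- sqrt((rows - bc[1])^2 + (cols - bc[2])^2)
  breast <- dist_b <= br
  skin <- dist_b > br & dist_b <= br + 2

  center <- lesion$center %||% bc
  r_px <- lesion$diameter / 2 / pixel_spacing
  dist_l <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  lesion_mask <- breast & (dist_l <= r_px) & r_px > 0

  texture <- 0.03 * sin(rows / 5) * cos(cols / 7)
  base <- matrix(0, H, W)
  base[chest] <- 0.60
  base[breast] <- 0.50 + texture[breast]
  base[skin] <- 0.75
  base[lesion_mask] <- 0.55

  u <- enhancement_curve(0:5, lesion$washin_rate, lesion$washout_rate)
  phases <- with_seed(seed, {
    lapply(1:6, function(i) {
      ph <- base
      ph[lesion_mask] <- 0.55 + lesion$amplitude * u[i]
      if (noise_sd > 0) ph <- ph + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      ph
    })
  })
  structure(list(phases = phases, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 interslice_gap = interslice_gap,
                 masks = list(breast = breast, lesion = lesion_mask,
                              skin = skin, chest = chest)),
            class = "dce_series")
}

#' Simulate the post-first-cycle lesion from the pre-treatment lesion
#'
#' Applies a RECIST 1.1-style diameter change by response category: CR
#' clears the lesion; PR shrinks the diameter by a fraction drawn in
#' `pr_range` (>= 30 %); SD draws a relative change within `sd_range`
#' (inside the RECIST stable band of -30 % to +20 %); PD grows by at least
#' 20 %. The enhancement amplitude scales with the same factor, mimicking
#' reduced perfusion of a responding lesion.
#'
#' @param pre_lesion A [lesion_params()] object with positive diameter.
#' @param response_category One of "CR", "PR", "SD", "PD".
#' @param seed Integer seed for the drawn change fraction.
#' @param pr_range,sd_range,pd_range Ranges of the relative diameter change
#'   (PR given as shrink fraction, SD/PD as signed relative change).
#' @return The post-treatment [lesion_params()].
#' @export
simulate_followup <- function(pre_lesion, response_category, seed = 1,
                              pr_range = c(0.30, 0.95),
                              sd_range = c(-0.299, 0.199),
                              pd_range = c(0.20, 0.60)) {
  if (pre_lesion$diameter <= 0) {
    abort_validation("pre_lesion", "diameter must be > 0")
  }
  if (!response_category %in% CATEGORIES) {
    abort_validation("response_category",
                     paste("unknown category:", response_category))
  }
  factor <- with_seed(seed, switch(
    response_category,
    CR = 0,
    PR = 1 - stats::runif(1, pr_range[1], pr_range[2]),
    SD = 1 + stats::runif(1, sd_range[1], sd_range[2]),
    PD = 1 + stats::runif(1, pd_range[1], pd_range[2])
  ))
  lesion_params(diameter = pre_lesion$diameter * factor,
                center = pre_lesion$center,
                amplitude = pre_lesion$amplitude * factor,
                washin_rate = pre_lesion$washin_rate,
                washout_rate = pre_lesion$washout_rate)
}

#' Write a cohort to disk as NIfTI series plus a CSV manifest
#'
#' Each MRI-complete record's pre and post six-phase series are simulated
#' from the manifest's lesion parameters and written as 4-D NIfTI
#' (H x W x 1 x 6, phases in the 4th dimension) with pixel-spacing metadata.
#' Incomplete records keep their row in the manifest but get no image files.
#' The manifest is written as `manifest.csv` and the generator settings
#' (seed, image size, noise) as a JSON sidecar.
#'
#' @param manifest A manifest from [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param image_size,noise_sd Passed to [simulate_dce_series()].
#' @return The manifest with `pre_path` / `post_path` filled in.
#' @export
write_cohort <- function(manifest, out_dir, image_size = c(64, 64),
                         noise_sd = 0.02) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(paste("cannot create directory", out_dir),
                 class = "nactresp_io_error")
  }
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  manifest <- dplyr::mutate(manifest,
                            pre_path = NA_character_,
                            post_path = NA_character_)
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    if (!isTRUE(rec$mri_complete)) next
    pre_lesion <- lesion_params(rec$lesion_diameter_mm,
                                amplitude = rec$lesion_amplitude,
                                washin_rate = rec$washin_rate,
                                washout_rate = rec$washout_rate)
    cat_i <- rec$response_category
    post_lesion <- if (!is.na(cat_i)) {
      simulate_followup(pre_lesion, cat_i, seed = rec$seed + 1L)
    } else pre_lesion
    pre <- simulate_dce_series(pre_lesion, image_size, noise_sd,
                               seed = rec$seed)
    post <- simulate_dce_series(post_lesion, image_size, noise_sd,
                                seed = rec$seed + 2L)
    pre_path <- file.path(img_dir, paste0(rec$patient_id, "_pre.nii.gz"))
    post_path <- file.path(img_dir, paste0(rec$patient_id, "_post.nii.gz"))
    write_dce_series(pre, pre_path)
    write_dce_series(post, post_path)
    manifest$pre_path[i] <- pre_path
    manifest$post_path[i] <- post_path
  }
  csv_path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest[, c("patient_id", "response_category",
                                "received_nact", "mri_complete",
                                "pre_path", "post_path")], csv_path)
  jsonlite::write_json(
    list(image_size = image_size, noise_sd = noise_sd,
         lesions = manifest[, c("patient_id", "lesion_diameter_mm",
                                "lesion_amplitude", "washin_rate",
                                "washout_rate", "seed")]),
    file.path(out_dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' Write / read one six-phase series as NIfTI
#'
#' @param series A `dce_series` object.
#' @param path Output `.nii` / `.nii.gz` path.
#' @export
write_dce_series <- function(series, path) {
  H <- nrow(series$phases[[1]]); W <- ncol(series$phases[[1]])
  arr <- array(0, c(H, W, 1L, 6L))
  for (i in 1:6) arr[, , 1L, i] <- series$phases[[i]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$pixel_spacing, series$pixel_spacing,
                           series$slice_thickness + series$interslice_gap, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_dce_series
#' @export
read_dce_series <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  structure(list(phases = lapply(1:6, function(i) arr[, , 1L, i]),
                 pixel_spacing = pd[1],
                 slice_thickness = pd[3] - 0.5, interslice_gap = 0.5,
                 masks = NULL),
            class = "dce_series")
}

#' Read a written cohort manifest back from disk
#'
#' @param dir Directory written by [write_cohort()].
#' @export
read_cohort <- function(dir) {
  readr::read_csv(file.path(dir, "manifest.csv"),
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    response_category = readr::col_character(),
                    received_nact = readr::col_logical(),
                    mri_complete = readr::col_logical(),
                    pre_path = readr::col_character(),
                    post_path = readr::col_character()))
}

#' Simulate an in-memory labelled image-pair cohort
#'
#' Convenience generator used by the training harness: draws responder (PR)
#' and non-responder (SD) patients, simulates their pre series and the
#' category-dependent post series, stacks phases into six-channel images and
#' returns everything as a tibble of labelled pairs. Pre-treatment lesion
#' parameters are drawn from the same distribution for both classes, so the
#' class signal lives entirely in the post image (the diameter change).
#'
#' @param n_responders,n_nonresponders Patients per class.
#' @param image_size,noise_sd Passed to [simulate_dce_series()].
#' @param seed Integer seed.
#' @param sd_range Relative-change range for the non-responders (default the
#'   narrow stable band used by the recovery experiments).
#' @param pr_range Shrink-fraction range for responders.
#' @return Tibble with `patient_id`, `label` (1 = responder), and `pre` /
#'   `post` list-columns of `[H, W, 6]` six-channel arrays.
#' @export
simulate_image_cohort <- function(n_responders, n_nonresponders,
                                  image_size = c(64, 64), noise_sd = 0.02,
                                  seed = 1,
                                  sd_range = c(-0.10, 0.10),
                                  pr_range = c(0.30, 0.95)) {
  n <- n_responders + n_nonresponders
  cats <- c(rep("PR", n_responders), rep("SD", n_nonresponders))
  params <- with_seed(seed, tibble::tibble(
    diameter = stats::runif(n, 18, 40),
    amplitude = stats::runif(n, 0.6, 1.1),
    washin = stats::runif(n, 0.9, 1.5),
    washout = stats::runif(n, 0.05, 0.2)
  ))
  rows <- lapply(seq_len(n), function(i) {
    s <- derive_seed(seed, i)
    pre_lesion <- lesion_params(params$diameter[i],
                                amplitude = params$amplitude[i],
                                washin_rate = params$washin[i],
                                washout_rate = params$washout[i])
    post_lesion <- simulate_followup(pre_lesion, cats[i], seed = s + 1L,
                                     pr_range = pr_range, sd_range = sd_range)
    pre <- simulate_dce_series(pre_lesion, image_size, noise_sd, seed = s)
    post <- simulate_dce_series(post_lesion, image_size, noise_sd,
                                seed = s + 2L)
    list(pre = stack_phases(pre$phases), post = stack_phases(post$phases))
  })
  tibble::tibble(
    patient_id = sprintf("S%04d", seq_len(n)),
    label = as.integer(cats %in% c("CR", "PR")),
    pre = lapply(rows, `[[`, "pre"),
    post = lapply(rows, `[[`, "post")
  )
}
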
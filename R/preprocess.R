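#' Cohort preprocessing pipeline
#'
#' Implements the workflow that turns a raw cohort manifest into labelled
#' six-channel image pairs: eligibility filtering, binary response
#' labelling, slice selection around the largest-diameter slice, rigid
#' pre/post alignment, breast masking, phase stacking, resizing,
#' patient-level 3:1:1 splitting and training-set augmentation.
#'
#' @name preprocess
NULL

#' Apply the inclusion / exclusion criteria
#'
#' Retains exactly the records that received NACT and have complete MRI,
#' preserving order. Mirrors the clinical flow in which patients without
#' NACT or with incomplete imaging are excluded before modelling.
#'
#' @param manifest A cohort manifest tibble.
#' @return The filtered manifest.
#' @export
apply_inclusion_exclusion <- function(manifest) {
  dplyr::filter(manifest, .data$received_nact & .data$mri_complete)
}

#' Assign binary response labels
#'
#' CR and PR are responders (label 1); SD and PD are non-responders
#' (label 0).
#'
#' @param records Manifest of eligible records; every record must carry a
#'   response category.
#' @return The manifest with a `label` column appended.
#' @export
assign_labels <- function(records) {
  if (nrow(records) == 0L) {
    return(dplyr::mutate(records, label = integer()))
  }
  if (any(is.na(records$response_category))) {
    abort_validation("response_category", "missing for one or more records")
  }
  bad <- setdiff(unique(records$response_category), CATEGORIES)
  if (length(bad)) {
    abort_validation("response_category", paste("unknown category", bad[1]))
  }
  dplyr::mutate(records,
                label = as.integer(.data$response_category %in% c("CR", "PR")))
}

#' Patient-level 3:1:1 train/validation/test split
#'
#' Sizes follow floor(3n/5) / floor(n/5) / remainder, the rounding that
#' yields 103/34/35 from 172 eligible patients. The split is patient-level
#' (no record appears in two splits) and deterministic under the seed. With
#' `stratify = TRUE` the class ratio is preserved per split within rounding
#' (largest-remainder allocation per class).
#'
#' @param records Manifest of eligible records (needs `label` for
#'   stratification).
#' @param ratio Split ratio; only 3:1:1 is supported.
#' @param stratify Preserve the class ratio per split.
#' @param seed Integer seed.
#' @return Tibble with `patient_id` and `split` (train / val / test).
#' @export
split_dataset <- function(records, ratio = c(3, 1, 1), stratify = FALSE,
                          seed = 1) {
  n <- nrow(records)
  if (n < 5) abort_validation("records", "need at least 5 records to split")
  if (!identical(as.numeric(ratio), c(3, 1, 1))) {
    abort_validation("ratio", "only the 3:1:1 ratio is supported")
  }
  n_train <- (3 * n) %/% 5
  n_val <- n %/% 5
  with_seed(seed, {
    if (!stratify) {
      ord <- sample(records$patient_id)
      split <- rep(c("train", "val", "test"),
                   c(n_train, n_val, n - n_train - n_val))
      out <- tibble::tibble(patient_id = ord, split = split)
    } else {
      if (!"label" %in% names(records)) {
        abort_validation("records", "stratified split requires a label column")
      }
      classes <- split(records$patient_id, records$label)
      classes <- lapply(classes, sample)
      n_c <- vapply(classes, length, integer(1))
      t_c <- (3 * n_c) %/% 5
      v_c <- n_c %/% 5
      # largest-remainder top-up so global sizes match the unstratified ones
      top_up <- function(base, exact, target) {
        deficit <- target - sum(base)
        if (deficit > 0) {
          ord <- order(exact - base, decreasing = TRUE)
          base[ord[seq_len(deficit)]] <- base[ord[seq_len(deficit)]] + 1L
        }
        base
      }
      t_c <- top_up(t_c, 3 * n_c / 5, n_train)
      v_c <- top_up(v_c, n_c / 5, n_val)
      pieces <- lapply(seq_along(classes), function(i) {
        ids <- classes[[i]]
        k1 <- t_c[i]; k2 <- v_c[i]
        tibble::tibble(
          patient_id = ids,
          split = rep(c("train", "val", "test"),
                      c(k1, k2, length(ids) - k1 - k2)))
      })
      out <- dplyr::bind_rows(pieces)
    }
    out$split <- factor(out$split, levels = c("train", "val", "test"))
    out[match(records$patient_id, out$patient_id), ]
  })
}

#' Select slices around the largest-diameter slice
#'
#' The slice with the largest tumour diameter is the central reference
#' slice (ties break to the lowest index); slices within `extent_mm` of it
#' are included, using `slice_thickness + interslice_gap` as the
#' inter-slice spacing, clamped to the volume bounds. Indices are 1-based.
#'
#' @param tumor_diameters_per_slice Numeric vector of per-slice diameters (mm).
#' @param slice_thickness,interslice_gap Slice geometry in mm.
#' @param extent_mm Half-extent of the selection in mm (default 20).
#' @return Integer vector of selected slice indices.
#' @export
select_slices <- function(tumor_diameters_per_slice, slice_thickness = 2.0,
                          interslice_gap = 0.5, extent_mm = 20) {
  d <- tumor_diameters_per_slice
  if (length(d) == 0L || all(d <= 0)) {
    abort_validation("tumor_diameters_per_slice",
                     "need at least one slice with positive diameter")
  }
  center <- which.max(d)
  spacing <- slice_thickness + interslice_gap
  n_side <- floor(extent_mm / spacing)
  lo <- max(1L, center - n_side)
  hi <- min(length(d), center + n_side)
  seq.int(lo, hi)
}

# content shift: output[r + dx, c + dy] = input[r, c], zero fill
shift_image <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  src_r <- seq_len(H) - dx
  src_c <- seq_len(W) - dy
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

rotate_image <- function(img, angle) {
  if (angle == 0) return(img)
  out <- EBImage::rotate(img, angle, filter = "bilinear",
                         output.dim = c(nrow(img), ncol(img)), bg.col = 0)
  matrix(as.numeric(out), nrow(img), ncol(img))
}

ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Rigid alignment of a post-treatment slice to its pre-treatment slice
#'
#' Exhaustive search over integer translations within `max_shift` pixels and
#' rotations within `max_angle` degrees (step `angle_step`), scoring
#' normalised cross-correlation on the overlapping region. Deterministic:
#' candidates are visited in order of increasing magnitude and only strict
#' improvements are accepted, so identical images map to the identity
#' transform.
#'
#' @param pre_slice,post_slice Same-shape numeric matrices.
#' @param max_shift Translation search bound in pixels.
#' @param max_angle,angle_step Rotation search bound / step in degrees.
#' @return List with `aligned_post` (post resampled into the pre frame) and
#'   `transform = c(dx, dy, dtheta)` (the shift and rotation applied to the
#'   post image).
#' @export
rigid_align <- function(pre_slice, post_slice, max_shift = 8,
                        max_angle = 10, angle_step = 0.5) {
  if (length(pre_slice) == 0L || length(post_slice) == 0L) {
    abort_validation("slices", "empty image")
  }
  if (!all(dim(pre_slice) == dim(post_slice))) {
    abort_validation("slices", "pre and post must share shape")
  }
  thetas <- sort(unique(c(0, seq(-max_angle, max_angle, by = angle_step))))
  thetas <- thetas[order(abs(thetas), thetas)]
  shifts <- -max_shift:max_shift
  shifts <- shifts[order(abs(shifts), shifts)]
  best <- list(score = -Inf, transform = c(0, 0, 0), img = post_slice)
  for (theta in thetas) {
    rot <- rotate_image(post_slice, theta)
    for (dx in shifts) {
      for (dy in shifts) {
        cand <- shift_image(rot, dx, dy)
        sc <- ncc(pre_slice, cand)
        if (sc > best$score) {
          best <- list(score = sc, transform = c(dx, dy, theta), img = cand)
        }
      }
    }
  }
  list(aligned_post = best$img, transform = best$transform,
       score = best$score)
}

#' Breast segmentation mask
#'
#' Otsu thresholding followed by largest-connected-component selection and a
#' 2-pixel rim erosion. The rim erosion removes the thin bright skin; the
#' chest-wall band, disconnected from the breast in the phantom geometry,
#' falls away with the smaller components.
#'
#' @param slice Numeric matrix.
#' @return Logical matrix of the same shape.
#' @export
segment_breast <- function(slice) {
  if (all(slice == 0)) return(matrix(FALSE, nrow(slice), ncol(slice)))
  rng <- range(slice)
  norm <- (slice - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  thr <- EBImage::otsu(EBImage::Image(norm))
  fg <- norm > thr
  labels <- EBImage::bwlabel(EBImage::Image(fg))
  tab <- table(labels[labels > 0])
  if (length(tab) == 0L) return(matrix(FALSE, nrow(slice), ncol(slice)))
  keep <- as.integer(names(tab)[which.max(tab)])
  comp <- matrix(labels == keep, nrow(slice), ncol(slice))
  eroded <- EBImage::erode(EBImage::Image(comp), EBImage::makeBrush(5, "disc"))
  matrix(as.logical(eroded), nrow(slice), ncol(slice))
}

#' Stack six phase images into a six-channel composite
#'
#' @param slices List of exactly six same-shape matrices, ordered S0..S5.
#' @return Array `[H, W, 6]`; channel `p + 1` equals phase `S_p` unchanged.
#' @export
stack_phases <- function(slices) {
  if (length(slices) != 6L) {
    abort_validation("slices", "exactly six phases (S0..S5) required")
  }
  dims <- lapply(slices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort_validation("slices", "all phases must share shape")
  }
  arr <- array(0, c(dims[[1]], 6L))
  for (i in 1:6) arr[, , i] <- slices[[i]]
  arr
}

#' Resize a six-channel image
#'
#' Bilinear per-channel resize to `side` x `side`.
#'
#' @param image `[H, W, 6]` array.
#' @param side Target side length (>= 8; default 224).
#' @return `[side, side, 6]` array.
#' @export
resize_image <- function(image, side = 224) {
  if (side < 8) abort_validation("side", "must be >= 8")
  if (dim(image)[1] == side && dim(image)[2] == side) return(image)
  out <- array(0, c(side, side, dim(image)[3]))
  for (i in seq_len(dim(image)[3])) {
    out[, , i] <- as.matrix(EBImage::resize(EBImage::Image(image[, , i]),
                                            w = side, h = side))
  }
  out
}

# apply one named augmentation variant to a six-channel array
apply_variant <- function(img, variant) {
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- array(0, dim(img))
  for (i in seq_len(dim(img)[3])) {
    ch <- img[, , i]
    out[, , i] <- switch(
      variant,
      hflip = ch[, rev(seq_len(W))],
      vflip = ch[rev(seq_len(H)), ],
      rot_p15 = rotate_image(ch, 15), rot_m15 = rotate_image(ch, -15),
      rot_p30 = rotate_image(ch, 30), rot_m30 = rotate_image(ch, -30),
      identity = ch,
      stop("unknown variant ", variant))
  }
  out
}

#' Augment a set of labelled training pairs
#'
#' `uniform4` yields each pair plus four variants — horizontal flip,
#' vertical flip, one 15-degree and one 30-degree rotation with seed-chosen
#' signs — so 103 pairs become 515. `class_balanced` instead chooses
#' per-class variant counts (from the pool h/v flips and the four fixed
#' rotations) so the post-augmentation class ratio is within 1.1:1 of
#' parity. Pre and post images of a pair always receive the identical
#' transform; validation and test sets must never be passed through this
#' function.
#'
#' @param pairs Tibble with `patient_id`, `label`, and `pre`/`post`
#'   list-columns of `[H, W, 6]` arrays.
#' @param policy `"uniform4"` or `"class_balanced"`.
#' @param seed Integer seed (rotation signs, balancing order).
#' @return Augmented pairs tibble with a `variant` column.
#' @export
augment_training_set <- function(pairs, policy = c("uniform4", "class_balanced"),
                                 seed = 1) {
  policy <- tryCatch(match.arg(policy),
                     error = function(e) abort_validation("policy",
                       paste("unknown policy:", policy[1])))
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(pairs, variant = character()))
  }
  with_seed(seed, {
    if (policy == "uniform4") {
      sign15 <- sample(c("rot_p15", "rot_m15"), nrow(pairs), replace = TRUE)
      sign30 <- sample(c("rot_p30", "rot_m30"), nrow(pairs), replace = TRUE)
      variants_per_pair <- lapply(seq_len(nrow(pairs)), function(i) {
        c("identity", "hflip", "vflip", sign15[i], sign30[i])
      })
    } else {
      pool <- c("hflip", "vflip", "rot_p15", "rot_m15", "rot_p30", "rot_m30")
      counts <- table(factor(pairs$label, levels = c(0, 1)))
      maj <- max(counts)
      variants_per_pair <- vector("list", nrow(pairs))
      for (cl in c(0L, 1L)) {
        idx <- which(pairs$label == cl)
        n_cl <- length(idx)
        if (n_cl == 0L) next
        # minimal per-pair variant counts bringing this class up to the
        # majority count; capped by the variant pool
        v_base <- min(length(pool), max(0L, maj %/% n_cl - 1L))
        extras <- max(0L, min(maj - n_cl * (v_base + 1L), n_cl))
        extra_idx <- if (extras > 0) sample(idx, extras) else integer()
        for (i in idx) {
          k <- v_base + as.integer(i %in% extra_idx)
          k <- min(k, length(pool))
          variants_per_pair[[i]] <- c("identity", pool[seq_len(k)])
        }
      }
    }
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      vs <- variants_per_pair[[i]]
      tibble::tibble(
        patient_id = pairs$patient_id[i],
        label = pairs$label[i],
        variant = vs,
        pre = lapply(vs, function(v) apply_variant(pairs$pre[[i]], v)),
        post = lapply(vs, function(v) apply_variant(pairs$post[[i]], v)))
    })
    dplyr::bind_rows(rows)
  })
}

#' Build labelled image pairs from a written cohort
#'
#' Reads each eligible record's pre/post NIfTI series, stacks the six
#' phases, optionally resizes, optionally applies the breast mask computed
#' from the pre-treatment S0 phase to both timepoints, and optionally
#' rigidly aligns the post slice to the pre slice per channel.
#'
#' @param manifest Manifest with paths (from [write_cohort()] or
#'   [read_cohort()]), already filtered and labelled.
#' @param side Target image side (`NULL` keeps the stored size).
#' @param mask Apply the breast mask.
#' @param align Run rigid alignment of post to pre (the phantom generator
#'   renders both timepoints in a common frame, so this defaults to FALSE).
#' @return Pairs tibble (`patient_id`, `label`, `pre`, `post`).
#' @export
prepare_pairs <- function(manifest, side = NULL, mask = FALSE, align = FALSE) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    pre <- read_dce_series(rec$pre_path)
    post <- read_dce_series(rec$post_path)
    if (align) {
      tf <- rigid_align(pre$phases[[1]], post$phases[[1]])
      post$phases <- lapply(post$phases, function(ch) {
        shift_image(rotate_image(ch, tf$transform[3]),
                    tf$transform[1], tf$transform[2])
      })
    }
    if (mask) {
      m <- segment_breast(pre$phases[[1]])
      pre$phases <- lapply(pre$phases, function(ch) ch * m)
      post$phases <- lapply(post$phases, function(ch) ch * m)
    }
    pre_img <- stack_phases(pre$phases)
    post_img <- stack_phases(post$phases)
    if (!is.null(side)) {
      pre_img <- resize_image(pre_img, side)
      post_img <- resize_image(post_img, side)
    }
    list(pre = pre_img, post = post_img)
  })
  tibble::tibble(patient_id = manifest$patient_id,
                 label = manifest$label,
                 pre = lapply(rows, `[[`, "pre"),
                 post = lapply(rows, `[[`, "post"))
}

#' Write processed image pairs and their manifest to disk
#'
#' Persists each labelled pair as two NIfTI files and a processed-manifest
#' CSV with columns `patient_id`, `split`, `label`, `n_slices`; when the
#' pairs carry a `variant` column (augmented sets) an augmentation log is
#' written as JSON.
#'
#' @param pairs Pairs tibble (optionally with `split` and `variant`).
#' @param out_dir Output directory.
#' @param pixel_spacing Spacing metadata for the written NIfTI files.
#' @return The manifest tibble, invisibly.
#' @export
write_processed_pairs <- function(pairs, out_dir, pixel_spacing = 1.125) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  as_series <- function(img) {
    structure(list(phases = lapply(1:6, function(i) img[, , i]),
                   pixel_spacing = pixel_spacing,
                   slice_thickness = 2.0, interslice_gap = 0.5),
              class = "dce_series")
  }
  for (i in seq_len(nrow(pairs))) {
    stem <- pairs$patient_id[i]
    if ("variant" %in% names(pairs)) {
      stem <- paste0(stem, "_", pairs$variant[i])
    }
    write_dce_series(as_series(pairs$pre[[i]]),
                     file.path(out_dir, paste0(stem, "_pre.nii.gz")))
    write_dce_series(as_series(pairs$post[[i]]),
                     file.path(out_dir, paste0(stem, "_post.nii.gz")))
  }
  manifest <- tibble::tibble(
    patient_id = pairs$patient_id,
    split = if ("split" %in% names(pairs)) as.character(pairs$split)
            else NA_character_,
    label = pairs$label,
    n_slices = 1L)
  readr::write_csv(manifest, file.path(out_dir, "processed_manifest.csv"))
  if ("variant" %in% names(pairs)) {
    jsonlite::write_json(
      lapply(split(pairs$variant, pairs$patient_id), as.list),
      file.path(out_dir, "augmentation_log.json"))
  }
  invisible(manifest)
}
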
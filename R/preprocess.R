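#' Rectangular region of interest
#'
#' 0-based, half-open pixel box `[row_start, row_stop) x [col_start,
#' col_stop)`, the convention used throughout the package so boxes round-trip
#' unambiguously with NIfTI readers.
#'
#' @param row_start,row_stop,col_start,col_stop Pixel indices.
#' @return An `roi_box`.
#' @export
roi_box <- function(row_start, row_stop, col_start, col_stop) {
  assert_that(row_stop > row_start && col_stop > col_start,
              "roi_box: stop must exceed start on both axes")
  assert_that(row_start >= 0 && col_start >= 0, "roi_box: negative start index")
  structure(list(row_start = as.integer(row_start), row_stop = as.integer(row_stop),
                 col_start = as.integer(col_start), col_stop = as.integer(col_stop)),
            class = "roi_box")
}

#' Multiphase key-slice stack
#'
#' A light wrapper around an `H x W x T` numeric array (one 2D key slice per
#' temporal phase) carrying a normalization flag and, when produced by
#' [select_key_slice()], the chosen slice indices.
#'
#' @param values `H x W x T` array.
#' @param normalized Has Z-score normalization been applied?
#' @param slice_index Optional integer vector of selected slice indices.
#' @return A `phase_stack`.
#' @export
phase_stack <- function(values, normalized = FALSE, slice_index = NULL) {
  assert_that(length(dim(values)) == 3, "phase_stack values must be H x W x T")
  structure(list(values = values, normalized = normalized,
                 slice_index = slice_index),
            class = "phase_stack")
}

#' @export
print.phase_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("phase_stack: %d x %d pixels, %d phases%s\n", d[1], d[2], d[3],
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Select the key slice of each phase by tumor burden
#'
#' For every phase, picks the 2D slice whose in-slice tumor mask area is
#' largest (ties broken toward the lowest slice index) and assembles the
#' key-slice stack.
#'
#' @param volumes List (one per phase) of `H x W x S` arrays.
#' @param masks List of matching binary tumor masks.
#' @return A [phase_stack()] with `slice_index` recorded.
#' @export
select_key_slice <- function(volumes, masks) {
  assert_that(length(volumes) == length(masks) && length(volumes) >= 1,
              "volumes and masks must be nonempty lists of equal length")
  slices <- integer(length(volumes))
  planes <- vector("list", length(volumes))
  for (p in seq_along(volumes)) {
    v <- volumes[[p]]; m <- masks[[p]]
    assert_that(identical(dim(v), dim(m)),
                "volume and mask shapes disagree for a phase")
    areas <- apply(m, 3, sum)
    if (all(areas == 0)) rlang::abort("no tumor delineated: mask is empty")
    slices[p] <- which.max(areas)  # lowest index on ties
    planes[[p]] <- v[, , slices[p]]
  }
  vals <- array(unlist(planes), dim = c(dim(volumes[[1]])[1:2], length(volumes)))
  phase_stack(vals, normalized = FALSE, slice_index = slices)
}

#' Fit global Z-score normalization statistics on the training cohort
#'
#' Pools every tumor-region voxel across all phases of all supplied training
#' samples and returns their overall mean and standard deviation. Validation
#' and testing samples must never be passed here: the returned object records
#' the contributing sample ids so leakage can be asserted downstream.
#'
#' @param stacks List of [phase_stack()] (or `H x W x T` arrays).
#' @param tumor_masks List of `H x W` logical masks, one per sample.
#' @param ids Optional character ids of the contributing samples.
#' @return A `norm_stats` list with `mu`, `sigma`, `n_voxels`, `ids`.
#' @export
fit_norm_stats <- function(stacks, tumor_masks, ids = NULL) {
  assert_that(length(stacks) == length(tumor_masks) && length(stacks) >= 1,
              "need matching nonempty lists of stacks and masks")
  vox <- unlist(lapply(seq_along(stacks), function(i) {
    v <- if (inherits(stacks[[i]], "phase_stack")) stacks[[i]]$values else stacks[[i]]
    m <- tumor_masks[[i]]
    if (!any(m)) return(numeric(0))
    apply(v, 3, function(plane) plane[m])
  }))
  assert_that(length(vox) > 0, "no tumor voxels in any training sample")
  mu <- mean(vox)
  sigma <- sqrt(mean((vox - mu)^2))
  if (sigma <= 0) rlang::abort("degenerate cohort: pooled tumor variance is zero")
  structure(list(mu = mu, sigma = sigma, n_voxels = length(vox),
                 ids = ids %||% paste0("sample", seq_along(stacks))),
            class = "norm_stats")
}

#' Z-score normalize a phase stack
#'
#' Every voxel `v` maps to `(v - mu) / sigma` with the training-cohort global
#' statistics; the same statistics are applied to all voxels of the crop,
#' tumor and non-tumor alike.
#'
#' @param stack A [phase_stack()].
#' @param stats A `norm_stats` from [fit_norm_stats()].
#' @return The normalized [phase_stack()].
#' @export
znormalize <- function(stack, stats) {
  assert_that(inherits(stats, "norm_stats") && stats$sigma > 0,
              "stats must be a norm_stats with positive sigma")
  phase_stack((stack$values - stats$mu) / stats$sigma, normalized = TRUE,
              slice_index = stack$slice_index)
}

#' Crop to an ROI and resize to the canonical model input size
#'
#' Crops each phase to the 0-based half-open box and resizes bilinearly to
#' `target_side x target_side` (224 by default, the canonical model input).
#' Masks should instead be resized with `interp = "nearest"` to stay binary.
#'
#' @param stack A [phase_stack()].
#' @param roi An [roi_box()].
#' @param target_side Output pixels per side.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return The cropped and resized [phase_stack()].
#' @export
crop_and_resize <- function(stack, roi, target_side = 224,
                            interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(stack$values)
  assert_that(roi$row_stop <= d[1] && roi$col_stop <= d[2],
              "roi outside image bounds")
  rows <- (roi$row_start + 1):roi$row_stop
  cols <- (roi$col_start + 1):roi$col_stop
  out <- array(0, dim = c(target_side, target_side, d[3]))
  fn <- if (interp == "bilinear") cpp_resize_bilinear else cpp_resize_nearest
  for (p in seq_len(d[3])) {
    out[, , p] <- fn(stack$values[rows, cols, p], target_side, target_side)
  }
  phase_stack(out, normalized = stack$normalized, slice_index = stack$slice_index)
}

# Nearest-time phase projection matrix mapping T acquired phases onto the
# canonical protocol grid. Each canonical phase copies the acquired phase
# closest in time (earlier one on ties).
phase_projection_matrix <- function(times_actual, times_canonical) {
  P <- matrix(0, nrow = length(times_canonical), ncol = length(times_actual))
  for (j in seq_along(times_canonical)) {
    i <- which.min(abs(times_actual - times_canonical[j]))
    P[j, i] <- 1
  }
  P
}

#' Adapt the phase count of a stack to the canonical protocol
#'
#' Patients occasionally lack one acquisition (the 60 s phase in about 5% of
#' cases). A `canonical_T x T` projection applied along the phase axis maps
#' the acquired phases onto the canonical 5-phase grid; with `T ==
#' canonical_T` the stack passes through unchanged. The default projection
#' duplicates the nearest acquired phase (in acquisition time); a learned 1x1
#' convolution can be supplied via `projection`.
#'
#' @param stack A [phase_stack()].
#' @param canonical_T Target phase count (default 5).
#' @param times Acquisition times of the stack's phases.
#' @param canonical_times Acquisition times of the canonical protocol.
#' @param projection Optional explicit `canonical_T x T` matrix.
#' @return A [phase_stack()] with `canonical_T` phases.
#' @export
adapt_phase_count <- function(stack, canonical_T = 5,
                              times = NULL,
                              canonical_times = c(0, 30, 60, 90, 300),
                              projection = NULL) {
  d <- dim(stack$values)
  T_in <- d[3]
  assert_that(T_in >= 2, "need at least 2 phases")
  if (is.null(projection)) {
    if (T_in == canonical_T) return(stack)
    if (is.null(times)) {
      # assume the missing acquisitions are interior ones nearest the middle
      times <- canonical_times[round(seq(1, length(canonical_times), length.out = T_in))]
    }
    projection <- phase_projection_matrix(times, canonical_times)
  }
  assert_that(nrow(projection) == canonical_T && ncol(projection) == T_in,
              "projection shape must be canonical_T x T")
  flat <- matrix(stack$values, nrow = d[1] * d[2], ncol = T_in)
  out <- flat %*% t(projection)
  phase_stack(array(out, dim = c(d[1], d[2], canonical_T)),
              normalized = stack$normalized, slice_index = stack$slice_index)
}

#' Default augmentation policy
#'
#' Transform probabilities and ranges for training-time augmentation. The
#' same spatial transform is applied to every phase of a sample (temporal
#' coherence). Noise scales are in normalized intensity units.
#'
#' @param p_rotate,max_rotate Rotation probability and max degrees.
#' @param p_scale,scale_range Isotropic scaling probability and range.
#' @param p_translate,max_translate Translation probability and max pixels.
#' @param p_rician,rician_sigma Rician noise probability and scale.
#' @param p_gaussian,gaussian_sigma Gaussian noise probability and scale.
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(p_rotate = 0.5, max_rotate = 15,
                           p_scale = 0.5, scale_range = c(0.9, 1.1),
                           p_translate = 0.5, max_translate = 10,
                           p_rician = 0.3, rician_sigma = 0.05,
                           p_gaussian = 0.3, gaussian_sigma = 0.05) {
  structure(as.list(environment()), class = "augment_policy")
}

#' Augment a phase stack
#'
#' Applies (with the policy's probabilities) a rotation, isotropic scaling
#' and translation -- composed into a single bilinear warp so repeated
#' resampling does not accumulate -- followed by optional Rician and Gaussian
#' noise. Identical transform parameters are used for all phases of the
#' sample. With all probabilities zero the stack is returned unchanged.
#'
#' @param stack A [phase_stack()].
#' @param policy An [augment_policy()].
#' @param seed Integer seed.
#' @return The augmented [phase_stack()].
#' @export
augment <- function(stack, policy = augment_policy(), seed = 1L) {
  with_seed(seed, {
    deg <- if (runif(1) < policy$p_rotate) runif(1, -policy$max_rotate, policy$max_rotate) else 0
    sc <- if (runif(1) < policy$p_scale) runif(1, policy$scale_range[1], policy$scale_range[2]) else 1
    tr <- if (runif(1) < policy$p_translate) runif(2, -policy$max_translate, policy$max_translate) else c(0, 0)
    use_ric <- runif(1) < policy$p_rician
    use_gau <- runif(1) < policy$p_gaussian
    d <- dim(stack$values)
    out <- stack$values
    if (deg != 0 || sc != 1 || any(tr != 0)) {
      th <- deg * pi / 180
      # inverse map: rotate by -th and scale by 1/sc about the centre
      a <- c(cos(th), -sin(th), sin(th), cos(th)) / sc
      for (p in seq_len(d[3])) {
        out[, , p] <- cpp_warp_affine(out[, , p], a, tr, 0, TRUE)
      }
    }
    if (use_ric) {
      g1 <- array(rnorm(length(out), 0, policy$rician_sigma), d)
      g2 <- array(rnorm(length(out), 0, policy$rician_sigma), d)
      # normalized images can be negative; apply magnitude model on the shifted
      # positive scale then shift back so the zero-noise limit is the identity
      lo <- min(out)
      out <- sqrt((out - lo + g1)^2 + g2^2) + lo
    }
    if (use_gau) out <- out + array(rnorm(length(out), 0, policy$gaussian_sigma), d)
    phase_stack(out, normalized = stack$normalized, slice_index = stack$slice_index)
  })
}

#' Mosaic augmentation from four samples
#'
#' Composes one stack from the four quadrants of four source stacks (the
#' quadrant assignment is shuffled by the seed). All stacks must share
#' dimensions.
#'
#' @param stacks List of exactly four [phase_stack()] objects.
#' @param seed Integer seed.
#' @return A mosaic [phase_stack()].
#' @export
augment_mosaic <- function(stacks, seed = 1L) {
  assert_that(length(stacks) == 4, "mosaic needs exactly four stacks")
  d <- dim(stacks[[1]]$values)
  with_seed(seed, {
    ord <- sample(4)
    h2 <- d[1] %/% 2; w2 <- d[2] %/% 2
    out <- stacks[[ord[1]]]$values
    out[1:h2, (w2 + 1):d[2], ] <- stacks[[ord[2]]]$values[1:h2, (w2 + 1):d[2], ]
    out[(h2 + 1):d[1], 1:w2, ] <- stacks[[ord[3]]]$values[(h2 + 1):d[1], 1:w2, ]
    out[(h2 + 1):d[1], (w2 + 1):d[2], ] <- stacks[[ord[4]]]$values[(h2 + 1):d[1], (w2 + 1):d[2], ]
    phase_stack(out, normalized = stacks[[1]]$normalized)
  })
}

#' Preprocess one phantom sample into the canonical model input
#'
#' Z-score normalization with training statistics, ROI crop, bilinear resize
#' to `224 x 224` and phase-count adaptation to the canonical 5-phase grid.
#'
#' @param sample A `phantom_sample`.
#' @param stats A `norm_stats` fitted on the training split.
#' @param target_side Canonical spatial size.
#' @param canonical_T Canonical phase count.
#' @return A [phase_stack()] of shape `target_side x target_side x canonical_T`.
#' @export
preprocess_sample <- function(sample, stats, target_side = 224, canonical_T = 5) {
  st <- phase_stack(sample$phases)
  st <- znormalize(st, stats)
  st <- crop_and_resize(st, sample$roi, target_side)
  adapt_phase_count(st, canonical_T, times = sample$phase_times)
}
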
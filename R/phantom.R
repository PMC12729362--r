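#' Configuration for the synthetic DCE-MRI phantom cohort
#'
#' The phantom emulates axial key-slice stacks of a contrast-enhanced bladder:
#' a circular bladder wall annulus around a urine-filled lumen, with a
#' half-disc tumor seated on the inner wall. Each of the acquisition
#' time-points receives an intensity computed from a piecewise-linear wash-in
#' / exponential washout enhancement curve. The two classes share baseline
#' intensity and differ in wash-in slope, peak timing, washout rate and in how
#' deep the enhancing tumor signal extends radially into the wall annulus
#' (muscle invasion).
#'
#' @param n_patients Number of patients to simulate.
#' @param class_fraction_invasive Fraction of invasive (MIBC, label 1)
#'   patients, in (0,1). Default 0.26, matching the reported cohort balance.
#' @param image_size Pixels per side of the square pre-crop image.
#' @param n_phases Number of DCE acquisition time-points (default 5).
#' @param acquisition_times Seconds post-contrast of each phase.
#' @param kinetics_noninvasive,kinetics_invasive Lists with elements
#'   `washin_slope` (intensity/s), `peak_phase` (1-based index of the peak
#'   acquisition), `washout_rate` (1/s) and `invasion_depth` (fraction of the
#'   wall thickness reached by enhancing tumor signal).
#' @param subject_sd Log-normal between-subject spread of the wash-in slope.
#' @param rician_sigma,gaussian_sigma Noise scales in intensity units.
#' @param missing_phase_prob Probability that a patient lacks the 60 s phase
#'   (4 acquisitions instead of 5).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_patients = 200,
                           class_fraction_invasive = 0.26,
                           image_size = 256,
                           n_phases = 5,
                           acquisition_times = c(0, 30, 60, 90, 300),
                           kinetics_noninvasive = list(
                             washin_slope = 0.006, peak_phase = 4,
                             washout_rate = 3e-4, invasion_depth = 0.15),
                           kinetics_invasive = list(
                             washin_slope = 0.010, peak_phase = 3,
                             washout_rate = 8e-4, invasion_depth = 0.85),
                           subject_sd = 0.25,
                           rician_sigma = 0.02,
                           gaussian_sigma = 0.01,
                           missing_phase_prob = 0.05,
                           seed = 1L) {
  assert_that(n_patients >= 1, "n_patients must be positive")
  assert_that(class_fraction_invasive > 0 && class_fraction_invasive < 1,
              "class_fraction_invasive must lie in (0,1)")
  assert_that(n_phases >= 2, "n_phases must be at least 2")
  assert_that(rician_sigma >= 0 && gaussian_sigma >= 0,
              "noise scales must be nonnegative")
  assert_that(image_size >= 96, "image_size too small to contain the wall annulus")
  assert_that(length(acquisition_times) == n_phases,
              "acquisition_times must have one entry per phase")
  structure(list(
    n_patients = as.integer(n_patients),
    class_fraction_invasive = class_fraction_invasive,
    image_size = as.integer(image_size),
    n_phases = as.integer(n_phases),
    acquisition_times = acquisition_times,
    kinetics_noninvasive = kinetics_noninvasive,
    kinetics_invasive = kinetics_invasive,
    subject_sd = subject_sd,
    rician_sigma = rician_sigma,
    gaussian_sigma = gaussian_sigma,
    missing_phase_prob = missing_phase_prob,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Enhancement level at given times for a kinetics triple
#'
#' Piecewise model: linear wash-in from zero at `t = 0` up to the peak
#' acquisition time, then exponential washout.
#'
#' @param times Seconds post-contrast.
#' @param kin Kinetics list (see [phantom_config()]).
#' @param slope_multiplier Per-subject multiplier on the wash-in slope.
#' @param acquisition_times Full protocol times used to resolve `peak_phase`.
#' @return Enhancement values (same length as `times`).
#' @export
enhancement_curve <- function(times, kin, slope_multiplier = 1,
                              acquisition_times = c(0, 30, 60, 90, 300)) {
  t_peak <- acquisition_times[kin$peak_phase]
  slope <- kin$washin_slope * slope_multiplier
  peak <- slope * t_peak
  ifelse(times <= t_peak,
         slope * times,
         peak * exp(-kin$washout_rate * (times - t_peak)))
}

#' Add Rician noise to an intensity image
#'
#' Returns the magnitude of the complex signal `(image + g1) + i g2` where
#' `g1`, `g2` are independent zero-mean Gaussian fields of scale `sigma` --
#' the noise model of magnitude MR images. The output is nonnegative
#' everywhere; with `sigma = 0` it equals `abs(image)`.
#'
#' @param image Numeric array or matrix of intensities.
#' @param sigma Noise scale, `>= 0`.
#' @param seed Optional integer seed for reproducibility.
#' @return Array of the same shape.
#' @export
add_rician_noise <- function(image, sigma, seed = NULL) {
  assert_that(sigma >= 0, "sigma must be nonnegative")
  if (sigma == 0) return(abs(image))
  run <- function() {
    g1 <- rnorm(length(image), 0, sigma)
    g2 <- rnorm(length(image), 0, sigma)
    out <- sqrt((as.numeric(image) + g1)^2 + g2^2)
    array(out, dim = dim(image) %||% length(image))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Geometry + intensities for one patient; all randomness comes from the
# caller's RNG stream.
simulate_sample <- function(config, label, patient_id) {
  n <- config$image_size
  kin <- if (label == 1L) config$kinetics_invasive else config$kinetics_noninvasive
  times <- config$acquisition_times

  cx <- n / 2 + runif(1, -8, 8)
  cy <- n / 2 + runif(1, -8, 8)
  r_out <- runif(1, n * 0.25, n * 0.30)
  thick <- runif(1, n * 0.045, n * 0.07)
  r_in <- r_out - thick

  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  rr <- sqrt((ys - cy)^2 + (xs - cx)^2)
  ang <- atan2(ys - cy, xs - cx)

  lumen <- rr < r_in
  wall <- rr >= r_in & rr < r_out

  # tumor: half-disc seated on the inner wall at a random angle
  theta <- runif(1, -pi, pi)
  r_t <- runif(1, n * 0.04, n * 0.07)
  tx <- cx + r_in * cos(theta)
  ty <- cy + r_in * sin(theta)
  disc <- sqrt((ys - ty)^2 + (xs - tx)^2) < r_t
  tumor <- disc & lumen

  # invasion: sector of the wall annulus behind the tumor
  depth_px <- kin$invasion_depth * thick
  dang <- abs(((ang - theta + pi) %% (2 * pi)) - pi)
  half_width <- asin(min(0.95, r_t / r_in))
  invasion <- wall & rr < r_in + depth_px & dang < half_width

  slope_mult <- exp(rnorm(1, 0, config$subject_sd))
  enh <- enhancement_curve(times, kin, slope_mult, config$acquisition_times)
  wall_enh <- 0.15 * pmin(times, 300) / 300  # mild, class-independent

  base_bg <- 0.05; base_lumen <- 0.10; base_wall <- 0.30; base_tumor <- 0.35
  curve <- base_tumor + enh  # per-phase noise-free tumor intensity

  keep <- seq_len(config$n_phases)
  if (config$n_phases == 5 && runif(1) < config$missing_phase_prob) {
    keep <- keep[-3]  # the 60 s acquisition is the one that drops out
  }

  phases <- array(0, dim = c(n, n, length(keep)))
  for (j in seq_along(keep)) {
    p <- keep[j]
    img <- matrix(base_bg, n, n)
    img[lumen] <- base_lumen
    img[wall] <- base_wall + wall_enh[p]
    img[invasion] <- base_wall + wall_enh[p] + 0.9 * enh[p]
    img[tumor] <- curve[p]
    if (config$rician_sigma > 0) {
      g1 <- matrix(rnorm(n * n, 0, config$rician_sigma), n, n)
      g2 <- matrix(rnorm(n * n, 0, config$rician_sigma), n, n)
      img <- sqrt((img + g1)^2 + g2^2)
    }
    if (config$gaussian_sigma > 0) {
      img <- img + matrix(rnorm(n * n, 0, config$gaussian_sigma), n, n)
    }
    phases[, , j] <- img
  }

  margin <- 6 + round(runif(1, 0, 4))
  r0 <- max(0L, floor(cy - r_out) - margin)
  r1 <- min(n, ceiling(cy + r_out) + margin)
  c0 <- max(0L, floor(cx - r_out) - margin)
  c1 <- min(n, ceiling(cx + r_out) + margin)

  structure(list(
    patient_id = patient_id,
    phases = phases,
    tumor_mask = tumor,
    wall_mask = wall,
    invasion_mask = invasion,
    label = as.integer(label),
    roi = roi_box(r0, r1, c0, c1),
    n_phases_actual = length(keep),
    phase_times = times[keep],
    curve = curve[keep]
  ), class = "phantom_sample")
}

#' Simulate a seeded synthetic DCE-MRI cohort
#'
#' Generates `config$n_patients` phantom samples. The number of invasive
#' patients is `round(fraction * n)`; class assignment order is shuffled by
#' the seed. With both noise scales zero, the mean tumor-region intensity of
#' each phase equals the sample's stored noise-free enhancement `curve`
#' exactly.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_cohort`: list with `samples` (list of
#'   `phantom_sample`), `manifest` (tibble: patient_id, label, class,
#'   n_phases), and `config`.
#' @export
simulate_cohort <- function(config) {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  n <- config$n_patients
  n_inv <- round(config$class_fraction_invasive * n)
  with_seed(config$seed, {
    labels <- sample(c(rep(1L, n_inv), rep(0L, n - n_inv)))
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      samples[[i]] <- simulate_sample(config, labels[i], sprintf("P%04d", i))
    }
    manifest <- tibble::tibble(
      patient_id = vapply(samples, `[[`, "", "patient_id"),
      label = vapply(samples, `[[`, 0L, "label"),
      class = ifelse(labels == 1L, "invasive", "noninvasive"),
      n_phases = vapply(samples, `[[`, 0L, "n_phases_actual")
    )
    structure(list(samples = samples, manifest = manifest, config = config),
              class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d patients (%d invasive), %dx%d px, seed %d\n",
              nrow(x$manifest), sum(x$manifest$label), x$config$image_size,
              x$config$image_size, x$config$seed))
  invisible(x)
}

#' Mean tumor-region intensity per phase
#'
#' @param sample A `phantom_sample`.
#' @return Numeric vector, one mean per acquired phase.
#' @export
tumor_phase_means <- function(sample) {
  apply(sample$phases, 3, function(m) mean(m[sample$tumor_mask]))
}

#' Write a phantom cohort to NIfTI volumes plus a manifest CSV
#'
#' Phases are stacked on the third axis of each patient's image volume; tumor
#' and wall masks are written as separate NIfTI files. The manifest records
#' file paths, labels and phase counts.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble with path columns added.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- lapply(cohort$samples, function(s) {
    img <- file.path(dir, paste0(s$patient_id, "_phases.nii.gz"))
    tmk <- file.path(dir, paste0(s$patient_id, "_tumor.nii.gz"))
    wmk <- file.path(dir, paste0(s$patient_id, "_wall.nii.gz"))
    RNifti::writeNifti(s$phases, img)
    RNifti::writeNifti(array(as.numeric(s$tumor_mask), dim(s$tumor_mask)), tmk)
    RNifti::writeNifti(array(as.numeric(s$wall_mask), dim(s$wall_mask)), wmk)
    c(img = img, tumor = tmk, wall = wmk)
  })
  manifest <- dplyr::mutate(cohort$manifest,
    image_path = vapply(paths, `[[`, "", "img"),
    tumor_mask_path = vapply(paths, `[[`, "", "tumor"),
    wall_mask_path = vapply(paths, `[[`, "", "wall"),
    roi_row_start = vapply(cohort$samples, function(s) s$roi$row_start, 0),
    roi_row_stop = vapply(cohort$samples, function(s) s$roi$row_stop, 0),
    roi_col_start = vapply(cohort$samples, function(s) s$roi$col_start, 0),
    roi_col_stop = vapply(cohort$samples, function(s) s$roi$col_stop, 0))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
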
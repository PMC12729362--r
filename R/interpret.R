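#' Gradient-weighted class activation maps, one per DCE phase
#'
#' Backpropagates the class score (the logit for the invasive class, its
#' negation for the non-invasive class) to the layer-1 ReLU activations of a
#' chosen convolution branch -- the last point at which the feature map still
#' has the full 5-phase temporal extent. For each phase, channel weights are
#' the spatially averaged gradients; the weighted activation map is ReLU
#' rectified, bilinearly upsampled to the input resolution and min-max
#' normalized to `[0, 1]` (a constant map yields all zeros, not NaN).
#'
#' @param model A `dce_model` or `dce_fit`.
#' @param x `H x W x T` input array or [phase_stack()].
#' @param target_branch Branch index (default 2, the mid-scale k = 3 branch).
#' @param class_index Class whose evidence is mapped (1 = invasive).
#' @param normalize `"per_phase"` (default) or `"global"` min-max scaling.
#' @return A `saliency_maps` object: list of `H x W` heatmaps (one per
#'   phase), plus the predicted probability.
#' @export
grad_cam <- function(model, x, target_branch = 2L, class_index = 1L,
                     normalize = c("per_phase", "global")) {
  normalize <- match.arg(normalize)
  if (inherits(model, "dce_fit")) model <- model$model
  assert_that(model$config$variant %in% c("full", "mhmc_only"),
              "grad_cam requires a model with convolution branches")
  if (inherits(x, "phase_stack")) x <- x$values
  d <- dim(x)
  fw <- model_forward(model, x, keep_cache = TRUE)
  dlogit <- if (class_index == 1L) 1 else -1
  bk <- model_backward(model, fw$cache, dlogit,
                       capture_branch = as.integer(target_branch))
  A <- fw$cache$mhmc[[target_branch]]$a1$out   # (n_vox x C), dims = input
  dA <- bk$dact1
  n_hw <- d[1] * d[2]
  maps <- vector("list", d[3])
  for (t in seq_len(d[3])) {
    rows <- ((t - 1) * n_hw + 1):(t * n_hw)
    alpha <- colMeans(dA[rows, , drop = FALSE])
    m <- matrix(A[rows, , drop = FALSE] %*% alpha, d[1], d[2])
    maps[[t]] <- pmax(m, 0)
  }
  norm01 <- function(m, lo, hi) {
    if (hi - lo <= 0) matrix(0, nrow(m), ncol(m)) else (m - lo) / (hi - lo)
  }
  if (normalize == "per_phase") {
    maps <- lapply(maps, function(m) norm01(m, min(m), max(m)))
  } else {
    lo <- min(vapply(maps, min, 0)); hi <- max(vapply(maps, max, 0))
    maps <- lapply(maps, norm01, lo = lo, hi = hi)
  }
  structure(list(maps = maps, prob = fw$prob,
                 target_branch = as.integer(target_branch),
                 class_index = as.integer(class_index)),
            class = "saliency_maps")
}

#' @export
print.saliency_maps <- function(x, ...) {
  cat(sprintf("saliency_maps: %d phases, branch %d, class %d, prob %.3f\n",
              length(x$maps), x$target_branch, x$class_index, x$prob))
  invisible(x)
}

# Simple deterministic heat palette (black-red-yellow-white), values in [0,1].
heat_rgb <- function(v) {
  r <- pmin(1, 3 * v)
  g <- pmin(1, pmax(0, 3 * v - 1))
  b <- pmin(1, pmax(0, 3 * v - 2))
  list(r = r, g = g, b = b)
}

#' Overlay a saliency heatmap on a grayscale phase image
#'
#' Alpha-blends the color-mapped heatmap onto the (min-max scaled) grayscale
#' image. `alpha = 0` returns the grayscale image; `alpha = 1` the pure
#' colormap. Deterministic: fixed inputs give byte-identical PNG output via
#' [write_overlay_png()].
#'
#' @param map `H x W` heatmap in `[0, 1]` (or one element of
#'   [grad_cam()]'s output).
#' @param image `H x W` grayscale phase image.
#' @param alpha Blend weight of the heatmap.
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
overlay <- function(map, image, alpha = 0.5) {
  assert_that(identical(dim(map), dim(image)), "map and image shapes differ")
  lo <- min(image); hi <- max(image)
  g <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  hm <- heat_rgb(map)
  out <- array(0, dim = c(dim(map), 3))
  out[, , 1] <- (1 - alpha) * g + alpha * hm$r
  out[, , 2] <- (1 - alpha) * g + alpha * hm$g
  out[, , 3] <- (1 - alpha) * g + alpha * hm$b
  out
}

#' Write an overlay (or panel of overlays) to PNG
#'
#' @param rgb `H x W x 3` array in `[0, 1]`, e.g. from [overlay()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_overlay_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Plot per-phase saliency maps
#'
#' @param object A `saliency_maps` object.
#' @param ... Unused.
#' @return A ggplot with one facet per phase.
#' @method autoplot saliency_maps
#' @export
autoplot.saliency_maps <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(seq_along(object$maps), function(t) {
    m <- object$maps[[t]]
    tibble::tibble(
      phase = paste("phase", t),
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.numeric(m))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~phase, nrow = 1) +
    ggplot2::scale_fill_gradientn(colours = c("black", "red", "yellow", "white")) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "attention") +
    ggplot2::theme_void()
}
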
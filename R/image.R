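#' Grayscale image stack with acquisition metadata
#'
#' A lightweight container for an ordered set of grayscale frames sharing
#' one shape, the inter-frame interval, the pixel scale and a rectangular
#' region of interest (ROI).
#'
#' @param frames A list of numeric matrices (or a single matrix), all of the
#'   same dimension, gray levels in native 8- or 16-bit units.
#' @param dt Inter-frame interval (s).
#' @param pixel_size Pixel scale (um/pixel).
#' @param roi Optional ROI as `c(row, col, height, width)` (1-based offsets),
#'   default 240 x 200 pixels anchored at the top-left corner, clipped to
#'   the frame.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, dt = 0.5, pixel_size = 1, roi = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames)) abort("`frames` must contain at least one frame.")
  dims <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), dims),
               logical(1))
  if (!all(ok)) abort("all frames must be matrices of one common shape.")
  check_positive(dt, "dt"); check_positive(pixel_size, "pixel_size")
  if (is.null(roi)) {
    roi <- c(1, 1, min(240L, dims[1]), min(200L, dims[2]))
  }
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] < 1 || roi[2] < 1 ||
      roi[1] + roi[3] - 1 > dims[1] || roi[2] + roi[4] - 1 > dims[2]) {
    abort("`roi` = c(row, col, height, width) must lie inside the frame.")
  }
  structure(list(frames = frames, dt = dt, pixel_size = pixel_size, roi = roi),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px, dt = %g s, %g um/px, ROI [%d,%d,%d,%d]\n",
              length(x$frames), d[1], d[2], x$dt, x$pixel_size,
              x$roi[1], x$roi[2], x$roi[3], x$roi[4]))
  invisible(x)
}

#' Read / write multi-page TIFF stacks
#'
#' Thin wrappers over the tiff package that attach acquisition metadata.
#' Gray levels are rescaled to the native 8-bit range on read.
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return [read_tiff_stack()] returns an [image_stack()].
#' @export
read_tiff_stack <- function(path, dt = 0.5, pixel_size = 1, roi = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop color planes if present
    p * 255
  })
  image_stack(frames, dt = dt, pixel_size = pixel_size, roi = roi)
}

#' @rdname read_tiff_stack
#' @param stack An [image_stack()] to write; gray levels are assumed 8-bit.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(f) pmin(pmax(f / 255, 0), 1)),
                  path)
  invisible(path)
}

roi_crop <- function(frame, roi) {
  frame[roi[1]:(roi[1] + roi[3] - 1), roi[2]:(roi[2] + roi[4] - 1), drop = FALSE]
}

## Otsu threshold on native gray levels, plus the between-class variance at
## the chosen threshold (normalized units^2) used as a bimodality score.
otsu_threshold <- function(mat) {
  rng <- if (max(mat) > 255) 65535 else 255
  x <- pmin(pmax(mat / rng, 0), 1)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256L)
  w1 <- mean(x <= th)
  w2 <- 1 - w1
  bcv <- if (w1 == 0 || w2 == 0) 0 else
    w1 * w2 * (mean(x[x > th]) - mean(x[x <= th]))^2
  list(threshold = th * rng, between_class_var = bcv, range = rng)
}

#' Interface fraction from a single co-flow frame
#'
#' Binarizes the ROI at the Otsu threshold, removes isolated misclassified
#' pixels with a single 3 x 3 morphological opening, and measures the
#' blood-filled width as the contiguous run of blood-class pixels from the
#' blood-inlet wall, averaged along the channel (rows). The interface
#' fraction is `alpha = W_B / W_roi`.
#'
#' @param frame A numeric gray-level matrix (rows along the channel, columns
#'   across it).
#' @param roi ROI `c(row, col, height, width)`; `NULL` uses the full frame.
#' @param blood_side Which ROI side touches the blood inlet: `"left"`
#'   (default) or `"right"`.
#' @param blood_dark Is blood the darker phase? Default `TRUE` (bright-field
#'   imaging).
#' @param min_bcv Floor on the between-class variance (normalized units^2)
#'   below which the ROI is declared low-contrast. Default 1e-3.
#' @return `alpha` (scalar), with attribute `W_B_px`.
#' @examples
#' f <- matrix(200, 50, 200); f[, 1:130] <- 40
#' interface_from_frame(f) # 0.65
#' @export
interface_from_frame <- function(frame, roi = NULL, blood_side = c("left", "right"),
                                 blood_dark = TRUE, min_bcv = 1e-3) {
  blood_side <- match.arg(blood_side)
  if (!is.matrix(frame) || !is.numeric(frame)) abort("`frame` must be a numeric matrix.")
  if (!is.null(roi)) frame <- roi_crop(frame, as.integer(roi))

  if (diff(range(frame)) < .Machine$double.eps^0.5) {
    warn("ROI has a single gray level; no interface detected, treating as no blood.")
    return(structure(0, W_B_px = 0))
  }
  ot <- otsu_threshold(frame)
  if (ot$between_class_var < min_bcv) {
    abort(sprintf(
      "low-contrast ROI: between-class variance %.2g below the floor %.2g; no bimodal interface.",
      ot$between_class_var, min_bcv))
  }
  mask <- if (blood_dark) frame < ot$threshold else frame >= ot$threshold
  mask <- EBImage::opening(mask, EBImage::makeBrush(3L, shape = "box")) > 0

  if (blood_side == "right") mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  ## run length of blood-class pixels from the inlet-side wall, per row
  runs <- apply(mask, 1L, function(r) {
    first_gap <- match(FALSE, r)
    if (is.na(first_gap)) length(r) else first_gap - 1L
  })
  w_b <- mean(runs)
  alpha <- w_b / ncol(mask)
  if (alpha == 0) warn("no blood-class pixels at the inlet wall; alpha = 0.")
  structure(alpha, W_B_px = w_b)
}

#' Interface trace from an image stack
#'
#' Applies [interface_from_frame()] to every frame and returns the
#' time-resolved interface fraction together with its linearizing transform
#' and the blood-filled width in micrometres.
#'
#' @param stack An [image_stack()].
#' @param W_um Channel width used to convert `alpha` to `W_B` (um); defaults
#'   to the ROI width times the pixel scale.
#' @inheritParams interface_from_frame
#' @return A `coflow_trace` tibble with columns `time_s`, `alpha`, `beta`,
#'   `W_B_um`.
#' @export
interface_trace <- function(stack, blood_side = "left", blood_dark = TRUE,
                            W_um = NULL, min_bcv = 1e-3) {
  stopifnot(inherits(stack, "image_stack"))
  W_um <- W_um %||% (stack$roi[4] * stack$pixel_size)
  alpha <- vapply(stack$frames, function(f) {
    as.numeric(interface_from_frame(f, roi = stack$roi, blood_side = blood_side,
                                    blood_dark = blood_dark, min_bcv = min_bcv))
  }, numeric(1))
  new_coflow_trace(tibble(
    time_s = (seq_along(alpha) - 1) * stack$dt,
    alpha = alpha,
    beta = 1 / (1 - alpha),
    W_B_um = alpha * W_um
  ))
}

#' ROI-averaged intensity trace
#'
#' Per-frame arithmetic mean of the ROI pixels, timestamped on the frame
#' grid (`t = k * dt`, `k = 0, 1, ...`).
#'
#' @param stack An [image_stack()].
#' @param roi Optional ROI override, `c(row, col, height, width)`.
#' @return A tibble with columns `time_s`, `I_mean`.
#' @export
intensity_trace <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  roi <- if (is.null(roi)) stack$roi else as.integer(roi)
  I <- vapply(stack$frames, function(f) mean(roi_crop(f, roi)), numeric(1))
  tibble(time_s = (seq_along(I) - 1) * stack$dt, I_mean = I)
}

#' Measure the channel width from a filled-channel frame
#'
#' Otsu-binarizes the frame, takes the channel phase (dark by default, i.e.
#' a blood-filled channel against a bright background), finds the two wall
#' crossings of each cross-channel profile, and averages the wall-to-wall
#' distance along the channel.
#'
#' @param frame Numeric gray-level matrix (rows along the channel).
#' @param pixel_size Pixel scale (um/pixel).
#' @param channel_dark Is the channel the darker phase? Default `TRUE`.
#' @return Width in micrometres, with attribute `width_px`.
#' @export
channel_width <- function(frame, pixel_size = 1, channel_dark = TRUE) {
  if (!is.matrix(frame)) abort("`frame` must be a numeric matrix.")
  if (diff(range(frame)) < .Machine$double.eps^0.5) {
    abort("uniform frame: no channel walls detected.")
  }
  ot <- otsu_threshold(frame)
  mask <- if (channel_dark) frame < ot$threshold else frame >= ot$threshold
  widths <- apply(mask, 1L, function(r) {
    idx <- which(r)
    if (length(idx) == 0L) return(NA_real_)
    if (idx[1] == 1L && idx[length(idx)] == length(r)) return(NA_real_)
    idx[length(idx)] - idx[1] + 1
  })
  if (all(is.na(widths))) {
    abort("fewer than two wall crossings in every profile: channel walls not inside the frame.")
  }
  w_px <- mean(widths, na.rm = TRUE)
  structure(w_px * pixel_size, width_px = w_px)
}
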
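# Reinhard colour transfer in the l-alpha-beta space: RGB -> LMS -> log10 ->
# decorrelated l,alpha,beta; per-channel linear moment matching; inverse chain
# back to RGB. Matrices follow Reinhard's original colour-transfer method.

.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)
.lab_eps <- 1e-4  # floor on LMS before log; keeps pure black finite

#' Convert an RGB raster to l-alpha-beta space
#'
#' @param pixels `H x W x 3` RGB array on the unit scale.
#' @return `H x W x 3` array of l, alpha, beta channels.
#' @export
rgb_to_lab <- function(pixels) {
  d <- dim(pixels)
  array(rgb_to_lab_m(matrix(pixels, ncol = 3L)), dim = d)
}

# flat-matrix (n x 3) variants used on hot paths to avoid array copies
rgb_to_lab_m <- function(m) {
  lms <- m %*% t(.rgb2lms)
  lms[lms < .lab_eps] <- .lab_eps
  log10(lms) %*% t(.lms2lab)
}

lab_to_rgb_m <- function(m) {
  lms <- 10 ^ (m %*% t(.lab2lms))
  rgb <- lms %*% t(.lms2rgb)
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1
  rgb
}

#' @rdname rgb_to_lab
#' @param lab `H x W x 3` l-alpha-beta array.
#' @return `lab_to_rgb`: RGB array clipped to `[0, 1]`.
#' @export
lab_to_rgb <- function(lab) {
  d <- dim(lab)
  array(lab_to_rgb_m(matrix(lab, ncol = 3L)), dim = d)
}

#' Per-channel colour statistics in l-alpha-beta space
#'
#' Computed over tissue pixels only when a mask is supplied, so that white
#' background does not dominate the moments.
#'
#' @param image RGB raster (`H x W x 3`, unit scale or 8-bit).
#' @param tissue_mask optional `H x W` logical; when given at least 100 pixels
#'   must be selected.
#' @return a `channel_stats` object: list with `space = "lab"`, `mean` and
#'   `sd` 3-vectors.
#' @export
compute_channel_stats <- function(image, tissue_mask = NULL) {
  if (max(image) > 1 + 1e-9) image <- image / 255
  lab <- rgb_to_lab(image)
  m <- matrix(lab, ncol = 3L)
  if (!is.null(tissue_mask)) {
    sel <- as.vector(tissue_mask)
    if (sum(sel) < 100L)
      stop("tissue mask selects fewer than 100 pixels")
    m <- m[sel, , drop = FALSE]
  }
  lab_matrix_stats(m)
}

# mean/sd per column of an n x 3 lab matrix (single pass, no apply)
lab_matrix_stats <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sdv <- sqrt(pmax(colSums(m * m) / n - mu^2, 0) * n / (n - 1))
  if (any(sdv == 0)) stop("zero variance channel")
  channel_stats(mu, sdv)
}

#' @rdname compute_channel_stats
#' @param mean,sd numeric 3-vectors.
#' @param space colour space tag, only `"lab"` supported.
#' @export
channel_stats <- function(mean, sd, space = "lab") {
  if (space != "lab") stop("unsupported colour space: ", space)
  if (length(mean) != 3L || length(sd) != 3L)
    stop("mean and sd must be 3-vectors")
  if (any(sd <= 0)) stop("sd components must be positive")
  structure(list(space = "lab", mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat(sprintf("<channel_stats lab> mean=(%.3f, %.3f, %.3f) sd=(%.3f, %.3f, %.3f)\n",
              x$mean[1], x$mean[2], x$mean[3], x$sd[1], x$sd[2], x$sd[3]))
  invisible(x)
}

#' Reinhard normalization of an image to target colour statistics
#'
#' Each l-alpha-beta channel `c` is mapped linearly,
#' `out = (in - source_mean_c) * target_sd_c / source_sd_c + target_mean_c`,
#' then converted back to RGB and clipped to the unit range. When `source`
#' equals the image's own statistics, the (pre-clipping) output statistics
#' equal the target's.
#'
#' @param image RGB raster on the unit scale (8-bit accepted).
#' @param source `channel_stats` of the image (typically of its slide).
#' @param target reference `channel_stats`.
#' @return normalized RGB raster in `[0, 1]`.
#' @export
reinhard_normalize <- function(image, source, target) {
  stopifnot(inherits(source, "channel_stats"), inherits(target, "channel_stats"))
  if (any(source$sd == 0)) stop("source sd contains 0")
  if (max(image) > 1 + 1e-9) image <- image / 255
  d <- dim(image)
  m <- rgb_to_lab_m(matrix(image, ncol = 3L))
  scale <- target$sd / source$sd
  for (ch in 1:3)
    m[, ch] <- (m[, ch] - source$mean[ch]) * scale[ch] + target$mean[ch]
  array(lab_to_rgb_m(m), dim = d)
}

#' Scale an 8-bit raster to the unit range
#'
#' Exactly `value / 255`; the inverse (`round(x * 255)`) recovers the input.
#'
#' @param image integer array with values in `0..255`.
#' @return numeric array in `[0, 1]`.
#' @export
to_unit_range <- function(image) {
  if (min(image) < 0 || max(image) > 255)
    stop("8-bit input expected (values in 0..255)")
  image / 255
}

#' Tissue mask of a slide (non-white pixels)
#'
#' @param pixels RGB raster on the unit scale.
#' @param white_level unit-scale white threshold.
#' @return `H x W` logical, `TRUE` on tissue.
#' @export
tissue_mask <- function(pixels, white_level = 0.94) {
  if (max(pixels) > 1 + 1e-9) pixels <- pixels / 255
  !((pixels[, , 1] >= white_level) & (pixels[, , 2] >= white_level) &
    (pixels[, , 3] >= white_level))
}
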
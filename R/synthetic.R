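# Seeded virtual-biopsy generator. A slide is a white canvas carrying a few
# disjoint tissue fragments; each fragment contains a tumour subregion whose
# texture identifies the class (S: coarse keratin-like speckle; NS: smooth
# gland/ring pattern), surrounded by stroma texture common to both classes.
# One GeoJSON polygon is emitted per tumour region. Texture families are
# chosen for learnability by a small CNN, not biological realism; all texture
# parameters live in .texture_params below.

.texture_params <- list(
  stroma_rgb  = c(0.90, 0.78, 0.86),
  stroma_amp  = 0.04, stroma_scale = 32L,
  ns_rgb      = c(0.80, 0.60, 0.80),
  ns_amp      = 0.10, ns_wavelength = 64,
  s_rgb       = c(0.78, 0.52, 0.64),
  s_amp       = 0.18, s_block = 8L,
  fragment_wobble = 0.18, n_vertices = 72L
)

# Run code under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic virtual-biopsy slide
#'
#' Defaults describe the stated world of the package's synthetic cohorts:
#' 2200 px square slides (a 10 x 10 grid of 220 px tiles) at 0.5 um/px, one
#' biopsy fragment whose tumour subregion sits off-centre and occupies 30%
#' of the tissue (biopsies carry little tumour relative to tissue), mild
#' pixel noise.
#'
#' @param slide_id character scalar.
#' @param true_class `"NS"` or `"S"`.
#' @param width_px,height_px canvas size; at least `3 * 220` so a 3 x 3 tile
#'   grid exists.
#' @param microns_per_pixel physical scale (default 0.5).
#' @param n_fragments number of disjoint tissue fragments.
#' @param tumour_fraction tumour area as a fraction of tissue area, in (0, 1].
#' @param stain_shift length-3 per-channel RGB offsets in `[-0.2, 0.2]` added
#'   to tissue pixels.
#' @param noise_sd per-pixel Gaussian noise sd on tissue (unit scale).
#' @param seed integer; the same spec and seed give bit-identical output.
#' @return object of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(slide_id = "synthetic", true_class = "NS",
                                 width_px = 2200L, height_px = 2200L,
                                 microns_per_pixel = 0.5, n_fragments = 1L,
                                 tumour_fraction = 0.3,
                                 stain_shift = c(0, 0, 0),
                                 noise_sd = 0.02, seed = 1L) {
  true_class <- match.arg(true_class, c("NS", "S"))
  if (!is.numeric(width_px) || width_px < 3L * 220L)
    stop("width_px must be at least 660 (a 3 x 3 tile grid)")
  if (!is.numeric(height_px) || height_px < 3L * 220L)
    stop("height_px must be at least 660 (a 3 x 3 tile grid)")
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be positive")
  if (n_fragments < 1L) stop("n_fragments must be a positive integer")
  if (tumour_fraction <= 0 || tumour_fraction > 1)
    stop("tumour_fraction must lie in (0, 1]")
  if (length(stain_shift) != 3L || any(abs(stain_shift) > 0.2))
    stop("stain_shift must be 3 per-channel offsets in [-0.2, 0.2]")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(slide_id = slide_id, true_class = true_class,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_pixel = microns_per_pixel,
                 n_fragments = as.integer(n_fragments),
                 tumour_fraction = tumour_fraction,
                 stain_shift = as.numeric(stain_shift),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

# Even-odd scanline rasterization of a polygon (open ring, pixel
# coordinates) onto the h x w canvas; pixel centers at (col+0.5, row+0.5),
# 0-based coordinates.
rasterize_polygon <- function(poly, h, w) {
  xs <- poly[, 1]; ys <- poly[, 2]
  xn <- c(xs[-1], xs[1]); yn <- c(ys[-1], ys[1])
  mask <- matrix(FALSE, h, w)
  y_lo <- max(0L, floor(min(ys))); y_hi <- min(h - 1L, ceiling(max(ys)))
  if (y_hi < y_lo) return(mask)
  for (row in y_lo:y_hi) {
    yc <- row + 0.5
    hit <- (ys > yc) != (yn > yc)
    if (!any(hit)) next
    xc <- sort(xs[hit] + (yc - ys[hit]) * (xn[hit] - xs[hit]) /
                 (yn[hit] - ys[hit]))
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      j0 <- max(0L, ceiling(xc[k] - 0.5))
      j1 <- min(w - 1L, ceiling(xc[k + 1L] - 0.5) - 1L)
      if (j1 >= j0) mask[row + 1L, (j0 + 1L):(j1 + 1L)] <- TRUE
    }
  }
  mask
}

# Smooth value noise: coarse iid uniform(-1,1) grid, bilinear upsampling.
# The coarse grid is drawn regardless of `idx`, so the field (and the RNG
# stream) is independent of where it is evaluated; with `idx` the field is
# returned only at those linear canvas indices.
value_noise <- function(h, w, scale, idx = NULL) {
  gh <- ceiling(h / scale) + 1L
  gw <- ceiling(w / scale) + 1L
  g <- matrix(runif(gh * gw, -1, 1), gh, gw)
  if (is.null(idx)) idx <- seq_len(h * w)
  py <- (idx - 1L) %% h
  px <- (idx - 1L) %/% h
  yy <- py / scale; xx <- px / scale
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  base_i <- y0 + 1 + x0 * gh                   # linear index of (y0+1, x0+1)
  (g[base_i] * (1 - fx) + g[base_i + gh] * fx) * (1 - fy) +
    (g[base_i + 1L] * (1 - fx) + g[base_i + gh + 1L] * fx) * fy
}

# Blocky speckle: coarse iid uniform(-1,1), nearest-neighbour upsampling.
block_noise <- function(h, w, block, idx = NULL) {
  gh <- ceiling(h / block); gw <- ceiling(w / block)
  g <- matrix(runif(gh * gw, -1, 1), gh, gw)
  if (is.null(idx)) idx <- seq_len(h * w)
  ri <- (idx - 1L) %% h %/% block + 1L
  ci <- (idx - 1L) %/% h %/% block
  g[ri + ci * gh]
}

# A wobbly closed blob: radius R modulated by a few random low harmonics.
fragment_polygon <- function(cx, cy, R, n_vertices, wobble) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  s <- rep(0, n_vertices)
  for (k in 2:5) s <- s + rnorm(1, 0, 0.5 / k) * cos(k * theta + runif(1, 0, 2 * pi))
  s <- s / max(1, max(abs(s)) / 1)          # bounded harmonics
  r <- R * (1 + wobble * s)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

#' Generate one synthetic slide with annotations
#'
#' @param spec a [synthetic_slide_spec()].
#' @return list with `slide` (a [slide_image()]), `annotations` (list of open
#'   `n x 2` polygon rings, one per tumour region, pixel coordinates), and
#'   `masks` (list of logical `tissue` and `tumour` rasters, mainly for
#'   testing).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  tp <- .texture_params
  h <- spec$height_px; w <- spec$width_px
  with_seed(spec$seed, {
    img <- array(1, dim = c(h, w, 3L))   # white canvas
    tissue <- matrix(FALSE, h, w)
    tumour <- matrix(FALSE, h, w)
    annotations <- list()

    # fragment layout: one cell per fragment on a near-square grid
    k <- ceiling(sqrt(spec$n_fragments))
    rows_n <- ceiling(spec$n_fragments / k)
    cell_w <- w / k; cell_h <- h / rows_n
    for (f in seq_len(spec$n_fragments)) {
      ci <- (f - 1L) %% k; ri <- (f - 1L) %/% k
      cx <- (ci + 0.5) * cell_w + runif(1, -0.03, 0.03) * cell_w
      cy <- (ri + 0.5) * cell_h + runif(1, -0.03, 0.03) * cell_h
      # 0.38 * cell with <= 18% wobble keeps fragments disjoint and in bounds
      R <- 0.38 * min(cell_w, cell_h) * runif(1, 0.9, 1)
      frag <- fragment_polygon(cx, cy, R, tp$n_vertices, tp$fragment_wobble)
      fmask <- rasterize_polygon(frag, h, w)
      tissue <- tissue | fmask

      # tumour subregion: the fragment ring scaled by sqrt(tumour_fraction)
      # (area ratio exact) and shifted off-centre, as in a biopsy where the
      # tumour sits to one side of the tissue core
      cen <- polygon_centroid_xy(frag)
      sc <- sqrt(spec$tumour_fraction)
      r_min <- min(sqrt((frag[, 1] - cen[1])^2 + (frag[, 2] - cen[2])^2))
      phi <- runif(1, 0, 2 * pi)
      delta <- 0.8 * (1 - sc) * r_min
      tpoly <- cbind(cen[1] + sc * (frag[, 1] - cen[1]) + delta * cos(phi),
                     cen[2] + sc * (frag[, 2] - cen[2]) + delta * sin(phi))
      tmask <- if (spec$tumour_fraction == 1) fmask else
        rasterize_polygon(tpoly, h, w)
      tumour <- tumour | tmask
      tissue <- tissue | tmask    # guard against sub-pixel overhang
      annotations[[f]] <- tpoly
    }

    # masked writes by linear index: channel ch of pixel i sits at
    # i + (ch-1)*h*w in the flat canvas
    npix <- h * w
    i_str <- which(tissue & !tumour)
    i_tum <- which(tumour)
    i_tis <- which(tissue)

    # stroma: light pink with smooth fibrous modulation
    fib <- value_noise(h, w, tp$stroma_scale, i_str) * tp$stroma_amp
    for (ch in 1:3)
      img[i_str + (ch - 1L) * npix] <- tp$stroma_rgb[ch] + fib

    # tumour texture by class
    if (length(i_tum)) {
      if (spec$true_class == "S") {
        spk <- block_noise(h, w, tp$s_block, i_tum) * tp$s_amp
        for (ch in 1:3)
          img[i_tum + (ch - 1L) * npix] <- tp$s_rgb[ch] + spk
      } else {
        # gland/ring pattern: sinusoid in distance to the nearest gland seed
        ty <- (i_tum - 1L) %% h
        tx <- (i_tum - 1L) %/% h
        n_gl <- max(3L, round(length(i_tum) / 100000))
        pick <- sample.int(length(i_tum), n_gl)
        d2 <- rep(Inf, length(i_tum))
        for (g in seq_len(n_gl)) {
          dd <- (ty - ty[pick[g]])^2 + (tx - tx[pick[g]])^2
          lt <- dd < d2
          d2[lt] <- dd[lt]
        }
        ring <- tp$ns_amp * sin(2 * pi * sqrt(d2) / tp$ns_wavelength)
        for (ch in 1:3)
          img[i_tum + (ch - 1L) * npix] <- tp$ns_rgb[ch] + ring
      }
    }

    # stain shift and pixel noise on tissue only, then clip and quantize
    for (ch in 1:3) {
      j <- i_tis + (ch - 1L) * npix
      img[j] <- img[j] + spec$stain_shift[ch]
      if (spec$noise_sd > 0)
        img[j] <- img[j] + rnorm(length(j), 0, spec$noise_sd)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    img <- round(img * 255) / 255

    list(slide = slide_image(img, spec$slide_id, spec$microns_per_pixel,
                             spec$true_class),
         annotations = annotations,
         masks = list(tissue = tissue, tumour = tumour))
  })
}

#' Generate a balanced synthetic cohort on disk
#'
#' Writes `2 * n_per_class` slides (PPM), one GeoJSON annotation file per
#' slide, and a manifest TSV (`slide_id path class annotation_path`). The
#' template's `stain_shift` is interpreted as a per-channel half-range: each
#' slide draws its own shift uniformly from `[-range, range]` to exercise
#' colour normalization. Per-slide seeds derive deterministically from
#' `seed`.
#'
#' @param n_per_class slides per class (>= 1).
#' @param out_dir output directory (created if needed).
#' @param template a [synthetic_slide_spec()] supplying geometry defaults;
#'   default template uses `stain_shift = c(0.12, 0.12, 0.12)` as range.
#' @param seed cohort seed.
#' @return path of the manifest TSV, invisibly; the manifest itself as a
#'   `data.table` attribute-free return value.
#' @export
generate_cohort <- function(n_per_class, out_dir,
                            template = synthetic_slide_spec(
                              stain_shift = c(0.12, 0.12, 0.12)),
                            seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  shift_range <- abs(template$stain_shift)
  classes <- rep(c("NS", "S"), each = n_per_class)
  ids <- sprintf("%s_%03d", classes, rep(seq_len(n_per_class), times = 2L))
  draws <- with_seed(seed, list(
    slide_seeds = sample.int(.Machine$integer.max %/% 2L, length(ids)),
    shifts = matrix(runif(3L * length(ids), -1, 1), ncol = 3L)))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    spec <- synthetic_slide_spec(
      slide_id = ids[i], true_class = classes[i],
      width_px = template$width_px, height_px = template$height_px,
      microns_per_pixel = template$microns_per_pixel,
      n_fragments = template$n_fragments,
      tumour_fraction = template$tumour_fraction,
      stain_shift = draws$shifts[i, ] * shift_range,
      noise_sd = template$noise_sd,
      seed = draws$slide_seeds[i])
    out <- generate_slide(spec)
    img_path <- file.path(out_dir, paste0(ids[i], ".ppm"))
    ann_path <- file.path(out_dir, paste0(ids[i], ".geojson"))
    write_ppm(out$slide$pixels, img_path)
    write_annotations(out$annotations, ann_path, slide_id = ids[i])
    rows[[i]] <- data.table::data.table(
      slide_id = ids[i], path = paste0(ids[i], ".ppm"),
      class = classes[i], annotation_path = paste0(ids[i], ".geojson"))
  }
  manifest <- data.table::rbindlist(rows)
  mpath <- file.path(out_dir, "manifest.tsv")
  write_manifest(manifest, mpath)
  invisible(mpath)
}

#' Load a slide named by a manifest row
#'
#' @param manifest_row one row of [read_manifest()] output.
#' @param microns_per_pixel physical scale to attach.
#' @return a [slide_image()].
#' @export
load_slide <- function(manifest_row, microns_per_pixel = 0.5) {
  slide_image(read_ppm(manifest_row$path), manifest_row$slide_id,
              microns_per_pixel, manifest_row$class)
}

#' Texture statistic used for class-separability checks
#'
#' Mean absolute difference between horizontally and vertically adjacent
#' pixels of the green channel — a fixed, implementation-independent summary
#' of local texture energy.
#'
#' @param tile_pixels `t x t x 3` array, unit scale.
#' @return nonnegative scalar.
#' @export
texture_stat <- function(tile_pixels) {
  g <- tile_pixels[, , 2]
  n <- nrow(g)
  (mean(abs(g[, -1] - g[, -ncol(g)])) + mean(abs(g[-1, ] - g[-n, ]))) / 2
}
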
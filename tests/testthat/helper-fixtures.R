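# Fixtures are built in code; nothing binary ships with the package.

# A uniform-colour slide of given size.
flat_slide <- function(value, h = 660L, w = 660L, id = "flat") {
  slide_image(array(value, dim = c(h, w, 3L)), id)
}

# Small tumour-only virtual biopsy (one fragment filling most of the canvas).
small_tumour_slide <- function(cls, seed, size = 1320L, noise_sd = 0,
                               stain_shift = c(0, 0, 0)) {
  generate_slide(synthetic_slide_spec(
    paste0(cls, "_", seed), cls, size, size, n_fragments = 1L,
    tumour_fraction = 1, stain_shift = stain_shift, noise_sd = noise_sd,
    seed = seed))
}

# Kept, mostly-tissue tiles of a slide with labels.
slide_tiles <- function(gen, max_white = 0.2) {
  g <- filter_tiles(build_tile_grid(gen$slide), gen$slide)
  kept <- g$tiles[g$tiles$kept & g$tiles$white_fraction <= max_white, ]
  tiles <- lapply(seq_len(nrow(kept)), function(i)
    tile_pixels(gen$slide, kept$row[i], kept$col[i]))
  list(tiles = tiles, addresses = kept, grid = g)
}

# Toy 56x56 texture tiles that a tiny CNN separates quickly:
# S = high-frequency speckle, NS = smooth gradient field.
toy_tile <- function(cls) {
  if (cls == "S") {
    base <- matrix(runif(56 * 56, 0.3, 0.9), 56, 56)
  } else {
    v <- seq(0.3, 0.9, length.out = 56)
    base <- outer(v, v, function(a, b) (a + b) / 2) + runif(1, -0.05, 0.05)
  }
  array(rep(base, 3), dim = c(56, 56, 3))
}

toy_dataset <- function(n_per_class, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tiles <- c(replicate(n_per_class, toy_tile("NS"), simplify = FALSE),
             replicate(n_per_class, toy_tile("S"), simplify = FALSE))
  list(tiles = tiles, labels = rep(c("NS", "S"), each = n_per_class))
}

# Random but well-formed tile prediction table on a square grid.
simulate_preds <- function(n_slides = 4L, grid = 10L, seed = 1,
                           acc = 0.8, conf_lo = 0.5, conf_hi = 1) {
  old <- if (exists(".Random.seed")) .Random.seed
  on.exit(if (!is.null(old)) .Random.seed <<- old)
  set.seed(seed)
  out <- lapply(seq_len(n_slides), function(s) {
    truth <- if (s %% 2 == 0) "S" else "NS"
    n <- grid * grid
    correct <- runif(n) < acc
    label <- ifelse(correct, truth, setdiff(c("NS", "S"), truth))
    conf <- runif(n, conf_lo, conf_hi)
    p_s <- ifelse(label == "S", conf, 1 - conf)
    data.table::data.table(
      slide_id = paste0("sl", s),
      row = rep(seq_len(grid) - 1L, each = grid),
      col = rep(seq_len(grid) - 1L, times = grid),
      p_ns = 1 - p_s, p_s = p_s, label = label,
      confidence = pmax(p_s, 1 - p_s), true_class = truth)
  })
  data.table::rbindlist(out)
}

# Even-odd point-in-polygon test, independent of the package's rasterizer.
pip <- function(px, py, poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- nrow(poly); inside <- rep(FALSE, length(px)); j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i]))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
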
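# Fixed, non-overlapping tile grid anchored at the image origin. Trailing
# partial strips are discarded: the grid has floor(H/px) x floor(W/px) tiles.

#' Partition a slide into a fixed tile grid
#'
#' Tiles are non-overlapping `tile_px x tile_px` squares (220 px at 20x by
#' default), addressed by 0-based `(row, col)` with half-open pixel boxes
#' `[col*tile_px, (col+1)*tile_px) x [row*tile_px, (row+1)*tile_px)`.
#'
#' @param slide a [slide_image()].
#' @param tile_px tile edge in pixels (default 220).
#' @return A `tile_grid`: list with `slide_id`, `tile_px`, `n_rows`, `n_cols`
#'   and `tiles`, a `data.table` with one row per grid cell
#'   (`slide_id row col x0 y0 x1 y1 white_fraction kept`); `white_fraction`
#'   is `NA` until [filter_tiles()] is applied, `kept` defaults to `TRUE`.
#' @export
build_tile_grid <- function(slide, tile_px = 220L) {
  d <- dim(slide$pixels)
  h <- d[1]; w <- d[2]
  if (h < tile_px || w < tile_px)
    stop(sprintf("image %d x %d smaller than one tile; need at least %d x %d",
                 h, w, tile_px, tile_px))
  n_rows <- h %/% tile_px
  n_cols <- w %/% tile_px
  g <- data.table::CJ(row = seq_len(n_rows) - 1L, col = seq_len(n_cols) - 1L)
  tiles <- data.table::data.table(
    slide_id = slide$slide_id, row = g$row, col = g$col,
    x0 = g$col * tile_px, y0 = g$row * tile_px,
    x1 = (g$col + 1L) * tile_px, y1 = (g$row + 1L) * tile_px,
    white_fraction = NA_real_, kept = TRUE)
  structure(list(slide_id = slide$slide_id, tile_px = as.integer(tile_px),
                 n_rows = n_rows, n_cols = n_cols, tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %s  %d x %d tiles of %d px  (%d kept)\n",
              x$slide_id, x$n_rows, x$n_cols, x$tile_px, sum(x$tiles$kept)))
  invisible(x)
}

#' Fraction of white-background pixels in a tile
#'
#' A pixel is white when all three channels are at or above `white_level` on
#' the unit scale. The level 0.94 tolerates mild stain shift while never
#' matching stained tissue.
#'
#' @param tile_pixels `t x t x 3` numeric array on the unit scale (or 8-bit,
#'   rescaled internally).
#' @param white_level unit-scale white threshold (default 0.94).
#' @return scalar in `[0, 1]`.
#' @export
white_fraction <- function(tile_pixels, white_level = 0.94) {
  d <- dim(tile_pixels)
  if (length(d) != 3L || d[3] != 3L || d[1] != d[2])
    stop("tile_pixels must be a square t x t x 3 array")
  if (max(tile_pixels) > 1 + 1e-9) tile_pixels <- tile_pixels / 255
  white <- (tile_pixels[, , 1] >= white_level) &
           (tile_pixels[, , 2] >= white_level) &
           (tile_pixels[, , 3] >= white_level)
  mean(white)
}

#' Flag background tiles in a grid
#'
#' A tile is removed when it contains strictly more than `max_white` white
#' background (default 2/3): a tile at exactly the limit is kept. The grid
#' geometry is unchanged; only `white_fraction` and `kept` are filled in.
#' Idempotent.
#'
#' @param grid a `tile_grid` built from `slide`.
#' @param slide the matching [slide_image()].
#' @param max_white maximum tolerated white fraction (default `2/3`).
#' @param white_level forwarded to [white_fraction()].
#' @return the grid with `white_fraction` computed and `kept` set.
#' @export
filter_tiles <- function(grid, slide, max_white = 2 / 3, white_level = 0.94) {
  if (grid$slide_id != slide$slide_id)
    stop("grid and slide have different slide_id")
  px <- slide$pixels
  if (max(px) > 1 + 1e-9) px <- px / 255
  t <- grid$tile_px
  tiles <- data.table::copy(grid$tiles)
  wf <- numeric(nrow(tiles))
  white <- (px[, , 1] >= white_level) & (px[, , 2] >= white_level) &
           (px[, , 3] >= white_level)
  for (i in seq_len(nrow(tiles))) {
    r <- tiles$row[i]; c <- tiles$col[i]
    wf[i] <- mean(white[(r * t + 1L):((r + 1L) * t),
                        (c * t + 1L):((c + 1L) * t)])
  }
  tiles[, `:=`(white_fraction = wf, kept = wf <= max_white)]
  grid$tiles <- tiles
  grid
}

#' Extract the pixel raster of one tile
#'
#' @param slide a [slide_image()].
#' @param row,col 0-based grid address.
#' @param tile_px tile edge in pixels.
#' @return `tile_px x tile_px x 3` array.
#' @export
tile_pixels <- function(slide, row, col, tile_px = 220L) {
  slide$pixels[(row * tile_px + 1L):((row + 1L) * tile_px),
               (col * tile_px + 1L):((col + 1L) * tile_px), , drop = FALSE]
}
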
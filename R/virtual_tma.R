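# Virtual tissue-microarray cores: a circle of 500 um radius around the
# area-weighted centroid of each pathologist annotation; tiles whose centers
# fall inside any core (and that survived background filtering) form the TMA
# tile set.

# Shoelace area-weighted centroid of one open ring; signed area handled.
polygon_centroid_xy <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-9) stop("degenerate (zero-area) polygon")
  c(sum((x + xn) * cross) / (6 * a), sum((y + yn) * cross) / (6 * a))
}

#' Area-weighted centroid of an annotation
#'
#' Standard shoelace centroid; for an annotation made of several disjoint
#' rings, the area-weighted centroid of their union.
#'
#' @param annotation an open `n x 2` polygon matrix (pixel coordinates), or a
#'   list of such rings.
#' @return length-2 numeric `(x, y)` in pixel coordinates.
#' @export
annotation_centroid <- function(annotation) {
  if (is.matrix(annotation)) return(polygon_centroid_xy(annotation))
  cents <- lapply(annotation, polygon_centroid_xy)
  areas <- vapply(annotation, function(p) {
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2)
  }, numeric(1))
  if (sum(areas) < 1e-9) stop("degenerate (zero-area) polygon")
  colSums(do.call(rbind, cents) * areas) / sum(areas)
}

#' Build virtual TMA regions from annotations
#'
#' One core per annotation polygon: centre at the annotation centroid, radius
#' `radius_um / microns_per_pixel` pixels (1000 px at the default 0.5 um/px).
#'
#' @param annotations list of open polygon rings for one slide.
#' @param slide_id slide identifier.
#' @param microns_per_pixel physical scale of the slide.
#' @param radius_um core radius in micrometres (default 500).
#' @return a `tma_regions` object: list with `slide_id`, `centers` (k x 2
#'   matrix) and `radius_px`.
#' @export
tma_regions <- function(annotations, slide_id, microns_per_pixel = 0.5,
                        radius_um = 500) {
  if (!length(annotations)) stop("no annotations supplied")
  centers <- do.call(rbind, lapply(annotations, annotation_centroid))
  structure(list(slide_id = slide_id, centers = centers,
                 radius_px = radius_um / microns_per_pixel),
            class = "tma_regions")
}

#' Restrict a tile grid to virtual TMA cores
#'
#' A tile is selected when its centre lies within Euclidean distance
#' `radius_px` of any core centre *and* it survived white-background
#' filtering; cores are pooled (union over annotations).
#'
#' @param grid a filtered `tile_grid`.
#' @param regions a [tma_regions()] object for the same slide.
#' @return the grid with `kept` updated to the TMA-selected subset.
#' @export
select_tma_tiles <- function(grid, regions) {
  if (!inherits(regions, "tma_regions") || !nrow(regions$centers))
    stop("no TMA regions supplied")
  if (!is.null(regions$slide_id) && regions$slide_id != grid$slide_id)
    stop("grid and regions have different slide_id")
  t <- grid$tile_px
  tiles <- data.table::copy(grid$tiles)
  cx <- (tiles$x0 + tiles$x1) / 2
  cy <- (tiles$y0 + tiles$y1) / 2
  inside <- rep(FALSE, nrow(tiles))
  for (k in seq_len(nrow(regions$centers))) {
    inside <- inside |
      (sqrt((cx - regions$centers[k, 1])^2 +
            (cy - regions$centers[k, 2])^2) <= regions$radius_px)
  }
  tiles[, kept := tiles$kept & inside]
  grid$tiles <- tiles
  grid
}

#' Serialize TMA regions to a JSON sidecar
#'
#' @param regions a [tma_regions()] object.
#' @param path JSON output path.
#' @export
write_tma_regions <- function(regions, path) {
  jsonlite::write_json(list(slide_id = regions$slide_id,
                            centers = regions$centers,
                            radius_px = regions$radius_px),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tma_regions
#' @export
read_tma_regions <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slide_id = obj$slide_id,
                 centers = matrix(obj$centers, ncol = 2L),
                 radius_px = obj$radius_px),
            class = "tma_regions")
}
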
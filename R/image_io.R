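#' @import data.table
#' @importFrom stats glm binomial plogis predict runif rnorm median sd setNames coef
#' @importFrom utils head tail write.csv
NULL

# Images are plain numeric arrays dim c(H, W, 3) on the unit scale [0, 1].
# Pixel coordinates: origin top-left, x rightward (columns), y downward (rows),
# 0-based in all external tables and GeoJSON; R's 1-based indexing is internal.

#' Slide image container
#'
#' Bundles an RGB raster with its identifier, physical scale and (optionally)
#' the slide's true histological class.
#'
#' @param pixels numeric array `H x W x 3`, values in `[0, 1]`, or an integer
#'   8-bit array which is rescaled by 1/255.
#' @param slide_id character scalar.
#' @param microns_per_pixel positive scalar, physical edge length of one pixel
#'   in micrometres (0.5 corresponds to a 20x scan).
#' @param true_class `"NS"`, `"S"` or `NA`.
#' @return An object of class `slide_image` (a list with fields `slide_id`,
#'   `pixels`, `microns_per_pixel`, `true_class`).
#' @export
slide_image <- function(pixels, slide_id, microns_per_pixel = 0.5,
                        true_class = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be a positive real")
  if (max(pixels) > 1 + 1e-9) pixels <- pixels / 255
  if (!is.na(true_class)) true_class <- match.arg(true_class, c("NS", "S"))
  structure(list(slide_id = as.character(slide_id),
                 pixels = pixels,
                 microns_per_pixel = microns_per_pixel,
                 true_class = true_class),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %s  %d x %d px  %.3g um/px  class=%s\n",
              x$slide_id, d[1], d[2], x$microns_per_pixel, x$true_class))
  invisible(x)
}

#' Write an RGB image as binary PPM (P6)
#'
#' PPM is the interchange raster format used throughout the package: it is a
#' trivial, dependency-free container for 8-bit RGB rasters. Values are
#' clipped to `[0, 1]` and quantized to 8 bits.
#'
#' @param pixels numeric `H x W x 3` array on the unit scale.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(pixels, path) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("pixels must be H x W x 3")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(d[2], d[1]), "255"), con, sep = "\n")
  v <- pmin(pmax(pixels, 0), 1)
  # PPM is row-major with interleaved channels; R arrays are column-major
  q <- as.integer(round(v * 255))
  dim(q) <- d
  inter <- aperm(q, c(3L, 2L, 1L))  # channel fastest, then column, then row
  writeBin(as.raw(inter), con)
  invisible(path)
}

#' Read a binary PPM (P6) image
#'
#' @param path file path to a P6 PPM written by [write_ppm()] or any
#'   conforming tool with maxval 255.
#' @return numeric `H x W x 3` array on the unit scale (exact multiples of
#'   1/255).
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PPM header: ", path)
      if (grepl("[[:space:]]", ch)) { if (length(tok)) break else next }
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
        if (!length(c2) || c2 == "\n") break }; next }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  if (read_token() != "P6") stop("not a P6 PPM: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (maxval != 255L) stop("unsupported PPM maxval: ", maxval)
  raw <- readBin(con, "raw", n = 3L * w * h)
  if (length(raw) != 3L * w * h) stop("truncated PPM payload: ", path)
  inter <- as.integer(raw)
  dim(inter) <- c(3L, w, h)
  aperm(inter, c(3L, 2L, 1L)) / 255
}

#' Read/write the cohort manifest TSV
#'
#' Columns: `slide_id path class annotation_path`. Paths are interpreted
#' relative to the manifest's directory when not absolute.
#'
#' @param path manifest file path.
#' @return `read_manifest`: a `data.table` with the four columns above plus
#'   absolute `path`/`annotation_path`.
#' @export
read_manifest <- function(path) {
  m <- read_tsv_checked(path, c("slide_id", "path", "class", "annotation_path"))
  base <- dirname(normalizePath(path))
  abspath <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$path <- abspath(m$path)
  m$annotation_path <- abspath(m$annotation_path)
  if (anyDuplicated(m$slide_id)) stop("duplicate slide_id in manifest: ", path)
  bad <- setdiff(unique(m$class), c("NS", "S"))
  if (length(bad)) stop("unknown class label(s) in manifest: ",
                        paste(bad, collapse = ", "))
  m
}

#' @rdname read_manifest
#' @param manifest data.frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("slide_id", "path", "class", "annotation_path")
  if (!all(need %in% names(manifest)))
    stop("manifest lacks column(s): ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  data.table::fwrite(as.data.table(manifest)[, need, with = FALSE], path,
                     sep = "\t")
  invisible(path)
}

# Shared schema-checked TSV reader: errors name the first missing column.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = NULL, showProgress = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(sprintf("%s: missing required column '%s'", path, missing[1]))
  d
}

#' Read/write per-tile prediction tables
#'
#' Columns `slide_id row col p_ns p_s label confidence`; `row`/`col` are the
#' 0-based tile grid address.
#'
#' @param preds data.frame of tile predictions.
#' @param path TSV path.
#' @export
write_predictions <- function(preds, path) {
  need <- c("slide_id", "row", "col", "p_ns", "p_s", "label", "confidence")
  miss <- setdiff(need, names(preds))
  if (length(miss)) stop("prediction table lacks column(s): ",
                         paste(miss, collapse = ", "))
  data.table::fwrite(as.data.table(preds)[, need, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  read_tsv_checked(path, c("slide_id", "row", "col", "p_ns", "p_s",
                           "label", "confidence"))
}

#' Read/write tile tables
#'
#' Columns `slide_id row col x0 y0 x1 y1 white_fraction kept`, half-open pixel
#' boxes, 0-based.
#'
#' @param tiles data.frame of tiles (one grid).
#' @param path TSV path.
#' @export
write_tile_table <- function(tiles, path) {
  need <- c("slide_id", "row", "col", "x0", "y0", "x1", "y1",
            "white_fraction", "kept")
  miss <- setdiff(need, names(tiles))
  if (length(miss)) stop("tile table lacks column(s): ",
                         paste(miss, collapse = ", "))
  data.table::fwrite(as.data.table(tiles)[, need, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_tile_table
#' @export
read_tile_table <- function(path) {
  read_tsv_checked(path, c("slide_id", "row", "col", "x0", "y0", "x1", "y1",
                           "white_fraction", "kept"))
}

#' Read/write slide-call tables
#'
#' Columns `slide_id method call score n_retained fallback_used`.
#'
#' @param calls data.frame of slide calls.
#' @param path TSV path.
#' @export
write_calls <- function(calls, path) {
  need <- c("slide_id", "method", "call", "score", "n_retained", "fallback_used")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("call table lacks column(s): ",
                         paste(miss, collapse = ", "))
  data.table::fwrite(as.data.table(calls)[, need, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  read_tsv_checked(path, c("slide_id", "method", "call", "score",
                           "n_retained", "fallback_used"))
}

#' GeoJSON annotation I/O
#'
#' Annotations are FeatureCollections of Polygons in pixel coordinates
#' (QuPath-export dialect): each feature one tumour region, exterior ring
#' closed (first vertex repeated last).
#'
#' @param polygons list of numeric matrices (n x 2, columns x,y, pixel units,
#'   open rings: the closing vertex is added on write and removed on read).
#' @param path output `.geojson` path.
#' @param slide_id slide identifier stored in each feature's properties.
#' @export
write_annotations <- function(polygons, path, slide_id = "") {
  feats <- lapply(polygons, function(p) {
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(slide_id = slide_id, classification = "tumour"),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @return `read_annotations`: list of open-ring `n x 2` matrices.
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  lapply(obj$features, function(f) {
    g <- f$geometry
    if (g$type != "Polygon") stop("unsupported geometry type: ", g$type)
    ring <- do.call(rbind, lapply(g$coordinates[[1]],
                                  function(v) as.numeric(unlist(v))))
    n <- nrow(ring)
    if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    if (nrow(ring) < 3) stop("polygon with fewer than 3 vertices in ", path)
    ring
  })
}

#' Channel statistics JSON sidecar
#'
#' @param stats a `channel_stats` object (see [compute_channel_stats()]).
#' @param path JSON path.
#' @export
write_channel_stats <- function(stats, path) {
  jsonlite::write_json(list(space = stats$space, mean = stats$mean,
                            sd = stats$sd),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_stats
#' @export
read_channel_stats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  channel_stats(as.numeric(obj$mean), as.numeric(obj$sd), space = obj$space)
}
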
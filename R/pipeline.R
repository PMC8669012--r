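# End-to-end pipeline: manifest -> tiling -> normalization -> slide-grouped
# split -> training -> per-tile prediction -> {threshold | kernel} x
# {WSI | TMA} x {majority | maxpool} -> reports. Every intermediate is
# written under the output directory; a run log echoes the configuration.

#' Pipeline configuration with reference defaults
#'
#' Defaults echo the reference method exactly: 220 px tiles, removal of tiles
#' with more than 2/3 white background, 60/20/20 slide-grouped split, lr
#' 0.001 decaying by 0.9 every 5 epochs, Adam epsilon 1e-7, batch 100, 100
#' epochs, loss factor 1.5, threshold grid step 0.05, 500 um TMA radius,
#' 0.5 um/px. Unknown arguments are rejected.
#'
#' @param tile_px tile edge (px).
#' @param max_white white-background removal limit.
#' @param white_level unit-scale white definition.
#' @param fractions train/val/test slide fractions.
#' @param split_seed seed for the slide split.
#' @param train a [train_config()].
#' @param grid_step threshold-search grid spacing.
#' @param min_retained minimum retained tile fraction in the grid search.
#' @param tma_radius_um virtual-TMA core radius (um).
#' @param microns_per_pixel slide scale (um/px).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(tile_px = 220L, max_white = 2 / 3,
                            white_level = 0.94,
                            fractions = c(0.6, 0.2, 0.2), split_seed = 1L,
                            train = train_config(), grid_step = 0.05,
                            min_retained = 0.05, tma_radius_um = 500,
                            microns_per_pixel = 0.5) {
  stopifnot(tile_px >= 1, max_white > 0, max_white <= 1,
            white_level > 0, white_level <= 1,
            grid_step > 0, tma_radius_um > 0, microns_per_pixel > 0,
            inherits(train, "train_config"))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three values summing to 1")
  structure(list(tile_px = as.integer(tile_px), max_white = max_white,
                 white_level = white_level, fractions = fractions,
                 split_seed = as.integer(split_seed), train = train,
                 grid_step = grid_step, min_retained = min_retained,
                 tma_radius_um = tma_radius_um,
                 microns_per_pixel = microns_per_pixel),
            class = "pipeline_config")
}

#' Validate a configuration list read from JSON
#'
#' @param lst named list of configuration fields (unknown keys rejected).
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_list <- function(lst) {
  train_keys <- setdiff(names(formals(train_config)), "backbone")
  top_keys <- names(formals(pipeline_config))
  unknown <- setdiff(names(lst), c(top_keys, "train"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  tr <- lst$train
  if (!is.null(tr)) {
    unknown_tr <- setdiff(names(tr), c(train_keys, "backbone"))
    if (length(unknown_tr))
      stop("unknown training key(s): ", paste(unknown_tr, collapse = ", "))
    lst$train <- do.call(train_config, tr)
  }
  do.call(pipeline_config, lst)
}

# Per-slide preprocessing: tile, filter, normalize, extract kept tiles
# (downsampled to the trainable resolution to bound memory). The slide is
# converted to lab space once; normalization is the per-channel affine map
# applied there before converting back.
process_slide <- function(row, config, target_stats = NULL) {
  slide <- load_slide(row, config$microns_per_pixel)
  grid <- build_tile_grid(slide, config$tile_px)
  grid <- filter_tiles(grid, slide, config$max_white, config$white_level)
  d <- dim(slide$pixels)
  m <- rgb_to_lab_m(matrix(slide$pixels, ncol = 3L))
  mask <- as.vector(tissue_mask(slide$pixels, config$white_level))
  stats <- lab_matrix_stats(m[mask, , drop = FALSE])
  if (!is.null(target_stats)) {
    scale <- target_stats$sd / stats$sd
    for (ch in 1:3)
      m[, ch] <- (m[, ch] - stats$mean[ch]) * scale[ch] +
        target_stats$mean[ch]
    px <- array(lab_to_rgb_m(m), dim = d)
  } else px <- slide$pixels
  rm(m)
  kept <- grid$tiles[grid$tiles$kept, ]
  tiles <- vector("list", nrow(kept))
  t <- config$tile_px
  s2 <- slide_image(px, slide$slide_id, slide$microns_per_pixel,
                    slide$true_class)
  for (i in seq_len(nrow(kept))) {
    tp <- tile_pixels(s2, kept$row[i], kept$col[i], t)
    d <- dim(tp)
    if (d[1] %% 4L == 0L)
      tp <- stem_downsample(array(tp, dim = c(d, 1L)))[, , , 1]
    tiles[[i]] <- tp
  }
  annotations <- read_annotations(row$annotation_path)
  regions <- tma_regions(annotations, row$slide_id,
                         config$microns_per_pixel, config$tma_radius_um)
  tma_grid <- select_tma_tiles(grid, regions)
  list(grid = grid, stats = stats, tiles = tiles, addresses = kept,
       regions = regions,
       tma_keys = with(tma_grid$tiles[tma_grid$tiles$kept, ],
                       paste(row, col)))
}

#' Preprocess a cohort once (tiling, filtering, normalization, TMA gating)
#'
#' The expensive image-side work of [run_pipeline()], reusable across
#' training seeds. The colour reference is the first slide of the manifest
#' (the reference choice is a cohort-level anchor and carries no label
#' information).
#'
#' @param manifest_path cohort manifest TSV.
#' @param config a [pipeline_config()].
#' @return an opaque cache list for `run_pipeline(cache = ...)`.
#' @export
preprocess_cohort <- function(manifest_path, config = pipeline_config()) {
  manifest <- read_manifest(manifest_path)
  ref <- load_slide(manifest[1, ], config$microns_per_pixel)
  target_stats <- compute_channel_stats(
    ref$pixels, tissue_mask(ref$pixels, config$white_level))
  rm(ref)
  per_slide <- vector("list", nrow(manifest))
  names(per_slide) <- manifest$slide_id
  for (i in seq_len(nrow(manifest)))
    per_slide[[manifest$slide_id[i]]] <-
      process_slide(manifest[i, ], config, target_stats)
  list(manifest = manifest, target_stats = target_stats,
       per_slide = per_slide)
}

#' Run the full pipeline on a cohort manifest
#'
#' Executes tiling, white filtering, Reinhard normalization to the first
#' training slide's statistics, slide-grouped splitting, training, per-tile
#' prediction, validation-split threshold search, training-split kernel-filter
#' fitting, virtual-TMA gating, and the full 2 x 2 x 2 strategy cross-product
#' (threshold/kernel x WSI/TMA x majority/maxpool) evaluated on the test
#' split at tile and slide level.
#'
#' @param manifest_path path to the cohort manifest TSV.
#' @param out_dir artifact directory (created).
#' @param config a [pipeline_config()].
#' @param cache optional result of [preprocess_cohort()] (must match the
#'   manifest and config); avoids repeating the image-side work when only
#'   seeds change.
#' @return list with `report` (strategy table), `calls`, `preds`,
#'   `thresholds`, `kernel`, `split`, `model`; all also written under
#'   `out_dir`.
#' @export
run_pipeline <- function(manifest_path, out_dir, config = pipeline_config(),
                         cache = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cache)) cache <- preprocess_cohort(manifest_path, config)
  manifest <- cache$manifest
  per_slide <- cache$per_slide
  write_channel_stats(cache$target_stats,
                      file.path(out_dir, "reference_stats.json"))
  split <- split_slides(manifest, config$fractions, config$split_seed)
  data.table::fwrite(split, file.path(out_dir, "split.tsv"), sep = "\t")
  tile_dir <- file.path(out_dir, "tiles")
  dir.create(tile_dir, showWarnings = FALSE)
  for (id in names(per_slide))
    write_tile_table(per_slide[[id]]$grid$tiles,
                     file.path(tile_dir, paste0(id, ".tsv")))

  split_of <- stats::setNames(split$split, split$slide_id)
  class_of <- stats::setNames(manifest$class, manifest$slide_id)

  # training on every kept tile of every training slide, slide label as
  # truth; the validation split steers best-epoch checkpoint selection
  tr_tiles <- list(); tr_labels <- character(0)
  va_tiles <- list(); va_labels <- character(0)
  for (id in names(per_slide)) {
    sp <- split_of[[id]]
    if (sp == "test") next
    if (sp == "train" && !length(per_slide[[id]]$tiles))
      stop("training slide ", id, " has no kept tiles")
    if (sp == "train") {
      tr_tiles <- c(tr_tiles, per_slide[[id]]$tiles)
      tr_labels <- c(tr_labels,
                     rep(class_of[[id]], length(per_slide[[id]]$tiles)))
    } else {
      va_tiles <- c(va_tiles, per_slide[[id]]$tiles)
      va_labels <- c(va_labels,
                     rep(class_of[[id]], length(per_slide[[id]]$tiles)))
    }
  }
  model <- train_classifier(tr_tiles, tr_labels, config$train,
                            val_tiles = va_tiles, val_labels = va_labels)
  utils::write.csv(model$history, file.path(out_dir, "training_history.csv"),
                   row.names = FALSE)

  preds <- data.table::rbindlist(lapply(names(per_slide), function(id) {
    ps <- per_slide[[id]]
    p <- predict_tiles(model, ps$tiles, ps$addresses[, c("slide_id", "row",
                                                         "col")])
    p[, `:=`(true_class = class_of[[id]], split = split_of[[id]],
             in_tma = paste(p$row, p$col) %in% ps$tma_keys)]
    p
  }))
  write_predictions(preds, file.path(out_dir, "predictions.tsv"))

  thr <- grid_search_thresholds(preds[preds$split == "val"],
                                config$grid_step, config$min_retained)
  write_thresholds(thr, file.path(out_dir, "thresholds.json"))
  kern <- fit_filter_kernel(preds[preds$split == "train"])
  write_kernel_model(kern, file.path(out_dir, "kernel.json"))

  test_preds <- preds[preds$split == "test"]
  truth_slide <- class_of[unique(test_preds$slide_id)]
  reports <- list(); calls_all <- list()
  for (gate in c("WSI", "TMA")) {
    base <- if (gate == "WSI") test_preds else test_preds[test_preds$in_tma]
    for (mode in c("threshold", "kernel")) {
      sel <- if (mode == "threshold") apply_thresholds(base, thr)
             else apply_filter_kernel(kern, base)
      tag0 <- sprintf("%s/%s", gate, if (mode == "threshold")
        sprintf("threshold(%.2f,%.2f)", thr$t_ns, thr$t_s) else "kernel")
      reports[[paste0(tag0, "/tile")]] <-
        accuracy_report(sel$label, sel$true_class, "tile", tag0)
      for (agg in c("majority", "maxpool")) {
        calls <- aggregate_slides(sel, base, agg)
        tag <- paste0(tag0, "/", agg)
        calls[, strategy := tag]
        calls_all[[tag]] <- calls
        reports[[paste0(tag, "/slide")]] <-
          accuracy_report(calls$call, class_of[calls$slide_id], "slide", tag)
      }
    }
  }
  report <- data.table::rbindlist(reports)
  calls <- data.table::rbindlist(calls_all)
  data.table::fwrite(report, file.path(out_dir, "report.tsv"), sep = "\t")
  write_calls(calls[, c("slide_id", "method", "call", "score", "n_retained",
                        "fallback_used"), with = FALSE],
              file.path(out_dir, "calls.tsv"))

  cfg_echo <- unclass(config); cfg_echo$train <- unclass(config$train)
  jsonlite::write_json(list(config = cfg_echo,
                            thresholds = list(t_ns = thr$t_ns, t_s = thr$t_s),
                            n_slides = nrow(manifest)),
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, calls = calls, preds = preds,
                 thresholds = thr, kernel = kern, split = split,
                 model = model))
}
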
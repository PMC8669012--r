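# Patient-inference post-processing: confidence thresholding tuned by grid
# search, spatial re-estimation of tile probabilities from the label
# distribution of the 8-neighbourhood (logistic-regression "filter kernel"),
# and slide-level aggregation by majority vote or max pooling.

#' Confidence threshold pair
#'
#' @param t_ns,t_s per-class confidence thresholds in `[0.5, 1)`. `(0.5, 0.5)`
#'   retains every tile in the binary setting.
#' @return a `threshold_pair` object.
#' @export
threshold_pair <- function(t_ns, t_s) {
  if (t_ns < 0.5 || t_ns >= 1 || t_s < 0.5 || t_s >= 1)
    stop("thresholds must lie in [0.5, 1)")
  structure(list(t_ns = t_ns, t_s = t_s), class = "threshold_pair")
}

#' Grid search for per-class confidence thresholds
#'
#' Exhaustively evaluates every pair on the grid `{0.5, 0.55, ..., 0.95}^2`
#' (step `grid_step`), scoring the tile-level correct-classification rate
#' among retained tiles, subject to a minimum retained fraction of 5%. Ties
#' are broken toward lower thresholds (more tiles retained).
#'
#' @param preds prediction table with `p_ns`, `p_s`, `label` and a
#'   `true_class` column (the tile's slide label).
#' @param grid_step grid spacing (default 0.05).
#' @param min_retained minimum retained fraction (default 0.05).
#' @return the winning [threshold_pair()] with attributes `objective` and
#'   `retained_fraction`.
#' @export
grid_search_thresholds <- function(preds, grid_step = 0.05,
                                   min_retained = 0.05) {
  preds <- as.data.table(preds)
  if (!nrow(preds)) stop("empty prediction table")
  if (!"true_class" %in% names(preds))
    stop("predictions need a true_class column")
  levels <- seq(0.5, 0.95, by = grid_step)
  best <- NULL; best_obj <- -Inf
  n <- nrow(preds)
  correct <- preds$label == preds$true_class
  is_s <- preds$label == "S"
  for (t_ns in levels) for (t_s in levels) {
    retained <- (!is_s & preds$p_ns >= t_ns) | (is_s & preds$p_s >= t_s)
    nr <- sum(retained)
    if (nr < min_retained * n) next
    obj <- sum(correct & retained) / nr
    if (obj > best_obj + 1e-12) {          # strict: first (lowest) pair wins ties
      best_obj <- obj
      best <- c(t_ns, t_s, nr / n)
    }
  }
  if (is.null(best)) stop("no threshold pair retains the minimum tile fraction")
  out <- threshold_pair(best[1], best[2])
  attr(out, "objective") <- best_obj
  attr(out, "retained_fraction") <- best[3]
  out
}

#' Filter low-confidence tile predictions
#'
#' A tile labelled NS is retained iff `p_ns >= t_ns`; a tile labelled S iff
#' `p_s >= t_s`. At `(0.5, 0.5)` every binary argmax prediction is retained.
#'
#' @param preds prediction table.
#' @param thr a [threshold_pair()].
#' @return the retained subset of `preds`.
#' @export
apply_thresholds <- function(preds, thr) {
  preds <- as.data.table(preds)
  keep <- ifelse(preds$label == "S", preds$p_s >= thr$t_s,
                 preds$p_ns >= thr$t_ns)
  preds[keep]
}

# 8-neighbour offsets, radius 1.
.noffs <- cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))[-5, ]

#' Neighbourhood features of every tile in a prediction grid
#'
#' For each tile: its own `p_s`; the fraction of its *existing* 8-neighbours
#' labelled S (absent or unkept neighbours are excluded from the
#' denominator); and the fraction of the 8 neighbour positions that are
#' absent. An isolated tile (no valid neighbour) falls back to its own label
#' indicator for the S fraction.
#'
#' @param preds prediction table of one slide (`slide_id row col p_s label`).
#' @return `data.table` with `p_s`, `frac_s`, `frac_missing` aligned to
#'   `preds` rows.
#' @export
neighbor_features <- function(preds) {
  preds <- as.data.table(preds)
  key <- paste(preds$slide_id, preds$row, preds$col)
  lab_s <- preds$label == "S"
  idx <- seq_len(nrow(preds))
  names(idx) <- key
  n_valid <- integer(nrow(preds))
  n_s <- integer(nrow(preds))
  for (k in seq_len(nrow(.noffs))) {
    nk <- paste(preds$slide_id, preds$row + .noffs[k, 1],
                preds$col + .noffs[k, 2])
    hit <- idx[nk]
    ok <- !is.na(hit)
    n_valid <- n_valid + ok
    n_s <- n_s + ifelse(ok, lab_s[hit], 0L)
  }
  frac_s <- ifelse(n_valid > 0, n_s / n_valid, as.numeric(lab_s))
  data.table::data.table(p_s = preds$p_s, frac_s = frac_s,
                         frac_missing = (8L - n_valid) / 8)
}

#' @rdname neighbor_features
#' @param row,col 0-based address of one tile present in `preds`.
#' @return `neighbor_label_distribution`: the length-3 feature vector of that
#'   tile.
#' @export
neighbor_label_distribution <- function(preds, row, col) {
  preds <- as.data.table(preds)
  i <- which(preds$row == row & preds$col == col)
  if (!length(i)) stop("tile not present in prediction grid")
  unlist(neighbor_features(preds)[i[1]])
}

#' Fit the spatial filter-kernel model
#'
#' Logistic regression of the tile's true class (its slide's class) on the
#' neighbourhood features — the parameter-estimation strategy for the filter
#' kernel. Deterministic given the data.
#'
#' @param preds training-split prediction table with a `true_class` column.
#' @return a `kernel_filter_model`: list with `intercept` and `coef`
#'   (named: `p_s`, `frac_s`, `frac_missing`).
#' @export
fit_filter_kernel <- function(preds) {
  preds <- as.data.table(preds)
  if (!"true_class" %in% names(preds))
    stop("predictions need a true_class column")
  if (length(unique(preds$true_class)) < 2L)
    stop("both classes are required to fit the filter kernel")
  feats <- do.call(rbind, lapply(split(preds, preds$slide_id),
                                 neighbor_features))
  ord <- unlist(lapply(split(seq_len(nrow(preds)), preds$slide_id),
                       identity), use.names = FALSE)
  y <- as.integer(preds$true_class[ord] == "S")
  fit <- stats::glm(y ~ p_s + frac_s + frac_missing,
                    data = cbind(feats, y = y), family = stats::binomial())
  co <- stats::coef(fit)
  co[is.na(co)] <- 0        # collinear/constant feature: dropped, weight 0
  structure(list(intercept = unname(co[1]),
                 coef = c(p_s = unname(co["p_s"]),
                          frac_s = unname(co["frac_s"]),
                          frac_missing = unname(co["frac_missing"]))),
            class = "kernel_filter_model")
}

#' @export
print.kernel_filter_model <- function(x, ...) {
  cat(sprintf(paste0("<kernel_filter_model> logit(p_S) = %.3f + %.3f p_s",
                     " + %.3f frac_s + %.3f frac_missing\n"),
              x$intercept, x$coef["p_s"], x$coef["frac_s"],
              x$coef["frac_missing"]))
  invisible(x)
}

#' Re-estimate tile probabilities with the filter kernel
#'
#' Every tile's probability pair is replaced by the model's prediction on its
#' neighbourhood features in a single simultaneous pass (features are
#' computed from the input labels, not iteratively). With a positive
#' neighbour coefficient, a tile agreeing with its neighbours gains
#' probability and a disagreeing tile loses it.
#'
#' @param model a fitted [fit_filter_kernel()] model (or one built by hand
#'   with the same structure).
#' @param preds prediction table (any number of slides).
#' @return `preds` with `p_ns`, `p_s`, `label`, `confidence` re-estimated.
#' @export
apply_filter_kernel <- function(model, preds) {
  preds <- as.data.table(preds)
  out <- vector("list", length(unique(preds$slide_id)))
  parts <- split(preds, preds$slide_id)
  for (i in seq_along(parts)) {
    f <- neighbor_features(parts[[i]])
    eta <- model$intercept + model$coef["p_s"] * f$p_s +
      model$coef["frac_s"] * f$frac_s +
      model$coef["frac_missing"] * f$frac_missing
    new_ps <- unname(stats::plogis(eta))
    part <- data.table::copy(parts[[i]])
    part[, `:=`(p_s = new_ps, p_ns = 1 - new_ps,
                label = ifelse(new_ps > 1 - new_ps, "S", "NS"),
                confidence = pmax(new_ps, 1 - new_ps))]
    out[[i]] <- part
  }
  data.table::rbindlist(out)
}

slide_call_row <- function(slide_id, method, call, score, n_retained,
                           fallback_used) {
  data.table::data.table(slide_id = slide_id, method = method, call = call,
                         score = score, n_retained = n_retained,
                         fallback_used = fallback_used)
}

#' Slide-level call by majority vote
#'
#' The slide receives the most frequent retained tile class; the score is the
#' fraction of retained tiles voting S. A count tie goes to the label with
#' the larger mean confidence, then to NS. If no tile survived thresholding
#' the unthresholded predictions are used and flagged (`fallback_used`).
#'
#' @param retained retained prediction rows of one slide.
#' @param all_preds the slide's full prediction table (fallback source).
#' @return one-row `data.table`:
#'   `slide_id method call score n_retained fallback_used`.
#' @export
call_majority <- function(retained, all_preds = retained) {
  retained <- as.data.table(retained)
  fallback <- nrow(retained) == 0L
  p <- if (fallback) as.data.table(all_preds) else retained
  if (!nrow(p)) stop("no predictions to aggregate")
  n_s <- sum(p$label == "S"); n_ns <- sum(p$label == "NS")
  call <- if (n_s > n_ns) "S" else if (n_ns > n_s) "NS" else {
    mean_s <- mean(p$confidence[p$label == "S"])
    mean_ns <- mean(p$confidence[p$label == "NS"])
    if (isTRUE(mean_s > mean_ns)) "S" else "NS"
  }
  slide_call_row(p$slide_id[1], "majority", call, n_s / nrow(p),
                 if (fallback) 0L else nrow(retained), fallback)
}

#' Slide-level call by max pooling
#'
#' The slide receives the label of the single most confident retained tile
#' (confidence ties go to NS); the score is the maximum `p_s`. Fallback as in
#' [call_majority()].
#'
#' @inheritParams call_majority
#' @return one-row `data.table`.
#' @export
call_maxpool <- function(retained, all_preds = retained) {
  retained <- as.data.table(retained)
  fallback <- nrow(retained) == 0L
  p <- if (fallback) as.data.table(all_preds) else retained
  if (!nrow(p)) stop("no predictions to aggregate")
  cmax <- max(p$confidence)
  top <- p[p$confidence == cmax]
  call <- if (any(top$label == "NS")) "NS" else "S"   # ties -> NS
  if (all(top$label == "S")) call <- "S"
  slide_call_row(p$slide_id[1], "maxpool", call, max(p$p_s),
                 if (fallback) 0L else nrow(retained), fallback)
}

#' Aggregate every slide of a prediction table
#'
#' @param retained retained predictions (all slides).
#' @param all_preds full predictions (fallback source; must cover every slide
#'   of interest).
#' @param method `"majority"` or `"maxpool"`.
#' @return `data.table` of one call per slide present in `all_preds`.
#' @export
aggregate_slides <- function(retained, all_preds, method = c("majority",
                                                             "maxpool")) {
  method <- match.arg(method)
  fn <- if (method == "majority") call_majority else call_maxpool
  retained <- as.data.table(retained)
  all_preds <- as.data.table(all_preds)
  ids <- unique(all_preds$slide_id)
  data.table::rbindlist(lapply(ids, function(id)
    fn(retained[retained$slide_id == id],
       all_preds[all_preds$slide_id == id])))
}

#' Threshold-pair JSON sidecar
#'
#' @param thr a [threshold_pair()]; `model` a `kernel_filter_model`.
#' @param path JSON path.
#' @export
write_thresholds <- function(thr, path) {
  jsonlite::write_json(list(t_ns = thr$t_ns, t_s = thr$t_s), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_pair(obj$t_ns, obj$t_s)
}

#' @rdname write_thresholds
#' @param model a `kernel_filter_model`.
#' @export
write_kernel_model <- function(model, path) {
  jsonlite::write_json(list(intercept = model$intercept,
                            coef = as.list(model$coef)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_kernel_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = obj$intercept,
                 coef = c(p_s = obj$coef$p_s, frac_s = obj$coef$frac_s,
                          frac_missing = obj$coef$frac_missing)),
            class = "kernel_filter_model")
}
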
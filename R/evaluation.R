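# Accuracy reports (overall + per-class recall), ROC/AUC with the
# Mann-Whitney tie convention, and probability heatmaps (red = squamous,
# green = non-squamous, grey = removed/unselected).

#' Accuracy report, overall and by class
#'
#' Overall accuracy is `correct / total`; the per-class value is recall
#' within that true class, so the overall value equals the count-weighted
#' mean of the per-class values.
#'
#' @param pred_labels predicted classes (`"NS"`/`"S"`).
#' @param true_labels true classes, same length.
#' @param level `"tile"` or `"slide"`.
#' @param strategy free-text tag (e.g. `"WSI/threshold(0.9,0.9)/majority"`).
#' @return one-row `data.table`:
#'   `level strategy overall acc_NS acc_S n_NS n_S`.
#' @export
accuracy_report <- function(pred_labels, true_labels, level = "tile",
                            strategy = "") {
  if (!length(pred_labels)) stop("empty predictions")
  if (length(pred_labels) != length(true_labels))
    stop("prediction/truth length mismatch")
  correct <- pred_labels == true_labels
  acc_cls <- function(cls) {
    n <- sum(true_labels == cls)
    if (n == 0L) NA_real_ else sum(correct & true_labels == cls) / n
  }
  data.table::data.table(level = level, strategy = strategy,
                         overall = mean(correct),
                         acc_NS = acc_cls("NS"), acc_S = acc_cls("S"),
                         n_NS = sum(true_labels == "NS"),
                         n_S = sum(true_labels == "S"))
}

#' ROC curve and AUC (squamous = positive class)
#'
#' AUC is the probability that a random S item outscores a random NS item,
#' with ties counted one half (the Mann-Whitney identity); the curve is a
#' threshold sweep over the observed scores, and its trapezoidal integral
#' equals the AUC.
#'
#' @param scores numeric score per item (larger = more S-like).
#' @param labels true classes (`"NS"`/`"S"`), both present.
#' @return a `roc_curve`: list with `points` (data.frame `fpr`, `tpr` sorted
#'   from threshold `+Inf` down) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "S"
  n_s <- sum(pos); n_ns <- sum(!pos)
  if (n_s == 0L || n_ns == 0L) stop("both classes are required for ROC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_s * (n_s + 1) / 2) / (n_s * n_ns)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- data.frame(
    fpr = vapply(thr, function(t) sum(scores >= t & !pos) / n_ns, numeric(1)),
    tpr = vapply(thr, function(t) sum(scores >= t & pos) / n_s, numeric(1)))
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points  AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Render a tile-probability heatmap
#'
#' One `block x block` pixel square per grid cell: red with intensity `p_s`
#' for tiles labelled S, green with intensity `p_ns` for tiles labelled NS
#' (the winning probability colours the tile), mid-grey for tiles removed by
#' the white-background filter or not selected (e.g. outside the virtual
#' TMA).
#'
#' @param preds prediction table of one slide (only selected tiles present).
#' @param grid the slide's `tile_grid` (geometry source).
#' @param path optional PPM output path.
#' @param block pixels per tile block (default 8).
#' @return the heatmap raster (`n_rows*block x n_cols*block x 3`), invisibly
#'   when `path` is given.
#' @export
render_heatmap <- function(preds, grid, path = NULL, block = 8L) {
  img <- array(0.5, dim = c(grid$n_rows * block, grid$n_cols * block, 3L))
  preds <- as.data.table(preds)
  for (i in seq_len(nrow(preds))) {
    r <- preds$row[i]; c <- preds$col[i]
    rgb <- if (preds$label[i] == "S") c(preds$p_s[i], 0, 0)
           else c(0, preds$p_ns[i], 0)
    for (ch in 1:3)
      img[(r * block + 1L):((r + 1L) * block),
          (c * block + 1L):((c + 1L) * block), ch] <- rgb[ch]
  }
  if (!is.null(path)) {
    write_ppm(img, path)
    return(invisible(img))
  }
  img
}
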
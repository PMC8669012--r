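# independent brute-force objective for the threshold grid search
sweep_oracle <- function(preds, levels, min_frac = 0.05) {
  best <- -Inf
  for (t_ns in levels) for (t_s in levels) {
    keep <- ifelse(preds$label == "S", preds$p_s >= t_s, preds$p_ns >= t_ns)
    if (sum(keep) < min_frac * nrow(preds)) next
    best <- max(best, mean(preds$label[keep] == preds$true_class[keep]))
  }
  best
}

test_that("grid search matches the exhaustive oracle and its tie-break", {
  preds <- simulate_preds(n_slides = 10L, grid = 10L, seed = 21, acc = 0.75)
  expect_equal(nrow(preds), 1000L)
  thr <- grid_search_thresholds(preds)
  expect_equal(attr(thr, "objective"),
               sweep_oracle(preds, seq(0.5, 0.95, 0.05)))

  # perfectly confident correct predictions: (0.5, 0.5) wins by tie-break
  perfect <- data.table::copy(preds)
  perfect[, `:=`(label = true_class,
                 p_s = ifelse(true_class == "S", 1, 0))]
  perfect[, `:=`(p_ns = 1 - p_s, confidence = 1)]
  thr0 <- grid_search_thresholds(perfect)
  expect_equal(c(thr0$t_ns, thr0$t_s), c(0.5, 0.5))
  expect_equal(attr(thr0, "objective"), 1.0)

  expect_error(grid_search_thresholds(preds[0]), "empty")
})

test_that("high-confidence-correct worlds drive the search to (0.9, 0.9)", {
  # confident tiles always correct, low-confidence tiles mostly wrong
  set.seed(31)
  n <- 2000L
  conf_hi <- runif(n) < 0.3
  truth <- sample(c("NS", "S"), n, replace = TRUE)
  label <- ifelse(conf_hi, truth,
                  ifelse(runif(n) < 0.45, truth,
                         ifelse(truth == "S", "NS", "S")))
  conf <- ifelse(conf_hi, runif(n, 0.92, 0.99), runif(n, 0.5, 0.88))
  p_s <- ifelse(label == "S", conf, 1 - conf)
  preds <- data.table::data.table(
    slide_id = "a", row = seq_len(n) - 1L, col = 0L,
    p_ns = 1 - p_s, p_s = p_s, label = label,
    confidence = conf, true_class = truth)
  thr <- grid_search_thresholds(preds)
  expect_equal(c(thr$t_ns, thr$t_s), c(0.9, 0.9))
  expect_equal(attr(thr, "objective"), sweep_oracle(preds, seq(0.5, 0.95, 0.05)))
})

test_that("apply_thresholds follows the per-class retention rule", {
  preds <- simulate_preds(n_slides = 4L, grid = 8L, seed = 5)
  # (0.5, 0.5) retains everything (binary argmax implies max p >= 0.5)
  expect_equal(nrow(apply_thresholds(preds, threshold_pair(0.5, 0.5))),
               nrow(preds))
  # counting oracle at (0.9, 0.9)
  kept <- apply_thresholds(preds, threshold_pair(0.9, 0.9))
  oracle <- sum(ifelse(preds$label == "S", preds$p_s >= 0.9,
                       preds$p_ns >= 0.9))
  expect_equal(nrow(kept), oracle)
  # a tile labelled S at p_s = 0.85 is dropped at t_s = 0.9
  one <- data.table::data.table(slide_id = "x", row = 0L, col = 0L,
                                p_ns = 0.15, p_s = 0.85, label = "S",
                                confidence = 0.85)
  expect_equal(nrow(apply_thresholds(one, threshold_pair(0.9, 0.9))), 0L)
  expect_error(threshold_pair(0.4, 0.6), "0.5")
})

test_that("neighbourhood features count the 8-neighbourhood correctly", {
  full <- simulate_preds(n_slides = 1L, grid = 3L, seed = 1)
  full[, label := "S"]
  f_center <- neighbor_label_distribution(full, 1L, 1L)
  expect_equal(unname(f_center["frac_s"]), 1.0)
  expect_equal(unname(f_center["frac_missing"]), 0.0)

  # corner tile with 3 existing neighbours, 2 labelled S
  corner <- full[(row == 0 & col <= 1) | (row == 1 & col <= 1)]
  corner[, label := c("NS", "S", "S", "NS")]   # (0,0) (1,0) (0,1) (1,1)
  f <- neighbor_label_distribution(corner, 0L, 0L)
  expect_equal(unname(f["frac_s"]), 2 / 3)
  expect_equal(unname(f["frac_missing"]), 5 / 8)

  # isolated tile: fallback to its own label indicator
  lone <- full[row == 0 & col == 0]
  lone[, label := "NS"]
  f_iso <- neighbor_label_distribution(lone, 0L, 0L)
  expect_equal(unname(f_iso["frac_s"]), 0.0)
  expect_equal(unname(f_iso["frac_missing"]), 1.0)

  expect_error(neighbor_label_distribution(full, 9L, 9L), "not present")
})

test_that("filter-kernel fit recovers a known logistic model", {
  # note: the response draw must use an RNG stream independent of the one
  # that generated the features
  set.seed(9917)
  preds <- simulate_preds(n_slides = 4L, grid = 50L, seed = 17, acc = 0.7,
                          conf_lo = 0.5, conf_hi = 0.95)
  expect_equal(nrow(preds), 10000L)
  # brute-force features, independent of neighbor_features()
  feats <- do.call(rbind, lapply(split(preds, preds$slide_id), function(p) {
    t(vapply(seq_len(nrow(p)), function(i) {
      nb <- p[abs(p$row - p$row[i]) <= 1 & abs(p$col - p$col[i]) <= 1 &
                !(p$row == p$row[i] & p$col == p$col[i])]
      c(p$p_s[i], mean(nb$label == "S"), (8 - nrow(nb)) / 8)
    }, numeric(3)))
  }))
  truth <- c(-2, 1.5, 2.5, 0)
  eta <- truth[1] + feats %*% truth[2:4]
  y <- rbinom(nrow(feats), 1, stats::plogis(eta))
  sim <- data.table::as.data.table(preds)
  ord <- unlist(split(seq_len(nrow(preds)), preds$slide_id), use.names = FALSE)
  sim$true_class[ord] <- ifelse(y == 1, "S", "NS")

  model <- fit_filter_kernel(sim)
  # oracle: glm on the brute-force features with its standard errors
  ref <- stats::glm(y ~ feats, family = stats::binomial())
  se <- sqrt(diag(stats::vcov(ref)))
  est <- c(model$intercept, model$coef)
  expect_lt(max(abs(est - stats::coef(ref))), 1e-6)   # same features, same fit
  expect_true(all(abs(est - truth) < 2 * se))

  # determinism
  model2 <- fit_filter_kernel(sim)
  expect_identical(model, model2)
  expect_error(fit_filter_kernel(sim[true_class == "S"]), "both classes")
})

test_that("kernel re-estimation raises agreeing tiles and lowers dissenters", {
  # hand-built model with positive own- and neighbour-coefficients for which
  # the quoted monotonicity holds over the whole p_s range used
  model <- structure(list(intercept = -4,
                          coef = c(p_s = 4, frac_s = 6, frac_missing = 0)),
                     class = "kernel_filter_model")
  grid <- simulate_preds(n_slides = 1L, grid = 5L, seed = 2)
  agree <- data.table::copy(grid)
  agree[, `:=`(label = "S", p_s = runif(.N, 0.5, 0.95))]
  agree[, `:=`(p_ns = 1 - p_s, confidence = p_s)]
  out <- apply_filter_kernel(model, agree)
  expect_true(all(out$p_s >= agree$p_s))

  # one S tile surrounded by NS tiles loses probability
  lone <- data.table::copy(grid)
  lone[, `:=`(label = "NS", p_s = 0.2, p_ns = 0.8, confidence = 0.8)]
  lone[row == 2 & col == 2, `:=`(label = "S", p_s = 0.7, p_ns = 0.3,
                                 confidence = 0.7)]
  out2 <- apply_filter_kernel(model, lone)
  expect_lt(out2[row == 2 & col == 2]$p_s, 0.7)

  # uniform grid stays uniform
  unif <- data.table::copy(grid)
  unif[, `:=`(label = "S", p_s = 0.6, p_ns = 0.4, confidence = 0.6)]
  out3 <- apply_filter_kernel(model, unif)
  interior <- out3[row > 0 & row < 4 & col > 0 & col < 4]
  expect_equal(var(interior$p_s), 0)

  # probabilities remain a valid pair
  expect_equal(out$p_s + out$p_ns, rep(1, nrow(out)))
})

test_that("majority vote counts, tie-breaks and falls back as specified", {
  mk <- function(labels, conf = 0.8, p_s = NULL) {
    if (is.null(p_s)) p_s <- ifelse(labels == "S", conf, 1 - conf)
    data.table::data.table(slide_id = "sl", row = seq_along(labels) - 1L,
                           col = 0L, p_ns = 1 - p_s, p_s = p_s,
                           label = labels, confidence = pmax(p_s, 1 - p_s))
  }
  r <- call_majority(mk(rep(c("S", "NS"), c(10, 3))))
  expect_equal(r$call, "S")
  expect_equal(r$score, 10 / 13)
  expect_equal(r$n_retained, 13L)
  expect_false(r$fallback_used)

  # 5 vs 5, S side more confident
  tied <- rbind(mk(rep("S", 5), conf = 0.8), mk(rep("NS", 5), conf = 0.6))
  expect_equal(call_majority(tied)$call, "S")
  # exactly symmetric tie goes to NS
  sym <- rbind(mk(rep("S", 5), conf = 0.7), mk(rep("NS", 5), conf = 0.7))
  expect_equal(call_majority(sym)$call, "NS")

  expect_equal(call_majority(mk("S"))$call, "S")

  # empty retention: falls back to the full table, flagged
  all_preds <- mk(rep(c("S", "NS"), c(2, 1)))
  fb <- call_majority(all_preds[0], all_preds)
  expect_true(fb$fallback_used)
  expect_equal(fb$call, "S")
  expect_equal(fb$n_retained, 0L)
})

test_that("max pooling picks the single most confident tile and matches brute force", {
  preds <- simulate_preds(n_slides = 1L, grid = 32L, seed = 8,
                          conf_lo = 0.5, conf_hi = 0.999)[seq_len(1000)]
  r <- call_maxpool(preds)
  i_star <- which.max(preds$confidence)
  expect_equal(r$call, preds$label[i_star])
  expect_equal(r$score, max(preds$p_s))

  top2 <- data.table::data.table(slide_id = "x", row = 0:1, col = 0L,
                                 p_ns = c(0.01, 0.02), p_s = c(0.99, 0.98),
                                 label = "S", confidence = c(0.99, 0.98))
  expect_equal(call_maxpool(top2)$call, "S")
  # confidence tie with conflicting labels resolves to NS
  tie <- data.table::data.table(slide_id = "x", row = 0:1, col = 0L,
                                p_ns = c(0.99, 0.01), p_s = c(0.01, 0.99),
                                label = c("NS", "S"), confidence = 0.99)
  expect_equal(call_maxpool(tie)$call, "NS")
  # all tiles identical
  same <- tie[2][rep(1, 4)]
  expect_equal(call_maxpool(same)$call, "S")
})

test_that("majority and maxpool agree when every tile shares one label", {
  for (seed in 1:5) {
    preds <- simulate_preds(n_slides = 1L, grid = 6L, seed = seed)
    preds[, `:=`(label = "NS", p_s = runif(.N, 0, 0.49))]
    preds[, `:=`(p_ns = 1 - p_s, confidence = 1 - p_s)]
    expect_equal(call_majority(preds)$call, call_maxpool(preds)$call)
  }
})

test_that("threshold and kernel parameters survive JSON round trips", {
  d <- withr::local_tempdir()
  thr <- threshold_pair(0.9, 0.55)
  p1 <- file.path(d, "thr.json")
  write_thresholds(thr, p1)
  thr2 <- read_thresholds(p1)
  expect_equal(thr2$t_ns, 0.9)
  expect_equal(thr2$t_s, 0.55)

  km <- structure(list(intercept = -1.25,
                       coef = c(p_s = 2.5, frac_s = 3.75, frac_missing = -0.5)),
                  class = "kernel_filter_model")
  p2 <- file.path(d, "kern.json")
  write_kernel_model(km, p2)
  expect_equal(read_kernel_model(p2), km)
})
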
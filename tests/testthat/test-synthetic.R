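test_that("generation is deterministic and annotations match the spec", {
  spec <- synthetic_slide_spec("det", "S", 1500L, 1500L, n_fragments = 1L,
                               tumour_fraction = 1, noise_sd = 0.02, seed = 7L)
  a <- generate_slide(spec)
  b <- generate_slide(spec)
  expect_length(a$annotations, 1L)
  expect_identical(a$slide$pixels, b$slide$pixels)
  expect_identical(a$annotations, b$annotations)

  # annotations strictly inside the image
  for (poly in a$annotations) {
    expect_true(all(poly[, 1] > 0 & poly[, 1] < 1500))
    expect_true(all(poly[, 2] > 0 & poly[, 2] < 1500))
  }
})

test_that("tumour_fraction = 1 puts every tissue pixel inside the annotation", {
  a <- generate_slide(synthetic_slide_spec("full", "NS", 660L, 660L,
                                           n_fragments = 1L,
                                           tumour_fraction = 1, seed = 3L))
  expect_identical(a$masks$tissue, a$masks$tumour)
  # oracle: re-rasterize the emitted polygon with an independent test
  idx <- which(a$masks$tissue, arr.ind = TRUE)
  sub <- idx[seq(1, nrow(idx), length.out = 500), , drop = FALSE]
  expect_true(all(pip(sub[, 2] - 0.5, sub[, 1] - 0.5, a$annotations[[1]])))
})

test_that("fragments are disjoint and annotated area tracks tumour_fraction", {
  spec <- synthetic_slide_spec("tri", "S", 3000L, 3000L, n_fragments = 3L,
                               tumour_fraction = 0.3, seed = 9L)
  a <- generate_slide(spec)
  expect_length(a$annotations, 3L)

  # pixel-count oracle over the generated masks
  ratio <- sum(a$masks$tumour) / sum(a$masks$tissue)
  expect_lt(abs(ratio - 0.3), 0.03)

  # the three annotation polygons are pairwise disjoint (bounding circles)
  cents <- t(vapply(a$annotations, annotation_centroid, numeric(2)))
  radii <- vapply(seq_len(3), function(i)
    max(sqrt((a$annotations[[i]][, 1] - cents[i, 1])^2 +
             (a$annotations[[i]][, 2] - cents[i, 2])^2)), numeric(1))
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(sqrt(sum((cents[i, ] - cents[j, ])^2)), radii[i] + radii[j])
})

test_that("the two classes are separable by the fixed texture statistic", {
  stat_of <- function(cls, seeds) {
    unlist(lapply(seeds, function(s) {
      gen <- small_tumour_slide(cls, s)
      st <- slide_tiles(gen, max_white = 0.05)
      vapply(st$tiles, texture_stat, numeric(1))
    }))
  }
  s_vals <- stat_of("S", 1:3)
  ns_vals <- stat_of("NS", 1:3)
  gap <- abs(mean(s_vals) - mean(ns_vals))
  expect_gt(gap, 5 * max(sd(s_vals), sd(ns_vals)))
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(synthetic_slide_spec(width_px = 500), "width_px")
  expect_error(synthetic_slide_spec(tumour_fraction = 0), "tumour_fraction")
  expect_error(synthetic_slide_spec(tumour_fraction = 1.2), "tumour_fraction")
  expect_error(synthetic_slide_spec(stain_shift = c(0.5, 0, 0)), "stain_shift")
  expect_error(synthetic_slide_spec(noise_sd = -1), "noise_sd")
  expect_error(synthetic_slide_spec(n_fragments = 0), "n_fragments")
})

test_that("cohorts are balanced, on disk, and byte-deterministic", {
  tpl <- synthetic_slide_spec(width_px = 660L, height_px = 660L,
                              n_fragments = 1L, tumour_fraction = 0.5,
                              stain_shift = c(0.1, 0.1, 0.1))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  mp1 <- generate_cohort(2L, d1, tpl, seed = 5L)
  mp2 <- generate_cohort(2L, d2, tpl, seed = 5L)
  m <- read_manifest(mp1)
  expect_equal(nrow(m), 4L)
  expect_equal(as.vector(table(m$class)), c(2L, 2L))
  expect_true(all(file.exists(m$path)))
  expect_true(all(file.exists(m$annotation_path)))
  expect_identical(readLines(mp1), readLines(mp2))
  # slide rasters are byte-identical across runs too
  expect_identical(readBin(m$path[1], "raw", 2e6),
                   readBin(read_manifest(mp2)$path[1], "raw", 2e6))

  # downstream tiling yields tissue tiles for every slide
  for (i in seq_len(nrow(m))) {
    s <- load_slide(m[i, ])
    g <- filter_tiles(build_tile_grid(s), s)
    expect_gt(sum(g$tiles$kept), 0L)
  }
})
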
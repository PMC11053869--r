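test_that("scenes are byte-identical under a fixed seed", {
  p <- dataset_preset("u373_like", seed = 42L)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$instances, s2$instances)
  p2 <- p; p2$seed <- 43L
  expect_false(identical(generate_scene(p2)$image, s1$image))
})

test_that("a fixed count range is honoured exactly", {
  sc <- generate_scene(scene_params(count_range = c(5L, 5L), seed = 3L))
  expect_length(sc$instances, 5L)
  expect_equal(nrow(sc$records), 5L)
})

test_that("unperturbed non-overlapping cells are disjoint ellipses", {
  p <- scene_params(deform = 0, overlap = 0, count_range = c(6L, 6L),
                    radius_range = c(10, 16), seed = 21L)
  sc <- generate_scene(p)
  for (i in seq_along(sc$instances)) {
    for (j in seq_len(i - 1L)) {
      expect_equal(sum(sc$instances[[i]] & sc$instances[[j]]), 0)
    }
  }
  # mask area matches the analytic ellipse area pi*a*b
  for (k in seq_along(sc$instances)) {
    analytic <- pi * sc$records$semi_a[k] * sc$records$semi_b[k]
    expect_lt(abs(sum(sc$instances[[k]]) - analytic) / analytic, 0.03)
  }
})

test_that("instance masks stay within bounds and match their records", {
  sc <- generate_scene(dataset_preset("t24_like", seed = 9L))
  for (k in seq_along(sc$instances)) {
    m <- sc$instances[[k]]
    expect_true(any(m))
    expect_equal(dim(m), c(256L, 256L))
    expect_equal(sc$records$area[k], sum(m))
  }
  # pairwise overlap bounded by the preset's fraction of the smaller mask
  p <- sc$params
  for (i in seq_along(sc$instances)) {
    for (j in seq_len(i - 1L)) {
      inter <- sum(sc$instances[[i]] & sc$instances[[j]])
      smaller <- min(sum(sc$instances[[i]]), sum(sc$instances[[j]]))
      expect_lte(inter, p$overlap * smaller)
    }
  }
})

test_that("presets order by the regimes they emulate", {
  u <- dataset_preset("u373_like")
  g <- dataset_preset("gowt1_like")
  s2 <- dataset_preset("simplus02_like")
  t <- dataset_preset("t24_like")
  expect_gt(g$count_range[1], u$count_range[2])          # many more cells
  expect_lt(g$fg_intensity - g$bg_intensity,
            u$fg_intensity - u$bg_intensity)             # lower contrast
  expect_gte(s2$radius_range[2] / s2$radius_range[1], 3) # high scale variance
  expect_gt(s2$overlap, 0)
  expect_gt(t$overlap, 0)                                 # adherent cells
  expect_error(dataset_preset("nonesuch"))
})

test_that("scene statistics concentrate around preset targets across seeds", {
  p <- dataset_preset("gowt1_like")
  counts <- numeric(60)
  areas <- numeric(60)
  for (s in seq_len(60)) {
    p$seed <- 1000L + s
    sc <- generate_scene(p)
    counts[s] <- length(sc$instances)
    areas[s] <- mean(sc$records$area)
  }
  expect_lt(abs(mean(counts) - mean(p$count_range)) / mean(p$count_range), 0.1)
  # E[pi * a * b] with a, b ~ U(6, 12) independent: pi * 81
  expect_lt(abs(mean(areas) - pi * 81) / (pi * 81), 0.1)
})

test_that("datasets write images, annotations and a deterministic 80/20 split", {
  d <- withr::local_tempdir()
  res <- generate_dataset(scene_params(image_size = 96L, count_range = c(3L, 5L),
                                       seed = 4L), 10L, 4L, d)
  expect_length(res$train, 8L)
  expect_length(res$test, 2L)
  expect_true(file.exists(file.path(d, "annotations.json")))
  expect_length(list.files(d, pattern = "\\.png$"), 10L)
  set <- read_annotations(file.path(d, "annotations.json"))
  n_insts <- sum(vapply(set$images, function(im) {
    length(masks_from_annotations(set, im$id))
  }, numeric(1)))
  expect_equal(n_insts, length(set$annotations))
  # rasterizing the stored polygons reproduces the generated masks
  p1 <- scene_params(image_size = 96L, count_range = c(3L, 5L), seed = 4L)
  p1$seed <- as.integer((4 + 1 * 7919) %% .Machine$integer.max)
  sc1 <- generate_scene(p1)
  back <- masks_from_annotations(set, 1L)
  expect_length(back, length(sc1$instances))
  for (k in seq_along(back)) expect_identical(back[[k]], sc1$instances[[k]])
  # second run with the same seed is identical on disk
  d2 <- withr::local_tempdir()
  generate_dataset(scene_params(image_size = 96L, count_range = c(3L, 5L),
                                seed = 4L), 10L, 4L, d2)
  expect_identical(readLines(file.path(d, "annotations.json")),
                   readLines(file.path(d2, "annotations.json")))
})

test_that("ground truth evaluated against itself scores perfectly", {
  for (preset in c("u373_like", "simplus02_like")) {
    sc <- generate_scene(dataset_preset(preset, seed = 14L))
    gt <- lapply(sc$instances, function(m) list(mask = m, score = 1))
    r <- evaluate_detections(gt, sc$instances)
    expect_equal(unlist(r[c("precision", "recall", "dice", "ap", "dq", "sq",
                            "pq")]),
                 c(precision = 1, recall = 1, dice = 1, ap = 1, dq = 1,
                   sq = 1, pq = 1))
  }
})

test_that("impossible packings raise a packing error", {
  p <- scene_params(image_size = 64L, count_range = c(30L, 30L),
                    radius_range = c(14, 18), overlap = 0, seed = 2L)
  expect_error(generate_scene(p), "packing")
})
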
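test_that("mask IoU counts intersection over union of pixel sets", {
  a <- rect_mask(4, 4, 1:2, 1:2)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, rect_mask(4, 4, 3:4, 3:4)), 0)
  # 2x2 block against the same block shifted one column: 2 / 6
  expect_equal(mask_iou(a, rect_mask(4, 4, 1:2, 2:3)), 1 / 3)
  expect_equal(mask_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
  expect_error(mask_iou(a, matrix(FALSE, 3, 3)), "dimensions")
})

test_that("instance matching is one-to-one and threshold-strict", {
  truths <- list(rect_mask(8, 8, 1:3, 1:3), rect_mask(8, 8, 5:7, 5:7),
                 rect_mask(8, 8, 1:2, 6:7))
  empty <- match_instances(list(), truths)
  expect_equal(c(empty$tp, empty$fp_count, empty$fn_count), c(0L, 0L, 3L))
  perfect <- match_instances(lapply(truths, function(m) list(mask = m, score = 1)),
                             truths)
  expect_equal(c(perfect$tp, perfect$fp_count, perfect$fn_count), c(3L, 0L, 0L))
  expect_true(all(perfect$pairs$iou == 1))
  # two predictions over one truth: only the better one matches
  t1 <- rect_mask(10, 10, 1:10, 1:5)
  p_good <- rect_mask(10, 10, 1:9, 1:5)   # IoU 45/50 = 0.9
  p_bad <- rect_mask(10, 10, 1:10, 2:6)   # IoU 40/60 = 0.667
  tab <- match_instances(list(list(mask = p_good, score = 0.9),
                              list(mask = p_bad, score = 0.8)), list(t1))
  expect_equal(tab$tp, 1L)
  expect_equal(tab$fp_count, 1L)
  expect_equal(tab$pairs$iou, 0.9)
})

test_that("matching at threshold 0.5 agrees with exhaustive optimal assignment", {
  set.seed(99)
  for (trial in 1:12) {
    nt <- sample(1:5, 1)
    np <- sample(1:6, 1)
    truths <- lapply(seq_len(nt), function(i) {
      r0 <- sample(1:12, 1); c0 <- sample(1:12, 1)
      rect_mask(16, 16, r0:min(16, r0 + sample(2:4, 1)),
                c0:min(16, c0 + sample(2:4, 1)))
    })
    preds <- lapply(seq_len(np), function(i) {
      base <- truths[[sample(nt, 1)]]
      shift <- sample(0:2, 1)
      m <- matrix(FALSE, 16, 16)
      idx <- which(base, arr.ind = TRUE)
      idx[, 2] <- pmin(16, idx[, 2] + shift)
      m[idx] <- TRUE
      list(mask = m, score = runif(1))
    })
    tab <- match_instances(preds, truths, 0.5)
    opt <- optimal_matching(lapply(preds, function(p) p$mask), truths, 0.5)
    expect_equal(tab$tp, opt$tp)
    expect_true(all(tab$pairs$iou > 0.5))
    expect_false(anyDuplicated(tab$pairs$prediction) > 0)
    expect_false(anyDuplicated(tab$pairs$truth) > 0)
    # pairings are provably unique only when predictions do not overlap each
    # other (the panoptic setting); check set equality in that case
    masks <- lapply(preds, function(p) p$mask)
    disjoint <- TRUE
    for (i in seq_along(masks)) {
      for (j in seq_len(i - 1L)) {
        if (sum(masks[[i]] & masks[[j]]) > 0) disjoint <- FALSE
      }
    }
    if (disjoint && tab$tp > 0) {
      got <- tab$pairs[order(tab$pairs$prediction), c("prediction", "truth")]
      want <- opt$pairs[order(opt$pairs$prediction), c("prediction", "truth")]
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
    }
  }
})

test_that("precision, recall and Dice follow the count formulas", {
  fake_table <- function(tp, fp, fn) {
    structure(list(tp = tp, fp_count = fp, fn_count = fn, tn_count = 0L),
              class = "match_table")
  }
  r <- precision_recall_dice(fake_table(2L, 1L, 1L))
  expect_equal(unlist(r), c(precision = 2 / 3, recall = 2 / 3, dice = 2 / 3))
  expect_equal(unlist(precision_recall_dice(fake_table(0L, 0L, 0L))),
               c(precision = 0, recall = 0, dice = 0))
  r2 <- precision_recall_dice(fake_table(3L, 1L, 2L))
  expect_equal(r2$dice, 2 / 3)
  # Dice is the harmonic mean of precision and recall when defined
  P <- r2$precision; R <- r2$recall
  expect_equal(r2$dice, 2 * P * R / (P + R))
})

test_that("average precision matches exhaustive threshold enumeration", {
  t1 <- rect_mask(12, 12, 1:4, 1:4)
  t2 <- rect_mask(12, 12, 7:10, 7:10)
  far <- rect_mask(12, 12, 10:12, 1:3)
  # single perfect prediction -> AP 1
  expect_equal(average_precision(list(list(mask = t1, score = 0.7)), list(t1))$ap, 1)
  # [0.9 hit, 0.8 miss, 0.7 hit] over two truths
  preds <- list(list(mask = t1, score = 0.9),
                list(mask = far, score = 0.8),
                list(mask = t2, score = 0.7))
  got <- average_precision(preds, list(t1, t2))
  expect_equal(got$ap, 5 / 6)
  expect_equal(got$ap, ap_by_enumeration(preds, list(t1, t2)))
  # all misses -> AP 0; empty problem -> AP 0
  expect_equal(average_precision(list(list(mask = far, score = 0.5)),
                                 list(t1))$ap, 0)
  expect_equal(average_precision(list(), list())$ap, 0)
  # randomized cross-check against the enumeration oracle
  set.seed(17)
  for (trial in 1:6) {
    truths <- list(t1, t2, rect_mask(12, 12, 5:6, 2:4))
    preds <- lapply(1:5, function(i) {
      m <- truths[[sample(3, 1)]]
      if (runif(1) < 0.4) m <- far
      list(mask = m, score = runif(1))
    })
    expect_equal(average_precision(preds, truths)$ap,
                 ap_by_enumeration(preds, truths), tolerance = 1e-12)
  }
})

test_that("AP is invariant to monotone score transformations", {
  t1 <- rect_mask(12, 12, 1:4, 1:4)
  t2 <- rect_mask(12, 12, 7:10, 7:10)
  far <- rect_mask(12, 12, 10:12, 1:3)
  preds <- list(list(mask = t1, score = 0.9),
                list(mask = far, score = 0.5),
                list(mask = t2, score = 0.2))
  base <- average_precision(preds, list(t1, t2))$ap
  squashed <- lapply(preds, function(p) { p$score <- p$score^3 / 2; p })
  expect_equal(average_precision(squashed, list(t1, t2))$ap, base)
})

test_that("panoptic quality decomposes into DQ x SQ", {
  t1 <- rect_mask(10, 10, 1:10, 1:5)  # 50 px column block
  # prediction covering 40 of the 50 px: IoU = 40/50 = 0.8
  p1 <- rect_mask(10, 10, 1:8, 1:5)
  t2 <- rect_mask(10, 10, 1:2, 9:10)  # missed truth
  fp <- rect_mask(10, 10, 9:10, 8:9)  # stray prediction
  pq <- panoptic_quality(list(list(mask = p1, score = 0.9),
                              list(mask = fp, score = 0.3)),
                         list(t1, t2))
  expect_equal(pq$dq, 0.5)
  expect_equal(pq$sq, 0.8)
  expect_equal(pq$pq, 0.4)
  perfect <- panoptic_quality(list(list(mask = t1, score = 1)), list(t1))
  expect_equal(unlist(perfect), c(pq = 1, dq = 1, sq = 1))
  none <- panoptic_quality(list(), list(t1, t2))
  expect_equal(unlist(none), c(pq = 0, dq = 0, sq = 0))
})

test_that("metrics are invariant to instance ordering", {
  set.seed(5)
  truths <- list(rect_mask(16, 16, 1:4, 1:4), rect_mask(16, 16, 6:9, 6:9),
                 rect_mask(16, 16, 12:15, 2:5))
  preds <- lapply(truths, function(m) list(mask = m, score = runif(1)))
  preds[[4]] <- list(mask = rect_mask(16, 16, 12:14, 12:14), score = 0.5)
  r1 <- evaluate_detections(preds, truths)
  r2 <- evaluate_detections(rev(preds), truths[c(2, 3, 1)])
  for (nm in c("precision", "recall", "dice", "ap", "dq", "sq", "pq")) {
    expect_equal(r1[[nm]], r2[[nm]], info = nm)
  }
  expect_equal(r1$pq, r1$dq * r1$sq, tolerance = 1e-12)
  expect_lte(r1$pq, r1$dq)
})

test_that("pixel Dice averages per-match overlap", {
  t1 <- rect_mask(10, 10, 1:10, 1:5)
  p1 <- rect_mask(10, 10, 1:8, 1:5)   # 2*40/(40+50)
  expect_equal(pixel_dice(list(list(mask = p1, score = 1)), list(t1)),
               80 / 90)
  expect_equal(pixel_dice(list(), list(t1)), 0)
})

test_that("reports serialize to JSON and TSV", {
  t1 <- rect_mask(8, 8, 1:3, 1:3)
  rep <- evaluate_detections(list(list(mask = t1, score = 1)), list(t1))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_report(rep, jf, tf)
  j <- jsonlite::read_json(jf)
  expect_equal(j$pq, 1)
  tab <- read.delim(tf)
  expect_true(all(c("precision", "pq") %in% tab$metric))
})
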
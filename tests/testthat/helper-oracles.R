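# Independent reference implementations used to verify the package's fast
# paths.  These are deliberately naive (loops, exhaustive enumeration) and
# share no code with the implementation under test.

# Plain dense convolution, cross-correlation convention, same padding
# pad = r*(K-1)/2, in pure R loops.  wfull: K x K x C x N.
conv_ref <- function(x, wfull, bias, K, r = 1L, stride = 1L) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(wfull)[4]
  pad <- r * (K - 1L) %/% 2L
  Ho <- (H - 1L) %/% stride + 1L
  Wo <- (W - 1L) %/% stride + 1L
  out <- array(0, dim = c(Ho, Wo, N))
  for (f in seq_len(N)) {
    for (oi in seq_len(Ho)) {
      for (oj in seq_len(Wo)) {
        acc <- bias[f]
        for (c in seq_len(C)) {
          for (ki in seq_len(K)) {
            for (kj in seq_len(K)) {
              xi <- (oi - 1L) * stride - pad + (ki - 1L) * r + 1L
              xj <- (oj - 1L) * stride - pad + (kj - 1L) * r + 1L
              if (xi >= 1L && xi <= H && xj >= 1L && xj <= W) {
                acc <- acc + x[xi, xj, c] * wfull[ki, kj, c, f]
              }
            }
          }
        }
        out[oi, oj, f] <- acc
      }
    }
  }
  out
}

# Exhaustive optimal one-to-one assignment: maximize the number of matched
# pairs with IoU > threshold, breaking ties by total IoU.  Feasible up to
# ~6 x 6 instances.
optimal_matching <- function(pred_masks, truth_masks, thr = 0.5) {
  np <- length(pred_masks); nt <- length(truth_masks)
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) iou[i, j] <- mask_iou(pred_masks[[i]], truth_masks[[j]])
  }
  best <- list(tp = -1, iou_sum = -1, pairs = NULL)
  recurse <- function(i, taken, pairs) {
    if (i > np) {
      tp <- nrow(pairs)
      s <- if (tp) sum(pairs$iou) else 0
      if (tp > best$tp || (tp == best$tp && s > best$iou_sum)) {
        best <<- list(tp = tp, iou_sum = s, pairs = pairs)
      }
      return(invisible())
    }
    recurse(i + 1L, taken, pairs)  # leave prediction i unmatched
    for (j in seq_len(nt)) {
      if (!taken[j] && iou[i, j] > thr) {
        taken[j] <- TRUE
        recurse(i + 1L, taken,
                rbind(pairs, data.frame(prediction = i, truth = j, iou = iou[i, j])))
        taken[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nt),
          data.frame(prediction = integer(), truth = integer(), iou = numeric()))
  best
}

# Average precision by exhaustive enumeration of score cutoffs: at every
# distinct score, evaluate the retained predictions with the optimal
# assignment, collect (recall, precision), monotonize precision and
# integrate over recall (all-point interpolation).
ap_by_enumeration <- function(preds, truth_masks, thr = 0.5) {
  scores <- sort(unique(vapply(preds, function(p) p$score, numeric(1))),
                 decreasing = TRUE)
  nt <- length(truth_masks)
  pts <- data.frame(recall = numeric(), precision = numeric())
  for (s in scores) {
    keep <- Filter(function(p) p$score >= s, preds)
    m <- optimal_matching(lapply(keep, function(p) p$mask), truth_masks, thr)
    tp <- m$tp
    pts <- rbind(pts, data.frame(recall = tp / nt,
                                 precision = tp / length(keep)))
  }
  pts <- pts[order(pts$recall, -pts$precision), ]
  # monotonized precision envelope, rectangle integration over recall
  ap <- 0; prev_r <- 0
  for (k in seq_len(nrow(pts))) {
    p_max <- max(pts$precision[k:nrow(pts)])
    ap <- ap + (pts$recall[k] - prev_r) * p_max
    prev_r <- pts$recall[k]
  }
  ap
}

# Small rectangular mask helper: rows/cols are 1-based inclusive ranges.
rect_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# Easy, well-separated bright-blob scenes used for smoke training.
easy_scene_params <- function(seed, image_size = 128L) {
  scene_params(image_size = image_size, count_range = c(4L, 7L),
               radius_range = c(8, 16), deform = 0.05, overlap = 0,
               fg_intensity = 200, bg_intensity = 30, noise_sd = 5,
               blur_sigma = 1, seed = seed)
}

smoke_train_config <- function(max_epochs = 3L, seed = 1L) {
  train_config(initial_lr = 0.1, max_epochs = max_epochs, seed = seed)
}
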
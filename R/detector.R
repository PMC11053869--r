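#' Training configuration
#'
#' SGD-with-momentum schedule: the learning rate at (0-based) epoch `e` is
#' `initial_lr * lr_decay_factor^floor(e / 10)`.  Defaults follow the
#' Mask R-DHCNN recipe (initial rate 0.001 decayed by 0.1 every 10 epochs,
#' weight decay 5e-4, 50 epochs).
#'
#' @param initial_lr Initial learning rate.
#' @param lr_decay_factor Multiplicative decay applied every 10 epochs.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 weight decay.
#' @param max_epochs Number of training epochs.
#' @param seed Integer seed controlling shuffling and initialization.
#' @return A `train_config` object.
#' @export
train_config <- function(initial_lr = 0.001, lr_decay_factor = 0.1,
                         momentum = 0.9, weight_decay = 5e-4,
                         max_epochs = 50L, seed = 1L) {
  structure(list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 momentum = momentum, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' @param config A [train_config()].
#' @param epoch 0-based epoch index.
#' @return The scheduled learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$initial_lr * config$lr_decay_factor^(epoch %/% 10L)
}

#' Build a compact Mask R-DHCNN cell detector
#'
#' Constructs a small fully convolutional detector whose backbone 3x3
#' convolutions are passed through [convert_backbone()] under `policy`
#' (default `P = 1/4`, `r = 2`), in the same way the full-size recipe rewrites
#' a ResNet-50-FPN Mask R-CNN backbone.  The network is a stem convolution
#' (never converted), `depth` convertible 3x3 blocks with ReLU, and two 1x1
#' heads: an objectness head scoring cell centres and a foreground head
#' producing the segmentation map.  Instances are extracted at prediction
#' time as connected components of the thresholded foreground map, scored by
#' the objectness head.  All weights are seeded and trainable with [train()].
#'
#' @param num_classes Total classes including background; only 2 (background +
#'   cell) is supported.
#' @param policy A [conversion_policy()]; use `p_fraction = 1,
#'   dilation_rate = 1` for the unconverted baseline.
#' @param config A [train_config()]; its seed fixes the initialization.
#' @param channels Feature channels in the backbone (must be divisible by
#'   `1 / p_fraction`).
#' @param depth Number of convertible 3x3 blocks after the stem.
#' @return A `mask_rdhcnn` object.
#' @export
build_mask_rdhcnn <- function(num_classes = 2L, policy = conversion_policy(),
                              config = train_config(), channels = 8L,
                              depth = 2L) {
  if (num_classes != 2L) {
    stop("only num_classes = 2 (background + cell) is supported", call. = FALSE)
  }
  seed <- config$seed
  mk <- function(name, role, spec, off, bias_init = 0) {
    list(name = name, role = role,
         kind = if (spec$p_fraction < 1 || spec$dilation_rate > 1L) "dhconv" else "conv",
         in_channels = spec$in_channels, out_channels = spec$out_channels,
         kernel_size = spec$kernel_size, stride = spec$stride,
         dilation_rate = spec$dilation_rate, p_fraction = spec$p_fraction,
         spec = spec, weights = dhconv_init(spec, seed = seed + off, bias_init))
  }
  layers <- list(mk("stem", "stem", dhconv_spec(3L, channels, 3L), 101L))
  for (d in seq_len(depth)) {
    layers[[length(layers) + 1L]] <-
      mk(sprintf("block%d.conv", d), "bottleneck",
         dhconv_spec(channels, channels, 3L), 101L + d)
  }
  backbone <- structure(list(name = "compact", layers = layers),
                        class = "dhcnn_backbone")
  conv <- convert_backbone(backbone, policy)
  heads <- list(
    obj = mk("head.obj", "head", dhconv_spec(channels, 1L, 1L), 301L, bias_init = -2),
    fg  = mk("head.fg",  "head", dhconv_spec(channels, 1L, 1L), 302L, bias_init = -2))
  structure(list(backbone = conv$backbone, heads = heads,
                 conversion_report = conv$report, policy = policy,
                 config = config, num_classes = 2L,
                 mask_threshold = 0.5,
                 trained_epochs = 0L, loss_history = numeric(0)),
            class = "mask_rdhcnn")
}

#' @export
print.mask_rdhcnn <- function(x, ...) {
  cat("Compact Mask R-DHCNN cell detector\n")
  cat(sprintf("  backbone layers : %d (%d converted to DHConv, P=%s, r=%d)\n",
              length(x$backbone$layers), nrow(x$conversion_report),
              format(x$policy$p_fraction), x$policy$dilation_rate))
  cat(sprintf("  parameters      : %d\n", as.integer(model_param_count(x))))
  cat(sprintf("  trained epochs  : %d\n", x$trained_epochs))
  if (length(x$loss_history)) {
    cat(sprintf("  last epoch loss : %.5f\n", tail(x$loss_history, 1L)))
  }
  invisible(x)
}

#' @export
summary.mask_rdhcnn <- function(object, ...) {
  print(object)
  if (nrow(object$conversion_report)) {
    cat("\nConverted layers:\n")
    print(object$conversion_report, row.names = FALSE)
  }
  invisible(object)
}

#' Total trainable parameter count of a detector
#' @param model A `mask_rdhcnn`.
#' @return Numeric count.
#' @export
model_param_count <- function(model) {
  ls <- c(model$backbone$layers, model$heads)
  sum(vapply(ls, function(l) dhconv_param_count(l$spec), numeric(1)))
}

#' Backbone description of a detector (for FLOPs accounting)
#' @param model A `mask_rdhcnn`.
#' @return A `dhcnn_backbone` including the head convolutions.
#' @export
model_description <- function(model) {
  structure(list(name = "mask_rdhcnn",
                 layers = c(model$backbone$layers, unname(model$heads))),
            class = "dhcnn_backbone")
}

# Forward pass through backbone + heads; optionally cache activations for
# backprop.  Input: H x W x 3 array of intensities in [0, 1].
model_forward <- function(model, x, cache = FALSE) {
  x <- as_feature_map(x) - 0.5
  acts <- list()
  inputs <- list()
  h <- x
  for (i in seq_along(model$backbone$layers)) {
    ly <- model$backbone$layers[[i]]
    inputs[[i]] <- h
    z <- apply_dhconv(h, ly$weights, ly$spec)
    h <- pmax(z, 0)
    acts[[i]] <- z
  }
  obj <- apply_dhconv(h, model$heads$obj$weights, model$heads$obj$spec)
  fg <- apply_dhconv(h, model$heads$fg$weights, model$heads$fg$spec)
  out <- list(obj_logit = obj[, , 1L], fg_logit = fg[, , 1L])
  if (cache) {
    out$inputs <- inputs
    out$preacts <- acts
    out$features <- h
  }
  out
}

#' Train a model
#'
#' Generic; see [train.mask_rdhcnn()].
#' @param model Model object.
#' @param dataset Training data.
#' @param config A [train_config()].
#' @param ... Method-specific arguments.
#' @export
train <- function(model, dataset, config = NULL, ...) UseMethod("train")

#' Train the compact detector with SGD
#'
#' Per-image stochastic gradient descent with momentum on the summed
#' binary-cross-entropy losses of the two heads: the foreground head is
#' supervised by the union of the instance masks, the objectness head by
#' discs of radius 3 px around each instance centroid.  The epoch order of
#' samples is a seeded shuffle; the learning rate follows [lr_at_epoch()].
#'
#' @param model A `mask_rdhcnn`.
#' @param dataset List of samples, each `list(image = H x W (x 3) array in
#'   [0, 1], masks = list of logical matrices)`, e.g. from
#'   [scenes_to_dataset()].
#' @param config A [train_config()]; defaults to the model's own.
#' @param ... Unused.
#' @return The trained model, with `loss_history` holding one mean loss per
#'   epoch.
#' @export
train.mask_rdhcnn <- function(model, dataset, config = NULL, ...) {
  if (is.null(config)) config <- model$config
  if (length(dataset) == 0L) stop("empty training dataset", call. = FALSE)
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(config$seed + 7L)
  state <- init_momentum(model)
  history <- numeric(config$max_epochs)
  for (epoch in seq_len(config$max_epochs) - 1L) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample.int(length(dataset))
    losses <- numeric(length(dataset))
    for (k in seq_along(ord)) {
      smp <- dataset[[ord[k]]]
      tgt <- sample_targets(smp)
      fw <- model_forward(model, smp$image, cache = TRUE)
      l_fg <- bce_loss(fw$fg_logit, tgt$fg, balanced = TRUE)
      l_obj <- bce_loss(fw$obj_logit, tgt$obj, balanced = TRUE)
      loss <- l_fg$loss + l_obj$loss
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, ", sample ", ord[k],
             " (fg = ", format(l_fg$loss), ", obj = ", format(l_obj$loss), ")",
             call. = FALSE)
      }
      losses[k] <- loss
      grads <- model_backward(model, fw, l_fg$grad, l_obj$grad)
      upd <- sgd_step(model, grads, state, lr, config)
      model <- upd$model
      state <- upd$state
    }
    history[epoch + 1L] <- mean(losses)
  }
  model$loss_history <- c(model$loss_history, history)
  model$trained_epochs <- model$trained_epochs + config$max_epochs
  model$config <- config
  model
}

#' Detect cell instances in an image
#'
#' Runs the detector, thresholds the foreground probability map at the
#' model's mask threshold (0.5), labels connected components as instances and
#' scores each by the peak objectness probability it contains.  Results are
#' sorted by descending score; only scores at or above `score_threshold` are
#' returned.
#'
#' @param object A `mask_rdhcnn`.
#' @param image `H x W` matrix or `H x W x 3` array of intensities in [0, 1];
#'   both dimensions must be at least 32 px.
#' @param score_threshold Minimum confidence in [0, 1].
#' @param ... Unused.
#' @return List of detections, each `list(mask, box, score, label)`; `box` is
#'   the tight `c(x, y, w, h)` bounding box of the mask, 0-based half-open.
#' @export
predict.mask_rdhcnn <- function(object, image, score_threshold = 0.5, ...) {
  image <- to_rgb(image)
  if (dim(image)[1] < 32L || dim(image)[2] < 32L) {
    stop("image must be at least 32 x 32 pixels, got ",
         dim(image)[1], " x ", dim(image)[2], call. = FALSE)
  }
  fw <- model_forward(object, image)
  fg <- sigmoid(fw$fg_logit)
  obj <- sigmoid(fw$obj_logit)
  bin <- fg > object$mask_threshold
  if (!any(bin)) return(list())
  lab <- EBImage::bwlabel(bin)
  dets <- list()
  for (id in seq_len(max(lab))) {
    mask <- lab == id
    if (!any(mask)) next
    score <- max(obj[mask])
    if (score < score_threshold) next
    dets[[length(dets) + 1L]] <- detection_result(mask, score)
  }
  dets[order(-vapply(dets, function(d) d$score, numeric(1)))]
}

#' Construct a detection result
#'
#' @param mask Nonempty logical matrix.
#' @param score Confidence in [0, 1].
#' @param label Category id.
#' @return A `detection_result`: list(mask, box, score, label) where `box` is
#'   the mask's tight bounding box `c(x, y, w, h)`, 0-based half-open.
#' @export
detection_result <- function(mask, score, label = 1L) {
  if (!any(mask)) stop("detection mask must be nonempty", call. = FALSE)
  structure(list(mask = mask, box = mask_bbox(mask), score = score,
                 label = as.integer(label)),
            class = "detection_result")
}

#' Tight bounding box of a binary mask
#' @param mask Logical matrix.
#' @return `c(x, y, w, h)`, 0-based half-open pixel units.
#' @export
mask_bbox <- function(mask) {
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  c(x = cols[1] - 1, y = rows[1] - 1,
    w = cols[2] - cols[1] + 1, h = rows[2] - rows[1] + 1)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are serialized with R's native format and restore to a model
#' producing identical predictions.
#'
#' @param model A `mask_rdhcnn`.
#' @param path File path.
#' @return `save_checkpoint` the path, invisibly; `load_checkpoint` the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mask_rdhcnn"))
  model
}

#' Convert synthetic scenes to a training dataset
#'
#' @param scenes List of [generate_scene()] results.
#' @return List of samples usable by [train.mask_rdhcnn()] and evaluation.
#' @export
scenes_to_dataset <- function(scenes) {
  lapply(scenes, function(sc) {
    list(image = to_rgb(sc$image), masks = sc$instances)
  })
}

# ---- internal ---------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

to_rgb <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  if (length(dim(image)) != 3L || !dim(image)[3] %in% c(1L, 3L)) {
    stop("image must be H x W or H x W x 3", call. = FALSE)
  }
  if (dim(image)[3] == 1L) {
    image <- array(rep(image[, , 1L], 3L), dim = c(dim(image)[1:2], 3L))
  }
  image
}

# Class-balanced binary cross-entropy over pixels, with gradient w.r.t. the
# logits.  With balanced = TRUE the positive and negative pixels receive equal
# total weight regardless of their frequency, the standard correction for the
# heavy foreground/background imbalance of dense detection targets.
bce_loss <- function(logit, target, balanced = FALSE) {
  p <- sigmoid(logit)
  eps <- 1e-7
  n <- length(p)
  if (balanced) {
    npos <- sum(target > 0)
    if (npos > 0 && npos < n) {
      w <- ifelse(target > 0, n / (2 * npos), n / (2 * (n - npos)))
    } else {
      w <- rep(1, n); dim(w) <- dim(p)
    }
  } else {
    w <- 1
  }
  loss <- -sum(w * (target * log(p + eps) + (1 - target) * log(1 - p + eps))) / n
  list(loss = loss, grad = w * (p - target) / n)
}

# Supervision targets: foreground = union of instance masks; objectness =
# discs of radius 3 around instance centroids.
sample_targets <- function(smp) {
  dims <- dim(smp$image)[1:2]
  fg <- matrix(0, dims[1], dims[2])
  obj <- matrix(0, dims[1], dims[2])
  for (m in smp$masks) {
    fg[m] <- 1
    idx <- which(m, arr.ind = TRUE)
    cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
    rr <- pmax(1L, round(cy) + (-3:3)); rr <- rr[rr <= dims[1]]
    cc <- pmax(1L, round(cx) + (-3:3)); cc <- cc[cc <= dims[2]]
    for (j in cc) {
      for (i in rr) {
        if ((i - cy)^2 + (j - cx)^2 <= 9) obj[i, j] <- 1
      }
    }
  }
  list(fg = fg, obj = obj)
}

layer_backward <- function(ly, input, gout) {
  cpp_dhconv_backward(input, dim(input), gout, ly$weights$large,
                      ly$weights$point, ly$weights$mask,
                      ly$spec$kernel_size, ly$spec$dilation_rate,
                      ly$spec$stride, ly$spec$use_bias, ly$spec$out_channels)
}

model_backward <- function(model, fw, g_fg, g_obj) {
  H <- nrow(g_fg); W <- ncol(g_fg)
  bo <- layer_backward(model$heads$obj, fw$features,
                       array(g_obj, dim = c(H, W, 1L)))
  bf <- layer_backward(model$heads$fg, fw$features,
                       array(g_fg, dim = c(H, W, 1L)))
  g <- bo$gx + bf$gx
  nb <- length(model$backbone$layers)
  bgrads <- vector("list", nb)
  for (i in rev(seq_len(nb))) {
    g <- g * (fw$preacts[[i]] > 0)          # ReLU gate
    bb <- layer_backward(model$backbone$layers[[i]], fw$inputs[[i]], g)
    bgrads[[i]] <- bb[c("gwl", "gwp", "gbias")]
    g <- bb$gx
  }
  list(backbone = bgrads,
       heads = list(obj = bo[c("gwl", "gwp", "gbias")],
                    fg = bf[c("gwl", "gwp", "gbias")]))
}

zero_like_weights <- function(w) {
  list(gwl = array(0, dim = dim(w$large)),
       gwp = matrix(0, nrow = nrow(w$point), ncol = ncol(w$point)),
       gbias = numeric(length(w$bias)))
}

init_momentum <- function(model) {
  list(backbone = lapply(model$backbone$layers,
                         function(l) zero_like_weights(l$weights)),
       heads = lapply(model$heads, function(l) zero_like_weights(l$weights)))
}

update_layer <- function(ly, g, v, lr, config) {
  wd <- config$weight_decay
  mom <- config$momentum
  v$gwl <- mom * v$gwl - lr * (g$gwl + wd * ly$weights$large)
  v$gwp <- mom * v$gwp - lr * (g$gwp + wd * ly$weights$point)
  v$gbias <- mom * v$gbias - lr * g$gbias
  ly$weights$large <- ly$weights$large + v$gwl
  ly$weights$point <- ly$weights$point + v$gwp
  ly$weights$bias <- ly$weights$bias + v$gbias
  list(layer = ly, v = v)
}

sgd_step <- function(model, grads, state, lr, config) {
  for (i in seq_along(model$backbone$layers)) {
    u <- update_layer(model$backbone$layers[[i]], grads$backbone[[i]],
                      state$backbone[[i]], lr, config)
    model$backbone$layers[[i]] <- u$layer
    state$backbone[[i]] <- u$v
  }
  for (nm in names(model$heads)) {
    u <- update_layer(model$heads[[nm]], grads$heads[[nm]],
                      state$heads[[nm]], lr, config)
    model$heads[[nm]] <- u$layer
    state$heads[[nm]] <- u$v
  }
  list(model = model, state = state)
}
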
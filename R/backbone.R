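#' Conversion policy for DHConv backbone surgery
#'
#' Names which convolutions of a backbone are rewritten as DHConv layers and
#' with what parameters.  The default mirrors the Mask R-DHCNN recipe: every
#' 3x3 convolution inside a residual bottleneck block is converted with
#' `P = 1/4` (one large kernel per four channels) and dilation rate 2; the
#' stem, 1x1 convolutions and downsample projections are never touched, and
#' strides are always preserved.
#'
#' @param p_fraction Fraction of large kernels per filter, in (0, 1].
#' @param dilation_rate Dilation applied to the surviving large kernels.
#' @param target_selector Function `layer -> logical`: should this layer be
#'   converted?  The default selects `role == "bottleneck"` convolutions with
#'   `kernel_size == 3`.
#' @return A `conversion_policy` object.
#' @export
conversion_policy <- function(p_fraction = 1 / 4, dilation_rate = 2L,
                              target_selector = NULL) {
  check_p_fraction(p_fraction)
  stopifnot_count(dilation_rate, "dilation_rate")
  if (is.null(target_selector)) {
    target_selector <- function(layer) {
      identical(layer$role, "bottleneck") && layer$kind == "conv" &&
        layer$kernel_size == 3L
    }
  }
  structure(list(p_fraction = p_fraction,
                 dilation_rate = as.integer(dilation_rate),
                 target_selector = target_selector,
                 preserve_stride = TRUE),
            class = "conversion_policy")
}

#' ResNet-50 backbone description
#'
#' Structural description (no weights) of the ResNet-50 convolutional trunk:
#' a 7x7/2 stem, a 3x3/2 max-pool, and four bottleneck stages of 3, 4, 6 and 3
#' blocks.  Each bottleneck holds a 1x1 reduce, a 3x3 (stride 2 in the first
#' block of stages 3-5), and a 1x1 expand convolution; the first block of each
#' stage carries a 1x1 downsample projection.  Used by [count_model_flops()]
#' and [convert_backbone()].
#'
#' @param in_channels Image channels fed to the stem.
#' @return A `dhcnn_backbone` object (list of layer records).
#' @export
resnet50_backbone <- function(in_channels = 3L) {
  conv <- function(name, role, cin, cout, k, s = 1L) {
    list(name = name, role = role, kind = "conv",
         in_channels = as.integer(cin), out_channels = as.integer(cout),
         kernel_size = as.integer(k), stride = as.integer(s),
         dilation_rate = 1L, p_fraction = 1)
  }
  layers <- list(
    conv("stem.conv1", "stem", in_channels, 64L, 7L, 2L),
    list(name = "stem.maxpool", role = "stem", kind = "pool",
         kernel_size = 3L, stride = 2L))
  cfg <- list(list(stage = 2L, blocks = 3L, mid = 64L, out = 256L, stride = 1L),
              list(stage = 3L, blocks = 4L, mid = 128L, out = 512L, stride = 2L),
              list(stage = 4L, blocks = 6L, mid = 256L, out = 1024L, stride = 2L),
              list(stage = 5L, blocks = 3L, mid = 512L, out = 2048L, stride = 2L))
  cin <- 64L
  for (st in cfg) {
    for (b in seq_len(st$blocks)) {
      pre <- sprintf("layer%d.block%d", st$stage - 1L, b)
      s <- if (b == 1L) st$stride else 1L
      layers <- c(layers, list(
        conv(paste0(pre, ".conv1"), "bottleneck", cin, st$mid, 1L),
        conv(paste0(pre, ".conv2"), "bottleneck", st$mid, st$mid, 3L, s),
        conv(paste0(pre, ".conv3"), "bottleneck", st$mid, st$out, 1L)))
      if (b == 1L) {
        layers <- c(layers, list(
          conv(paste0(pre, ".downsample"), "downsample", cin, st$out, 1L, s)))
      }
      cin <- st$out
    }
  }
  structure(list(name = "resnet50", layers = layers), class = "dhcnn_backbone")
}

#' @export
print.dhcnn_backbone <- function(x, ...) {
  kinds <- vapply(x$layers, function(l) l$kind, "")
  cat(sprintf("Backbone '%s': %d layers (%d conv, %d dhconv, %d other)\n",
              x$name %||% "backbone", length(x$layers), sum(kinds == "conv"),
              sum(kinds == "dhconv"), sum(!kinds %in% c("conv", "dhconv"))))
  invisible(x)
}

#' Convert a backbone's convolutions to DHConv
#'
#' Rewrites every layer matched by the policy's selector as a DHConv layer
#' with the same channel counts and stride and the policy's `p_fraction` and
#' `dilation_rate`.  When a matched layer carries weights, they are copied:
#' large-kernel slots keep the original K x K kernel for that channel, and
#' pointwise slots take the original kernel's centre tap, so a policy of
#' `P = 1, r = 1` reproduces the original layer exactly.
#'
#' @param backbone A `dhcnn_backbone` (description or runnable, see
#'   [resnet50_backbone()] and [build_mask_rdhcnn()]).
#' @param policy A [conversion_policy()].
#' @return List with `backbone` (converted) and `report`, a data frame of the
#'   replaced layers with before/after parameter and FLOP counts (FLOPs per
#'   output pixel; multiply by the layer's output area for absolute counts).
#' @export
convert_backbone <- function(backbone, policy = conversion_policy()) {
  stopifnot(inherits(policy, "conversion_policy"))
  layers <- backbone_layers(backbone)
  inv_p <- as.integer(round(1 / policy$p_fraction))
  rows <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (!isTRUE(policy$target_selector(ly))) next
    if (ly$in_channels %% inv_p != 0L) {
      stop("cannot convert layer '", ly$name,
           "': in_channels = ", ly$in_channels,
           " is not divisible by 1/P = ", inv_p, call. = FALSE)
    }
    before_spec <- layer_spec(ly)
    new <- ly
    new$kind <- "dhconv"
    new$p_fraction <- policy$p_fraction
    new$dilation_rate <- policy$dilation_rate
    new$spec <- NULL                      # force re-derivation from the fields
    after_spec <- layer_spec(new)
    if (!is.null(ly$spec) || !is.null(ly$weights)) new$spec <- after_spec
    if (!is.null(ly$weights)) {
      new$weights <- convert_weights(ly, after_spec)
    }
    layers[[i]] <- new
    pb <- dhconv_param_count(before_spec)
    pa <- dhconv_param_count(after_spec)
    fb <- flops_standard(1, 1, ly$out_channels, ly$kernel_size, ly$in_channels)
    fa <- flops_het(1, 1, ly$out_channels, ly$kernel_size, ly$in_channels,
                    policy$p_fraction)$het_flops
    rows[[length(rows) + 1L]] <- data.frame(
      name = ly$name, kernel_size = ly$kernel_size,
      p_fraction = policy$p_fraction, dilation_rate = policy$dilation_rate,
      params_before = pb, params_after = pa,
      flops_before = fb, flops_after = fa, stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), kernel_size = integer(),
               p_fraction = numeric(), dilation_rate = integer(),
               params_before = numeric(), params_after = numeric(),
               flops_before = numeric(), flops_after = numeric())
  out <- if (inherits(backbone, "dhcnn_backbone")) {
    backbone$layers <- layers
    backbone
  } else layers
  list(backbone = out, report = report)
}

#' Total parameter count of a backbone
#'
#' Sums [dhconv_param_count()] over all convolutional layers of a backbone
#' description; non-convolution layers contribute zero.
#'
#' @param backbone A `dhcnn_backbone` or list of layer records.
#' @return Numeric parameter count.
#' @export
backbone_param_count <- function(backbone) {
  sum(vapply(backbone_layers(backbone), function(ly) {
    if (ly$kind %in% c("conv", "dhconv")) dhconv_param_count(layer_spec(ly)) else 0
  }, numeric(1)))
}

# ---- internal ---------------------------------------------------------------

layer_spec <- function(ly) {
  if (!is.null(ly$spec)) return(ly$spec)
  dhconv_spec(ly$in_channels, ly$out_channels, ly$kernel_size,
              ly$dilation_rate %||% 1L,
              if (ly$kind == "dhconv") ly$p_fraction %||% 1 else 1,
              ly$stride %||% 1L)
}

convert_weights <- function(ly, after_spec) {
  old <- ly$weights
  K <- after_spec$kernel_size
  ctr <- (K + 1L) %/% 2L
  w <- list(large = array(0, dim = dim(old$large)),
            point = matrix(0, nrow = after_spec$in_channels,
                           ncol = after_spec$out_channels),
            bias = old$bias,
            mask = build_layout(after_spec))
  for (f in seq_len(after_spec$out_channels)) {
    for (c in seq_len(after_spec$in_channels)) {
      if (w$mask[c, f] == 1L) {
        w$large[, , c, f] <- old$large[, , c, f]
      } else {
        w$point[c, f] <- old$large[ctr, ctr, c, f]
      }
    }
  }
  w
}
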
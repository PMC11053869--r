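#' Effective extent of a dilated convolution kernel
#'
#' A `base_size` x `base_size` kernel dilated with rate `dilation_rate` samples
#' the input on a grid spanning `(base_size - 1) * dilation_rate + 1` pixels per
#' side.  Dilation rate 1 is ordinary convolution, so the extent equals the
#' base size.
#'
#' @param base_size Odd positive integer, the number of taps per kernel side
#'   (`K`).
#' @param dilation_rate Positive integer spacing between taps (`r`).
#' @return Positive integer, the effective kernel side in pixels.
#' @examples
#' dilated_kernel_extent(3, 2)  # 5
#' dilated_kernel_extent(5, 3)  # 13
#' @export
dilated_kernel_extent <- function(base_size, dilation_rate) {
  stopifnot_count(base_size, "base_size")
  stopifnot_count(dilation_rate, "dilation_rate")
  as.integer((base_size - 1L) * dilation_rate + 1L)
}

#' FLOPs of a standard convolution layer
#'
#' Multiply--accumulate count of an ordinary dense convolution producing an
#' `out_w` x `out_h` x `n_filters` output from `in_channels` input channels
#' with square `kernel_size` kernels:
#' `out_w * out_h * n_filters * kernel_size^2 * in_channels`.
#' One FLOP is one multiply--accumulate; biases are excluded.
#'
#' @param out_w,out_h Output spatial dimensions in pixels.
#' @param n_filters Number of filters (output channels, `N`).
#' @param kernel_size Kernel side (`K`).
#' @param in_channels Input channels (`C`).
#' @return Numeric count of multiply--accumulates.
#' @export
flops_standard <- function(out_w, out_h, n_filters, kernel_size, in_channels) {
  for (a in list(out_w = out_w, out_h = out_h, n_filters = n_filters,
                 kernel_size = kernel_size, in_channels = in_channels)) {
    stopifnot_count(a, "argument")
  }
  as.numeric(out_w) * out_h * n_filters * kernel_size^2 * in_channels
}

#' FLOPs of a heterogeneous convolution layer
#'
#' Cost of a layer whose filters carry a fraction `p_fraction` of full
#' `kernel_size` x `kernel_size` kernels and `1 - p_fraction` pointwise 1x1
#' kernels.  The large-kernel branch costs `flops_standard(...) * P` and the
#' pointwise branch `out_w * out_h * in_channels * (N - N * P)`.  Dilation of
#' the large kernels changes no count: the inserted holes carry no weights.
#'
#' @inheritParams flops_standard
#' @param p_fraction Fraction of large kernels per filter, in (0, 1].  Both
#'   `n_filters * p_fraction` and `in_channels * p_fraction` must be whole
#'   numbers (a filter holds an integer number of large kernels).
#' @return A `layer_cost` object: list with `standard_flops`,
#'   `large_kernel_flops`, `pointwise_flops`, `het_flops` and `ratio`.
#' @examples
#' flops_het(4, 4, 2, 3, 8, 1 / 4)
#' @export
flops_het <- function(out_w, out_h, n_filters, kernel_size, in_channels, p_fraction) {
  std <- flops_standard(out_w, out_h, n_filters, kernel_size, in_channels)
  check_p_fraction(p_fraction)
  if (!is_whole(in_channels * p_fraction)) {
    stop("p_fraction must allocate a whole number of large kernels per ",
         "filter: in_channels * p_fraction must be an integer", call. = FALSE)
  }
  large <- std * p_fraction
  point <- as.numeric(out_w) * out_h * in_channels * (n_filters - n_filters * p_fraction)
  structure(
    list(standard_flops = std,
         large_kernel_flops = large,
         pointwise_flops = point,
         het_flops = large + point,
         ratio = (large + point) / std),
    class = "layer_cost")
}

#' @export
print.layer_cost <- function(x, ...) {
  cat("Heterogeneous convolution layer cost (multiply-accumulates)\n")
  cat(sprintf("  standard     : %s\n", format(x$standard_flops, big.mark = ",")))
  cat(sprintf("  large-kernel : %s\n", format(x$large_kernel_flops, big.mark = ",")))
  cat(sprintf("  pointwise    : %s\n", format(x$pointwise_flops, big.mark = ",")))
  cat(sprintf("  heterogeneous: %s  (ratio %.6f)\n",
              format(x$het_flops, big.mark = ","), x$ratio))
  invisible(x)
}

#' Cost ratio of heterogeneous versus standard convolution
#'
#' Closed form `P + (1 - P) / K^2`: the fraction of the standard layer's
#' multiply--accumulates a heterogeneous layer performs.  Equals 1 exactly when
#' `p_fraction` is 1; for `P = 1/4, K = 3` it is 1/3, i.e. a two-thirds cost
#' reduction.
#'
#' @param p_fraction Fraction of large kernels per filter, in (0, 1].
#' @param kernel_size Kernel side (`K`), positive integer.
#' @return The ratio as a double (exact for rational inputs up to floating
#'   point).
#' @export
flops_ratio <- function(p_fraction, kernel_size) {
  check_p_fraction(p_fraction)
  stopifnot_count(kernel_size, "kernel_size")
  p_fraction + (1 - p_fraction) / kernel_size^2
}

#' Per-layer and total FLOPs of a backbone description
#'
#' Walks a backbone (see [resnet50_backbone()]), propagating spatial
#' dimensions through the same-padding/stride contract, and accounts each
#' convolution with [flops_standard()] or [flops_het()].  Only convolutions
#' are counted: normalization, activation and pooling layers contribute zero,
#' and fully connected heads are excluded unless `include_dense` is set.
#' Unknown layer kinds are counted as zero with a warning.
#'
#' @param backbone A `dhcnn_backbone` or plain list of layer records (fields
#'   `name`, `kind`, `in_channels`, `out_channels`, `kernel_size`, `stride`,
#'   and for `dhconv` layers `p_fraction`).
#' @param input_size Integer vector `c(height, width)` of the input image.
#' @param include_dense Count `fc` layers (`in_features * out_features`)?
#' @return List with `layers` (a data frame: name, kind, K, P, r, out_h,
#'   out_w, flops, ratio) and `total`.
#' @export
count_model_flops <- function(backbone, input_size = c(224L, 224L),
                              include_dense = FALSE) {
  layers <- backbone_layers(backbone)
  h <- input_size[1]
  w <- input_size[2]
  rows <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    kind <- ly$kind %||% "unknown"
    fl <- 0
    ratio <- NA_real_
    if (kind %in% c("conv", "dhconv", "pool")) {
      s <- ly$stride %||% 1L
      h <- (h - 1L) %/% s + 1L
      w <- (w - 1L) %/% s + 1L
    }
    if (kind == "conv") {
      fl <- flops_standard(w, h, ly$out_channels, ly$kernel_size, ly$in_channels)
      ratio <- 1
    } else if (kind == "dhconv") {
      lc <- flops_het(w, h, ly$out_channels, ly$kernel_size, ly$in_channels,
                      ly$p_fraction)
      fl <- lc$het_flops
      ratio <- lc$ratio
    } else if (kind == "fc") {
      if (include_dense) fl <- as.numeric(ly$in_features) * ly$out_features
    } else if (!kind %in% c("pool", "norm", "act")) {
      warning("unknown layer kind '", kind, "' for layer '",
              ly$name %||% i, "': counted as zero FLOPs", call. = FALSE)
    }
    rows[[i]] <- data.frame(
      name = ly$name %||% paste0("layer", i), kind = kind,
      K = if (kind %in% c("conv", "dhconv")) ly$kernel_size else NA_integer_,
      P = if (kind == "dhconv") ly$p_fraction else if (kind == "conv") 1 else NA_real_,
      r = if (kind %in% c("conv", "dhconv")) (ly$dilation_rate %||% 1L) else NA_integer_,
      out_h = h, out_w = w, flops = fl, ratio = ratio,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  list(layers = tab, total = sum(tab$flops))
}

# ---- internal helpers --------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

is_whole <- function(x, tol = 1e-9) abs(x - round(x)) < tol

stopifnot_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || !is_whole(x)) {
    stop(name, " must be a positive integer, got ", deparse(substitute(x)),
         " = ", paste(format(x), collapse = ","), call. = FALSE)
  }
  invisible(TRUE)
}

check_p_fraction <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1) {
    stop("p_fraction must lie in (0, 1], got ", format(p), call. = FALSE)
  }
  invisible(TRUE)
}

backbone_layers <- function(backbone) {
  if (inherits(backbone, "dhcnn_backbone")) backbone$layers else backbone
}
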
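#' Specify a dilation heterogeneous convolution layer
#'
#' A DHConv layer has `out_channels` filters over `in_channels` input channels.
#' Within each filter, a fraction `p_fraction` of the per-channel kernels are
#' dilated `kernel_size` x `kernel_size` kernels with dilation rate
#' `dilation_rate`; the rest are pointwise 1x1 kernels.  `p_fraction = 1`
#' degenerates to an ordinary dilated convolution, and additionally
#' `dilation_rate = 1` to a standard convolution.
#'
#' @param in_channels,out_channels Positive integers (`M` and `N`).
#' @param kernel_size Odd positive integer (`K`).
#' @param dilation_rate Positive integer (`r`).
#' @param p_fraction Fraction of large kernels per filter in (0, 1];
#'   `1 / p_fraction` must be an integer and divide `in_channels`.
#' @param stride Positive integer, applied identically to both branches.
#' @param layout `"shifted"` (each successive filter offsets its large-kernel
#'   channels, so every input channel is seen by a large kernel) or
#'   `"leading"` (every filter puts its large kernels on the first channels).
#' @param use_bias One shared bias per filter across both branches.
#' @return A `dhconv_spec` object.
#' @export
dhconv_spec <- function(in_channels, out_channels, kernel_size = 3L,
                        dilation_rate = 1L, p_fraction = 1,
                        stride = 1L, layout = c("shifted", "leading"),
                        use_bias = TRUE) {
  layout <- match.arg(layout)
  stopifnot_count(in_channels, "in_channels")
  stopifnot_count(out_channels, "out_channels")
  stopifnot_count(kernel_size, "kernel_size")
  stopifnot_count(dilation_rate, "dilation_rate")
  stopifnot_count(stride, "stride")
  check_p_fraction(p_fraction)
  if (kernel_size %% 2L == 0L) {
    stop("kernel_size must be odd (same-padding contract), got ", kernel_size,
         call. = FALSE)
  }
  if (!is_whole(1 / p_fraction)) {
    stop("1 / p_fraction must be an integer, got p_fraction = ",
         format(p_fraction), call. = FALSE)
  }
  if (!is_whole(in_channels * p_fraction)) {
    stop("in_channels * p_fraction must be a positive integer ",
         "(whole number of large kernels per filter)", call. = FALSE)
  }
  structure(
    list(in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         kernel_size = as.integer(kernel_size),
         dilation_rate = as.integer(dilation_rate),
         p_fraction = p_fraction,
         stride = as.integer(stride),
         layout = layout,
         use_bias = isTRUE(use_bias)),
    class = "dhconv_spec")
}

#' @export
print.dhconv_spec <- function(x, ...) {
  cat(sprintf(
    "DHConv spec: %d -> %d channels, K=%d, r=%d, P=%s, stride=%d, layout=%s%s\n",
    x$in_channels, x$out_channels, x$kernel_size, x$dilation_rate,
    format(x$p_fraction), x$stride, x$layout, if (x$use_bias) ", bias" else ""))
  invisible(x)
}

#' Kernel layout of a DHConv layer
#'
#' Deterministic assignment of each (filter, channel) slot to the large dilated
#' kernel or the pointwise kernel.  Under `layout = "shifted"`, channel `c` of
#' filter `f` (0-based) is LARGE iff `(c + f) mod (1/P) == 0`, so every filter
#' carries exactly `M * P` large kernels and, when the filter count is a
#' multiple of `1/P`, every input channel is LARGE in the same fraction `P` of
#' filters.  Under `layout = "leading"` the first `M * P` channels of every
#' filter are LARGE.
#'
#' @param spec A [dhconv_spec()].
#' @return Integer matrix `in_channels` x `out_channels`; 1 = LARGE,
#'   0 = POINTWISE.  Class `kernel_layout_mask`.
#' @export
build_layout <- function(spec) {
  stopifnot(inherits(spec, "dhconv_spec"))
  M <- spec$in_channels
  N <- spec$out_channels
  inv_p <- as.integer(round(1 / spec$p_fraction))
  m <- matrix(0L, nrow = M, ncol = N)
  if (spec$layout == "shifted") {
    for (f in seq_len(N)) {
      cc <- 0:(M - 1L)
      m[((cc + (f - 1L)) %% inv_p) == 0L, f] <- 1L
    }
  } else {
    n_large <- as.integer(round(M * spec$p_fraction))
    m[seq_len(n_large), ] <- 1L
  }
  structure(m, class = c("kernel_layout_mask", "matrix", "array"))
}

#' Initialize DHConv weights
#'
#' Fan-in-scaled random normal initialization: each filter's fan-in counts the
#' true footprint of its kernels (`K^2` per large kernel, 1 per pointwise
#' kernel), and all its weights are drawn N(0, 2/fan_in).  Head layers in the
#' detector override the bias via `bias_init`.
#'
#' @param spec A [dhconv_spec()].
#' @param seed Optional integer seed for reproducible draws.
#' @param bias_init Initial value of every filter bias.
#' @return List with `large` (K x K x M x N array), `point` (M x N matrix),
#'   `bias` (length N) and `mask` (layout from [build_layout()]).  Entries of
#'   `large`/`point` not selected by the mask are zero and stay zero.
#' @export
dhconv_init <- function(spec, seed = NULL, bias_init = 0) {
  mask <- build_layout(spec)
  K <- spec$kernel_size
  M <- spec$in_channels
  N <- spec$out_channels
  if (!is.null(seed)) {
    old <- rng_snapshot(); on.exit(rng_restore(old))
    set.seed(as.integer(seed))
  }
  n_large <- sum(mask[, 1L])
  fan_in <- n_large * K^2 + (M - n_large)
  sd <- sqrt(2 / fan_in)
  large <- array(0, dim = c(K, K, M, N))
  point <- matrix(0, nrow = M, ncol = N)
  for (f in seq_len(N)) {
    for (c in seq_len(M)) {
      if (mask[c, f] == 1L) {
        large[, , c, f] <- rnorm(K * K, sd = sd)
      } else {
        point[c, f] <- rnorm(1L, sd = sd)
      }
    }
  }
  list(large = large, point = point, bias = rep(bias_init, N), mask = mask)
}

#' Apply a DHConv layer to a feature map
#'
#' Two parallel branches are computed and summed: the dilated large-kernel
#' branch (padded by `r * (K - 1) / 2` per side) and the pointwise branch
#' (unpadded), so at stride 1 the output spatial size equals the input size.
#' The shared per-filter bias is added once.
#'
#' @param x Feature map: `H x W` matrix (single channel) or `H x W x C` array;
#'   `C` must equal `spec$in_channels`.
#' @param weights Weights from [dhconv_init()] (or with the same structure).
#' @param spec A [dhconv_spec()].
#' @return `H' x W' x out_channels` array, `H' = floor((H-1)/stride) + 1`.
#' @export
apply_dhconv <- function(x, weights, spec) {
  x <- as_feature_map(x)
  if (dim(x)[3] != spec$in_channels) {
    stop("input has ", dim(x)[3], " channels but spec expects ",
         spec$in_channels, call. = FALSE)
  }
  cpp_dhconv_forward(x, dim(x), weights$large, weights$point,
                     as.numeric(weights$bias), weights$mask,
                     spec$kernel_size, spec$dilation_rate, spec$stride,
                     spec$use_bias)
}

#' Dense masked-kernel oracle for DHConv
#'
#' Reference implementation used for verification: for every (filter, channel)
#' it materializes a dense `K_D` x `K_D` kernel (`K_D` from
#' [dilated_kernel_extent()]) -- large-kernel taps scattered onto the dilation
#' grid with zeros in the holes, pointwise weights as a single centre value --
#' and performs one ordinary dense convolution in plain R.  It also counts the
#' nonzero-weight multiply--accumulates, the empirical quantity the analytic
#' [flops_het()] must reproduce.
#'
#' @inheritParams apply_dhconv
#' @return Output array as [apply_dhconv()], with attribute `mac_count`.
#' @export
dense_oracle <- function(x, weights, spec) {
  x <- as_feature_map(x)
  M <- spec$in_channels
  N <- spec$out_channels
  K <- spec$kernel_size
  r <- spec$dilation_rate
  s <- spec$stride
  if (dim(x)[3] != M) {
    stop("input has ", dim(x)[3], " channels but spec expects ", M, call. = FALSE)
  }
  KD <- dilated_kernel_extent(K, r)
  ctr <- (KD + 1L) %/% 2L
  dense <- array(0, dim = c(KD, KD, M, N))
  for (f in seq_len(N)) {
    for (c in seq_len(M)) {
      if (weights$mask[c, f] == 1L) {
        idx <- 1L + (seq_len(K) - 1L) * r
        dense[idx, idx, c, f] <- weights$large[, , c, f]
      } else {
        dense[ctr, ctr, c, f] <- weights$point[c, f]
      }
    }
  }
  H <- dim(x)[1]; W <- dim(x)[2]
  pad <- r * (K - 1L) %/% 2L
  Ho <- (H - 1L) %/% s + 1L
  Wo <- (W - 1L) %/% s + 1L
  xp <- array(0, dim = c(H + 2L * pad, W + 2L * pad, M))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  out <- array(0, dim = c(Ho, Wo, N))
  for (f in seq_len(N)) {
    kern <- dense[, , , f, drop = FALSE]
    dim(kern) <- c(KD, KD, M)
    for (oj in seq_len(Wo)) {
      jx <- (oj - 1L) * s + seq_len(KD)
      for (oi in seq_len(Ho)) {
        ix <- (oi - 1L) * s + seq_len(KD)
        patch <- xp[ix, jx, , drop = FALSE]
        dim(patch) <- c(KD, KD, M)
        acc <- sum(patch * kern)
        if (spec$use_bias) acc <- acc + weights$bias[f]
        out[oi, oj, f] <- acc
      }
    }
  }
  nz_per_filter <- apply(dense != 0, 4, sum)
  attr(out, "mac_count") <- as.numeric(Ho) * Wo * sum(nz_per_filter)
  out
}

#' Measure a DHConv layer's receptive field by impulse probing
#'
#' Builds the layer with all-ones weights and zero bias, feeds a unit impulse
#' at the centre of a sufficiently large blank input, and returns the side of
#' the bounding box of nonzero responses in the output map -- the set of
#' output units a single input pixel can influence, which by symmetry of the
#' tap grid equals the set of input pixels influencing one output unit.  For a
#' valid spec this equals `dilated_kernel_extent(K, r)`.
#'
#' @param spec A [dhconv_spec()] with stride 1.
#' @return Integer extent in pixels.
#' @export
measure_receptive_field <- function(spec) {
  stopifnot(inherits(spec, "dhconv_spec"))
  if (spec$stride != 1L) stop("receptive-field probe requires stride 1", call. = FALSE)
  KD <- dilated_kernel_extent(spec$kernel_size, spec$dilation_rate)
  S <- 2L * KD + 1L
  w <- dhconv_init(spec)
  # unit weights on every structurally present tap, zero elsewhere
  w$large <- array(0, dim = dim(w$large))
  for (f in seq_len(spec$out_channels)) {
    for (c in seq_len(spec$in_channels)) {
      if (w$mask[c, f] == 1L) w$large[, , c, f] <- 1
    }
  }
  w$point[] <- ifelse(w$mask == 0L, 1, 0)
  w$bias[] <- 0
  x <- array(0, dim = c(S, S, spec$in_channels))
  ctr <- (S + 1L) %/% 2L
  x[ctr, ctr, ] <- 1
  out <- apply_dhconv(x, w, spec)
  hit <- apply(abs(out) > 0, c(1, 2), any)
  rows <- range(which(apply(hit, 1, any)))
  cols <- range(which(apply(hit, 2, any)))
  as.integer(max(rows[2] - rows[1], cols[2] - cols[1]) + 1L)
}

#' Parameter count of a DHConv layer
#'
#' `N * (M * P * K^2 + M * (1 - P))` weights plus `N` biases when present;
#' strictly fewer than the standard layer's `N * M * K^2` whenever `P < 1`.
#'
#' @param spec A [dhconv_spec()].
#' @return Numeric parameter count.
#' @export
dhconv_param_count <- function(spec) {
  M <- spec$in_channels; N <- spec$out_channels
  K <- spec$kernel_size; P <- spec$p_fraction
  N * (M * P * K^2 + M * (1 - P)) + if (spec$use_bias) N else 0
}

# ---- internal ---------------------------------------------------------------

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("feature map must be an H x W matrix or H x W x C array", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

rng_restore <- function(snapshot) {
  if (is.null(snapshot)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", snapshot, envir = globalenv())
  }
}
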
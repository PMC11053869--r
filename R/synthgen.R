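#' Parameters of a synthetic microscopy scene
#'
#' Cells are rendered as ellipses with a low-order sinusoidal radial
#' perturbation, composited onto a noisy background and blurred -- a cheap,
#' fully controllable stand-in for phase-contrast / fluorescence microscopy
#' imagery with tunable shape deformation, density, contrast, scale variance
#' and overlap.
#'
#' @param image_size Side of the square scene in pixels.
#' @param count_range `c(min, max)` cells per scene.
#' @param radius_range `c(min, max)` semi-axis length in pixels.
#' @param deform Radial-perturbation amplitude in [0, 1); 0 gives exact
#'   ellipses.
#' @param overlap Allowed pairwise overlap as a fraction of the smaller
#'   instance, in [0, 1).
#' @param fg_intensity,bg_intensity Foreground / background means on the
#'   8-bit scale [0, 255].
#' @param noise_sd Additive Gaussian pixel noise, 8-bit scale.
#' @param blur_sigma Gaussian blur radius in pixels (0 disables).
#' @param seed Integer seed; scenes are byte-identical given the same seed.
#' @return A `scene_params` object.
#' @export
scene_params <- function(image_size = 256L, count_range = c(5L, 10L),
                         radius_range = c(8, 20), deform = 0.2,
                         overlap = 0, fg_intensity = 150, bg_intensity = 60,
                         noise_sd = 10, blur_sigma = 1, seed = 1L) {
  stopifnot(radius_range[1] > 0, radius_range[2] >= radius_range[1],
            overlap >= 0, overlap < 1, deform >= 0, deform < 1,
            fg_intensity >= 0, fg_intensity <= 255,
            bg_intensity >= 0, bg_intensity <= 255)
  structure(list(image_size = as.integer(image_size),
                 count_range = as.integer(count_range),
                 radius_range = as.numeric(radius_range),
                 deform = deform, overlap = overlap,
                 fg_intensity = fg_intensity, bg_intensity = bg_intensity,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Preset scene parameters emulating the benchmark dataset regimes
#'
#' Fixed parameter bundles mimicking the qualitative character of the public
#' cell benchmarks the method targets: `u373_like` -- few large, strongly
#' deformed adherent cells; `gowt1_like` -- many small low-contrast cells;
#' `simplus01_like` -- complex shapes at low foreground/background contrast;
#' `simplus02_like` -- high scale variance (max/min radius ratio >= 3) with
#' partial occlusion; `t24_like` -- adherent, overlapping cells of widely
#' varying size.
#'
#' @param name One of `"u373_like"`, `"gowt1_like"`, `"simplus01_like"`,
#'   `"simplus02_like"`, `"t24_like"`.
#' @param seed Seed stored in the returned params.
#' @return A [scene_params()] object.
#' @export
dataset_preset <- function(name = c("u373_like", "gowt1_like", "simplus01_like",
                                    "simplus02_like", "t24_like"),
                           seed = 1L) {
  name <- match.arg(name)
  switch(name,
    u373_like = scene_params(256L, c(3L, 6L), c(20, 40), deform = 0.35,
                             overlap = 0, fg_intensity = 150, bg_intensity = 60,
                             noise_sd = 10, blur_sigma = 1.5, seed = seed),
    gowt1_like = scene_params(256L, c(15L, 25L), c(6, 12), deform = 0.10,
                              overlap = 0, fg_intensity = 95, bg_intensity = 60,
                              noise_sd = 12, blur_sigma = 1, seed = seed),
    simplus01_like = scene_params(256L, c(8L, 14L), c(8, 18), deform = 0.30,
                                  overlap = 0, fg_intensity = 100,
                                  bg_intensity = 70, noise_sd = 14,
                                  blur_sigma = 1.5, seed = seed),
    simplus02_like = scene_params(256L, c(6L, 12L), c(6, 30), deform = 0.15,
                                  overlap = 0.2, fg_intensity = 140,
                                  bg_intensity = 60, noise_sd = 10,
                                  blur_sigma = 1, seed = seed),
    t24_like = scene_params(256L, c(8L, 16L), c(8, 28), deform = 0.25,
                            overlap = 0.3, fg_intensity = 130,
                            bg_intensity = 70, noise_sd = 10,
                            blur_sigma = 1.5, seed = seed))
}

#' Generate one synthetic scene
#'
#' Deterministic given `params$seed`.  Cells are placed sequentially; a
#' placement is accepted only if its mask overlaps every existing instance by
#' at most `params$overlap` of the smaller mask.  Later cells occlude earlier
#' ones in the rendered image (z-order), but every instance's full
#' pre-occlusion mask is kept as ground truth, matching how annotators label
#' partially occluded cells.  If the minimum cell count cannot be placed in
#' 1000 attempts per cell, a packing error is raised.
#'
#' @param params A [scene_params()].
#' @return A `synthetic_scene`: list with `image` (H x W intensity matrix in
#'   [0, 1], 8-bit quantized), `instances` (list of logical masks), `records`
#'   (data frame id/area/bbox) and `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(params$seed)
  S <- params$image_size
  n_target <- if (params$count_range[1] == params$count_range[2]) {
    params$count_range[1]
  } else {
    sample(params$count_range[1]:params$count_range[2], 1L)
  }
  masks <- list()
  cells <- list()
  shades <- numeric(0)
  for (k in seq_len(n_target)) {
    placed <- FALSE
    for (att in seq_len(1000L)) {
      cell <- render_cell(params, S)
      if (is.null(cell)) next
      m <- cell$mask
      ok <- TRUE
      for (mm in masks) {
        inter <- sum(m & mm)
        if (inter > params$overlap * min(sum(m), sum(mm))) { ok <- FALSE; break }
      }
      if (ok) {
        masks[[k]] <- m
        cells[[k]] <- cell
        shades[k] <- params$fg_intensity + stats::runif(1, -12, 12)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      if (length(masks) >= params$count_range[1]) break
      stop("packing error: could not place cell ", k, " of minimum ",
           params$count_range[1], " at allowed overlap ", params$overlap,
           " in 1000 attempts", call. = FALSE)
    }
  }
  img <- matrix(params$bg_intensity, S, S)
  for (k in seq_along(masks)) img[masks[[k]]] <- shades[k]   # z-order occlusion
  img <- img / 255 + stats::rnorm(S * S, sd = params$noise_sd / 255)
  if (params$blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = params$blur_sigma))
  }
  img <- matrix(pmin(1, pmax(0, img)), S, S)
  img <- round(img * 255) / 255                               # 8-bit quantized
  records <- do.call(rbind, lapply(seq_along(masks), function(k) {
    bb <- mask_bbox(masks[[k]])
    data.frame(id = k, area = sum(masks[[k]]),
               x = bb["x"], y = bb["y"], w = bb["w"], h = bb["h"],
               cx = cells[[k]]$cx, cy = cells[[k]]$cy,
               semi_a = cells[[k]]$a, semi_b = cells[[k]]$b,
               angle = cells[[k]]$phi, row.names = NULL)
  }))
  structure(list(image = img, instances = masks, records = records,
                 params = params),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d px, %d instances (seed %d)\n",
              nrow(x$image), ncol(x$image), length(x$instances),
              x$params$seed))
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG scenes, one COCO annotation file covering all of
#' them, and deterministic 80/20 train/test split lists (`train.txt`,
#' `test.txt`).  Per-image seeds are derived from `seed` so the dataset is
#' reproducible end to end.
#'
#' @param params A [scene_params()] or preset name accepted by
#'   [dataset_preset()].
#' @param n_images At least 2.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly: list with `annotation_file`, `image_files`, `train`,
#'   `test` and the `coco_annotation_set`.
#' @export
generate_dataset <- function(params, n_images, seed, out_dir) {
  if (is.character(params)) params <- dataset_preset(params)
  stopifnot(inherits(params, "scene_params"), n_images >= 2L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  images <- list(); annotations <- list(); files <- character(n_images)
  next_ann <- 1L
  for (i in seq_len(n_images)) {
    p <- params
    p$seed <- as.integer((seed + i * 7919L) %% .Machine$integer.max)
    sc <- generate_scene(p)
    fn <- sprintf("img_%03d.png", i)
    png::writePNG(sc$image, file.path(out_dir, fn))
    files[i] <- fn
    images[[i]] <- list(id = i, file_name = fn,
                        width = ncol(sc$image), height = nrow(sc$image))
    anns <- annotations_from_masks(sc$instances, i, start_id = next_ann)
    next_ann <- next_ann + length(anns)
    annotations <- c(annotations, anns)
  }
  set <- coco_annotation_set(images, annotations,
                             categories = list(list(id = 1L, name = "cell")))
  ann_path <- file.path(out_dir, "annotations.json")
  write_annotations(set, ann_path)
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(as.integer(seed))
  ord <- sample.int(n_images)
  n_test <- max(1L, round(0.2 * n_images))
  test <- sort(ord[seq_len(n_test)])
  train <- sort(ord[-seq_len(n_test)])
  writeLines(files[train], file.path(out_dir, "train.txt"))
  writeLines(files[test], file.path(out_dir, "test.txt"))
  invisible(list(annotation_file = ann_path, image_files = files,
                 train = files[train], test = files[test], set = set))
}

#' Load a generated dataset as in-memory training samples
#'
#' @param dir Directory written by [generate_dataset()].
#' @param split `"train"`, `"test"` or `"all"`.
#' @return List of samples (`image`, `masks`) as consumed by
#'   [train.mask_rdhcnn()].
#' @export
load_dataset <- function(dir, split = c("train", "test", "all")) {
  split <- match.arg(split)
  set <- read_annotations(file.path(dir, "annotations.json"))
  keep <- if (split == "all") {
    vapply(set$images, function(im) im$file_name, "")
  } else {
    readLines(file.path(dir, paste0(split, ".txt")))
  }
  samples <- list()
  for (im in set$images) {
    if (!im$file_name %in% keep) next
    img <- png::readPNG(file.path(dir, im$file_name))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    samples[[length(samples) + 1L]] <-
      list(image = to_rgb(img), masks = masks_from_annotations(set, im$id))
  }
  samples
}

# ---- internal ---------------------------------------------------------------

# Render one radially perturbed ellipse as a full-scene mask, or NULL if the
# drawn placement leaves the canvas (centres are kept a margin inside).
render_cell <- function(params, S) {
  rr <- params$radius_range
  a <- stats::runif(1, rr[1], rr[2])
  b <- stats::runif(1, rr[1], rr[2])
  phi <- stats::runif(1, 0, pi)
  rmax <- max(a, b) * (1 + params$deform)
  if (2 * rmax + 2 >= S) return(NULL)
  cx <- stats::runif(1, rmax + 1, S - rmax - 1)
  cy <- stats::runif(1, rmax + 1, S - rmax - 1)
  c1 <- stats::runif(1, -1, 1); c2 <- stats::runif(1, -1, 1)
  ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
  norm <- max(abs(c1) + abs(c2), 1e-9)
  ilo <- max(1L, floor(cy - rmax)); ihi <- min(S, ceiling(cy + rmax))
  jlo <- max(1L, floor(cx - rmax)); jhi <- min(S, ceiling(cx + rmax))
  ii <- ilo:ihi; jj <- jlo:jhi
  dy <- (ii - 0.5) - cy
  dx <- (jj - 0.5) - cx
  DX <- matrix(dx, nrow = length(ii), ncol = length(jj), byrow = TRUE)
  DY <- matrix(dy, nrow = length(ii), ncol = length(jj))
  u <- DX * cos(phi) + DY * sin(phi)
  v <- -DX * sin(phi) + DY * cos(phi)
  rho <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  re <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  pert <- 1 + params$deform * (c1 * sin(2 * th + ph1) + c2 * sin(3 * th + ph2)) / norm
  inside <- rho <= re * pert
  if (!any(inside)) return(NULL)
  m <- matrix(FALSE, S, S)
  m[ii, jj] <- inside
  list(mask = m, a = a, b = b, phi = phi, cx = cx, cy = cy)
}
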
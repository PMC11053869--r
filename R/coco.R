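#' Construct and validate a COCO-style annotation set
#'
#' The five-part annotation container of the MS COCO 2014 dialect: `info`
#' (free-form description), `licenses`, `images` (id, file_name, width,
#' height), `annotations` (id, image_id, category_id, polygon segmentation,
#' bbox, area, iscrowd) and `categories` (id, name).  Coordinates are 0-based
#' pixel units, x rightward and y downward; boxes are `(x, y, w, h)`,
#' half-open.  Validation checks that every annotation's image and category
#' ids resolve, that polygons have at least 3 vertices and lie within the
#' image bounds.
#'
#' @param images,annotations,categories Lists of records (see above).
#' @param info,licenses Optional descriptive records.
#' @return A validated `coco_annotation_set`.
#' @export
coco_annotation_set <- function(images, annotations, categories,
                                info = list(description = "dhcnn synthetic"),
                                licenses = list()) {
  set <- structure(list(info = info,
                        licenses = licenses,
                        images = lapply(images, canonical_image),
                        annotations = lapply(annotations, canonical_annotation),
                        categories = lapply(categories, canonical_category)),
                   class = "coco_annotation_set")
  validate_annotation_set(set)
  set
}

#' @export
print.coco_annotation_set <- function(x, ...) {
  cat(sprintf("COCO annotation set: %d images, %d annotations, %d categories\n",
              length(x$images), length(x$annotations), length(x$categories)))
  invisible(x)
}

#' Read a COCO-style annotation JSON file
#'
#' Parses and validates the five-part JSON; schema violations (missing
#' required field) and integrity violations (dangling image/category
#' reference) are reported with the offending record id.
#'
#' @param path Path to a JSON file.
#' @return A `coco_annotation_set`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (part in c("images", "annotations", "categories")) {
    if (is.null(raw[[part]])) {
      stop("schema error: missing required section '", part, "'", call. = FALSE)
    }
  }
  coco_annotation_set(images = raw$images, annotations = raw$annotations,
                      categories = raw$categories,
                      info = raw$info %||% list(), licenses = raw$licenses %||% list())
}

#' Write a COCO-style annotation JSON file
#'
#' Emits the five sections in the fixed order info, licenses, images,
#' annotations, categories with stable key order inside each record, so
#' repeated writes of the same set diff cleanly.  The output is readable by
#' [read_annotations()] and by standard COCO tooling.
#'
#' @param set A `coco_annotation_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "coco_annotation_set"))
  out <- list(info = set$info, licenses = set$licenses, images = set$images,
              annotations = set$annotations, categories = set$categories)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Rasterize polygon(s) to a binary mask
#'
#' Pixel-centre, even-odd rasterization: pixel (i, j) is set iff its centre
#' `(i + 0.5, j + 0.5)` (0-based) lies inside an odd number of ring crossings
#' over all supplied rings.  This is exact for the integer-vertex boundary
#' polygons produced by [mask_to_polygon()], and for convex polygons the mask
#' area tracks the analytic (shoelace) area up to a boundary term.
#'
#' @param segmentation Flat numeric vector `c(x1, y1, x2, y2, ...)` or a list
#'   of such rings (holes included, even-odd rule), or an uncompressed COCO
#'   RLE record `list(size = c(h, w), counts = ...)`.
#' @param width,height Mask dimensions in pixels.
#' @return Logical `height` x `width` matrix.
#' @export
polygon_to_mask <- function(segmentation, width, height) {
  if (is.list(segmentation) && !is.null(segmentation$counts)) {
    return(rle_to_mask(segmentation$counts, segmentation$size))
  }
  rings <- if (is.list(segmentation)) segmentation else list(segmentation)
  parity <- matrix(FALSE, nrow = height, ncol = width)
  any_area <- FALSE
  for (ring in rings) {
    ring <- as.numeric(ring)
    if (length(ring) < 6L) next
    xs <- ring[seq(1L, length(ring), by = 2L)]
    ys <- ring[seq(2L, length(ring), by = 2L)]
    if (abs(shoelace_area(xs, ys)) > 0) any_area <- TRUE
    n <- length(xs)
    cy <- seq_len(height) - 0.5
    for (e in seq_len(n)) {
      x1 <- xs[e]; y1 <- ys[e]
      x2 <- xs[e %% n + 1L]; y2 <- ys[e %% n + 1L]
      if (y1 == y2) next
      ylo <- min(y1, y2); yhi <- max(y1, y2)
      rows <- which(cy >= ylo & cy < yhi)
      if (!length(rows)) next
      xint <- x1 + (cy[rows] - y1) / (y2 - y1) * (x2 - x1)
      # number of pixel centres (i - 0.5) strictly left of the crossing
      ncov <- pmin(width, pmax(0L, ceiling(xint - 0.5)))
      for (k in seq_along(rows)) {
        if (ncov[k] > 0L) {
          parity[rows[k], seq_len(ncov[k])] <- !parity[rows[k], seq_len(ncov[k])]
        }
      }
    }
  }
  if (!any_area) {
    warning("degenerate polygon (zero area): returning empty mask", call. = FALSE)
  }
  parity
}

#' Trace a binary mask into boundary polygons
#'
#' Walks the boundary of the union of pixel squares along pixel edges,
#' producing closed integer-vertex rings: one outer ring per 4-connected
#' component plus one ring per hole.  Rasterizing the result with
#' [polygon_to_mask()] reproduces the mask exactly (the round-trip identity).
#'
#' @param mask Logical (or 0/1) matrix.
#' @return List of flat numeric rings `c(x1, y1, ...)`; empty list for an
#'   empty mask.
#' @export
mask_to_polygon <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) return(list())
  # crop to the occupied bounding box; restore the offset at the end
  bb <- mask_bbox(mask)
  off_x <- unname(bb["x"]); off_y <- unname(bb["y"])
  mask <- mask[(bb["y"] + 1):(bb["y"] + bb["h"]),
               (bb["x"] + 1):(bb["x"] + bb["w"]), drop = FALSE]
  H <- nrow(mask); W <- ncol(mask)
  # Directed boundary edges, interior on the left (x = col-1, y = row-1,
  # y downward).  Each edge row: (x1, y1, x2, y2).
  padm <- matrix(FALSE, H + 2L, W + 2L)
  padm[2:(H + 1L), 2:(W + 1L)] <- mask
  bnd <- function(exposed, mk) {
    idx <- which(mask & exposed, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    mk(idx[, 2] - 1L, idx[, 1] - 1L)  # (px, py) of each pixel's square
  }
  em <- rbind(
    bnd(!padm[1:H, 2:(W + 1L)],           # nothing above: top edge
        function(px, py) cbind(px, py, px + 1L, py)),
    bnd(!padm[2:(H + 1L), 3:(W + 2L)],    # nothing right: right edge
        function(px, py) cbind(px + 1L, py, px + 1L, py + 1L)),
    bnd(!padm[3:(H + 2L), 2:(W + 1L)],    # nothing below: bottom edge
        function(px, py) cbind(px + 1L, py + 1L, px, py + 1L)),
    bnd(!padm[2:(H + 1L), 1:W],           # nothing left: left edge
        function(px, py) cbind(px, py + 1L, px, py)))
  key <- function(x, y) paste(x, y, sep = "_")
  out_of <- split(seq_len(nrow(em)), key(em[, 1], em[, 2]))
  used <- logical(nrow(em))
  rings <- list()
  for (start in seq_len(nrow(em))) {
    if (used[start]) next
    path_x <- em[start, 1]; path_y <- em[start, 2]
    cur <- start
    repeat {
      used[cur] <- TRUE
      vx <- em[cur, 3]; vy <- em[cur, 4]
      path_x <- c(path_x, vx); path_y <- c(path_y, vy)
      if (vx == em[start, 1] && vy == em[start, 2]) break
      cand <- out_of[[key(vx, vy)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break  # should not happen on valid masks
      if (length(cand) > 1L) {
        # corner touched by two diagonal pixels: take the sharpest right turn
        # so the loops of distinct components stay separate
        din <- c(em[cur, 3] - em[cur, 1], em[cur, 4] - em[cur, 2])
        cross <- vapply(cand, function(e) {
          dout <- c(em[e, 3] - em[e, 1], em[e, 4] - em[e, 2])
          din[1] * dout[2] - din[2] * dout[1]
        }, numeric(1))
        cand <- cand[which.max(cross)]
      }
      cur <- cand
    }
    # drop closing vertex, merge collinear runs
    nv <- length(path_x) - 1L
    keep <- vapply(seq_len(nv), function(k) {
      prev <- if (k == 1L) nv else k - 1L
      nxt <- k %% nv + 1L
      d1 <- c(path_x[k] - path_x[prev], path_y[k] - path_y[prev])
      d2 <- c(path_x[nxt] - path_x[k], path_y[nxt] - path_y[k])
      d1[1] * d2[2] - d1[2] * d2[1] != 0
    }, logical(1))
    xs <- path_x[seq_len(nv)][keep] + off_x
    ys <- path_y[seq_len(nv)][keep] + off_y
    rings[[length(rings) + 1L]] <- as.numeric(rbind(xs, ys))
  }
  rings
}

#' Build COCO annotations from instance masks
#'
#' One annotation per mask: polygon segmentation from [mask_to_polygon()],
#' tight bounding box, pixel area, `iscrowd = 0`.
#'
#' @param masks List of logical matrices.
#' @param image_id Image these instances belong to.
#' @param start_id Id of the first annotation.
#' @param category_id Category for all instances.
#' @return List of annotation records.
#' @export
annotations_from_masks <- function(masks, image_id, start_id = 1L,
                                   category_id = 1L) {
  lapply(seq_along(masks), function(k) {
    m <- masks[[k]] > 0
    list(id = start_id + k - 1L, image_id = as.integer(image_id),
         category_id = as.integer(category_id),
         segmentation = mask_to_polygon(m),
         bbox = as.numeric(mask_bbox(m)),
         area = as.numeric(sum(m)), iscrowd = 0L)
  })
}

#' Rasterize all annotations of one image back to masks
#'
#' @param set A `coco_annotation_set`.
#' @param image_id Which image.
#' @return List of logical masks, one per annotation of the image, in
#'   annotation-id order.
#' @export
masks_from_annotations <- function(set, image_id) {
  img <- NULL
  for (im in set$images) if (im$id == image_id) img <- im
  if (is.null(img)) stop("unknown image id ", image_id, call. = FALSE)
  anns <- Filter(function(a) a$image_id == image_id, set$annotations)
  anns <- anns[order(vapply(anns, function(a) a$id, numeric(1)))]
  lapply(anns, function(a) polygon_to_mask(a$segmentation, img$width, img$height))
}

#' Decode an uncompressed COCO run-length encoding
#'
#' Counts alternate runs of 0s and 1s (starting with 0) in column-major
#' order, the COCO `iscrowd` convention.
#'
#' @param counts Integer run lengths.
#' @param size `c(height, width)`.
#' @return Logical matrix.
#' @export
rle_to_mask <- function(counts, size) {
  size <- as.integer(unlist(size))
  v <- rep(rep(c(FALSE, TRUE), length.out = length(counts)),
           times = as.integer(unlist(counts)))
  if (length(v) != prod(size)) {
    stop("RLE counts sum to ", length(v), " but size implies ", prod(size),
         call. = FALSE)
  }
  matrix(v, nrow = size[1], ncol = size[2])
}

# ---- internal ---------------------------------------------------------------

shoelace_area <- function(xs, ys) {
  n <- length(xs)
  nxt <- c(2:n, 1L)
  sum(xs * ys[nxt] - xs[nxt] * ys) / 2
}

require_fields <- function(rec, fields, what) {
  for (f in fields) {
    if (is.null(rec[[f]])) {
      stop("schema error: ", what, " record ",
           if (!is.null(rec$id)) paste0("id ", rec$id) else "(no id)",
           " is missing required field '", f, "'", call. = FALSE)
    }
  }
}

canonical_image <- function(im) {
  require_fields(im, c("id", "file_name", "width", "height"), "image")
  out <- list(id = as.integer(im$id), file_name = as.character(im$file_name),
              width = as.integer(im$width), height = as.integer(im$height))
  if (!is.null(im$date_captured)) out$date_captured <- as.character(im$date_captured)
  out
}

canonical_annotation <- function(an) {
  require_fields(an, c("id", "image_id", "category_id", "segmentation",
                       "bbox", "area"), "annotation")
  seg <- an$segmentation
  if (is.list(seg) && !is.null(seg$counts)) {
    seg <- list(size = as.integer(unlist(seg$size)),
                counts = as.integer(unlist(seg$counts)))
  } else {
    if (!is.list(seg)) seg <- list(seg)
    seg <- lapply(seg, function(r) as.numeric(unlist(r)))
  }
  list(id = as.integer(an$id), image_id = as.integer(an$image_id),
       category_id = as.integer(an$category_id), segmentation = seg,
       bbox = as.numeric(unlist(an$bbox)), area = as.numeric(an$area),
       iscrowd = as.integer(an$iscrowd %||% 0L))
}

canonical_category <- function(ct) {
  require_fields(ct, c("id", "name"), "category")
  out <- list(id = as.integer(ct$id), name = as.character(ct$name))
  if (!is.null(ct$supercategory)) out$supercategory <- as.character(ct$supercategory)
  out
}

validate_annotation_set <- function(set) {
  img_ids <- vapply(set$images, function(im) im$id, integer(1))
  cat_ids <- vapply(set$categories, function(ct) ct$id, integer(1))
  if (anyDuplicated(img_ids)) stop("duplicate image ids", call. = FALSE)
  dims <- stats::setNames(lapply(set$images, function(im) c(im$width, im$height)),
                          img_ids)
  for (an in set$annotations) {
    if (!an$image_id %in% img_ids) {
      stop("integrity error: annotation id ", an$id,
           " references unknown image id ", an$image_id, call. = FALSE)
    }
    if (!an$category_id %in% cat_ids) {
      stop("integrity error: annotation id ", an$id,
           " references unknown category id ", an$category_id, call. = FALSE)
    }
    if (is.null(an$segmentation$counts)) {
      wh <- dims[[as.character(an$image_id)]]
      for (ring in an$segmentation) {
        if (length(ring) < 6L || length(ring) %% 2L != 0L) {
          stop("annotation id ", an$id,
               ": polygon must have at least 3 (x, y) vertices", call. = FALSE)
        }
        xs <- ring[seq(1L, length(ring), by = 2L)]
        ys <- ring[seq(2L, length(ring), by = 2L)]
        if (any(xs < 0 | xs > wh[1] | ys < 0 | ys > wh[2])) {
          stop("annotation id ", an$id, ": polygon coordinates outside image ",
               "bounds ", wh[1], " x ", wh[2], call. = FALSE)
        }
      }
    }
  }
  invisible(set)
}
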
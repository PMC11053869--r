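minimal_set <- function() {
  coco_annotation_set(
    images = list(list(id = 1L, file_name = "a.png", width = 32L, height = 32L)),
    annotations = list(list(id = 1L, image_id = 1L, category_id = 1L,
                            segmentation = list(c(2, 2, 10, 2, 2, 10)),
                            bbox = c(2, 2, 8, 8), area = 32, iscrowd = 0L)),
    categories = list(list(id = 1L, name = "cell")))
}

test_that("a minimal annotation file parses and validates", {
  set <- minimal_set()
  expect_s3_class(set, "coco_annotation_set")
  expect_length(set$annotations, 1L)
  f <- withr::local_tempfile(fileext = ".json")
  write_annotations(set, f)
  expect_length(read_annotations(f)$annotations, 1L)
})

test_that("schema and integrity violations are reported with the record id", {
  expect_error(coco_annotation_set(
    images = list(list(id = 1L, file_name = "a.png", width = 32L, height = 32L)),
    annotations = list(list(id = 7L, image_id = 2L, category_id = 1L,
                            segmentation = list(c(0, 0, 4, 0, 0, 4)),
                            bbox = c(0, 0, 4, 4), area = 8)),
    categories = list(list(id = 1L, name = "cell"))),
    "annotation id 7 references unknown image id 2")
  expect_error(coco_annotation_set(
    images = list(list(id = 1L, width = 32L, height = 32L)),
    annotations = list(), categories = list(list(id = 1L, name = "cell"))),
    "missing required field 'file_name'")
  # polygons must stay within image bounds and have >= 3 vertices
  bad_poly <- function(seg) coco_annotation_set(
    images = list(list(id = 1L, file_name = "a.png", width = 16L, height = 16L)),
    annotations = list(list(id = 1L, image_id = 1L, category_id = 1L,
                            segmentation = list(seg), bbox = c(0, 0, 4, 4),
                            area = 8)),
    categories = list(list(id = 1L, name = "cell")))
  expect_error(bad_poly(c(0, 0, 4, 0)), "at least 3")
  expect_error(bad_poly(c(0, 0, 40, 0, 0, 4)), "bounds")
})

test_that("write then read is the identity on annotation sets", {
  d <- withr::local_tempdir()
  res <- generate_dataset(scene_params(image_size = 96L, count_range = c(3L, 5L),
                                       seed = 8L), 4L, 8L, d)
  f2 <- withr::local_tempfile(fileext = ".json")
  set1 <- read_annotations(res$annotation_file)
  write_annotations(set1, f2)
  set2 <- read_annotations(f2)
  expect_equal(set1, set2)
  # writing the same set twice yields byte-identical files
  f3 <- withr::local_tempfile(fileext = ".json")
  write_annotations(set1, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("polygon rasterization follows pixel-centre even-odd sampling", {
  sq <- polygon_to_mask(c(0, 0, 10, 0, 10, 10, 0, 10), 20, 20)
  expect_equal(sum(sq), 100)
  expect_true(all(which(sq, arr.ind = TRUE) <= 10))
  tri <- polygon_to_mask(c(0, 0, 4, 0, 0, 4), 10, 10)
  # shoelace area 8; centre sampling may deviate by a boundary term
  expect_lt(abs(sum(tri) - 8), 7)  # half the perimeter
  # convex polygon with area >= 100 px: within 2% of the shoelace area
  hex <- c(2, 10, 10, 2, 20, 2, 28, 10, 20, 22, 10, 22)
  xs <- hex[seq(1, 12, 2)]; ys <- hex[seq(2, 12, 2)]
  n <- length(xs); nxt <- c(2:n, 1)
  shoelace <- abs(sum(xs * ys[nxt] - xs[nxt] * ys)) / 2
  expect_gt(shoelace, 100)
  got <- sum(polygon_to_mask(hex, 32, 32))
  expect_lt(abs(got - shoelace) / shoelace, 0.02)
  expect_warning(polygon_to_mask(c(0, 0, 5, 0, 9, 0), 12, 12), "degenerate")
})

test_that("mask tracing round-trips exactly through rasterization", {
  # single pixel -> one 4-vertex ring
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  p <- mask_to_polygon(m)
  expect_length(p, 1L)
  expect_length(p[[1]], 8L)
  expect_identical(polygon_to_mask(p, 5, 5), m)
  # two disjoint blobs -> two rings
  m2 <- rect_mask(12, 12, 2:4, 2:4) | rect_mask(12, 12, 8:10, 7:11)
  expect_length(mask_to_polygon(m2), 2L)
  # diagonally touching pixels stay separate rings
  m3 <- matrix(FALSE, 4, 4); m3[1, 1] <- TRUE; m3[2, 2] <- TRUE
  expect_length(mask_to_polygon(m3), 2L)
  expect_identical(polygon_to_mask(mask_to_polygon(m3), 4, 4), m3)
  # a blob with a hole needs an inner ring and still round-trips
  m4 <- rect_mask(10, 10, 2:8, 2:8); m4[4:6, 4:6] <- FALSE
  p4 <- mask_to_polygon(m4)
  expect_length(p4, 2L)
  expect_identical(polygon_to_mask(p4, 10, 10), m4)
  # seeded random blobs
  set.seed(23)
  for (t in 1:15) {
    mm <- matrix(runif(18 * 14) > 0.55, 18, 14)
    expect_identical(polygon_to_mask(mask_to_polygon(mm), 14, 18), mm)
  }
  expect_length(mask_to_polygon(matrix(FALSE, 4, 4)), 0L)
})

test_that("uncompressed RLE decodes in column-major order", {
  m <- rle_to_mask(c(2, 3, 4, 3), c(3, 4))
  expect_equal(sum(m), 6)
  expect_equal(dim(m), c(3L, 4L))
  expect_true(m[3, 1] && m[1, 2] && !m[1, 1])
  expect_error(rle_to_mask(c(2, 2), c(3, 4)), "size")
})

test_that("annotations built from masks carry tight boxes and exact areas", {
  masks <- list(rect_mask(20, 20, 3:7, 4:9), rect_mask(20, 20, 12:16, 12:14))
  anns <- annotations_from_masks(masks, image_id = 5L, start_id = 10L)
  expect_equal(vapply(anns, function(a) a$id, integer(1)), c(10L, 11L))
  expect_equal(anns[[1]]$bbox, c(3, 2, 6, 5))  # x, y, w, h 0-based
  expect_equal(anns[[1]]$area, 30)
  set <- coco_annotation_set(
    images = list(list(id = 5L, file_name = "x.png", width = 20L, height = 20L)),
    annotations = anns, categories = list(list(id = 1L, name = "cell")))
  back <- masks_from_annotations(set, 5L)
  expect_identical(back[[1]], masks[[1]])
  expect_identical(back[[2]], masks[[2]])
})
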
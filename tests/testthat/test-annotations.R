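test_that("YOLO files round-trip losslessly at 6 decimals with order preserved", {
  recs <- tibble::tibble(
    class_id = c(0L, 1L, 0L),
    cx = c(0.5, 0.25, 0.123456), cy = c(0.5, 0.75, 0.9),
    w = c(0.1, 0.05, 0.2), h = c(0.1, 0.05, 0.01)
  )
  f <- withr::local_tempfile(fileext = ".txt")
  write_yolo(recs, f)
  expect_identical(readLines(f)[2], "1 0.250000 0.750000 0.050000 0.050000")
  back <- read_yolo(f)
  expect_equal(back, recs, tolerance = 1e-6)
  write_yolo(back, f)
  expect_equal(read_yolo(f), back) # fixed point after first rounding
})

test_that("single-record and empty files parse by the format definition", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.1 0.1", f)
  rec <- read_yolo(f)
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$class_id, 0L) # SD
  expect_equal(c(rec$cx, rec$cy), c(0.5, 0.5))
  writeLines(character(), f)
  expect_equal(nrow(read_yolo(f)), 0L)
})

test_that("malformed and out-of-range lines report their line number", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.1 0.1", "1 0.2 0.3"), f)
  expect_error(read_yolo(f), "line 2", class = "trapscan_parse_error")
  writeLines(c("0 0.5 0.5 0.1 0.1", "0 1.5 0.5 0.1 0.1"), f)
  expect_error(read_yolo(f), "line 2", class = "trapscan_range_error")
})

make_dataset <- function(labels, lighting) {
  n <- length(labels)
  tibble::tibble(
    trap_id = "t1", col = seq_len(n) - 1L, row = 0L,
    tile_i = 0L, tile_j = 0L, lighting = lighting,
    labels = labels
  )
}

test_that("labels transfer verbatim between superposable lighting datasets", {
  lab <- list(
    tibble::tibble(class_id = 0L, cx = .5, cy = .5, w = .1, h = .1),
    tibble::tibble(class_id = c(0L, 1L), cx = c(.2, .8), cy = c(.2, .8),
      w = c(.05, .05), h = c(.05, .05)),
    tibble::tibble(class_id = 1L, cx = .3, cy = .7, w = .2, h = .1)
  )
  src <- make_dataset(lab, "transmittance")
  tgt <- make_dataset(list(NULL, NULL, NULL), "reflectance")
  out <- transfer_annotations(src, tgt)
  expect_identical(out$labels, src$labels)
  expect_identical(out$lighting, rep("reflectance", 3))
  expect_identical(src$labels, lab) # source untouched

  empty <- make_dataset(list(lab[[1]][0, ], lab[[1]][0, ], lab[[1]][0, ]),
    "transmittance")
  out2 <- transfer_annotations(empty, tgt)
  expect_true(all(vapply(out2$labels, nrow, integer(1)) == 0L))

  expect_error(transfer_annotations(src, tgt[-2, ]),
    regexp = "only in source", class = "trapscan_key_mismatch")
})

test_that("empty tiles are filtered out, keeping order", {
  lab <- list(
    tibble::tibble(class_id = 0L, cx = .5, cy = .5, w = .1, h = .1),
    tibble::tibble(class_id = integer(), cx = double(), cy = double(),
      w = double(), h = double()),
    tibble::tibble(class_id = c(0L, 1L), cx = c(.2, .8), cy = c(.5, .5),
      w = c(.1, .1), h = c(.1, .1))
  )
  ds <- make_dataset(lab, "transmittance")
  kept <- filter_empty_tiles(ds)
  expect_equal(kept$col, c(0L, 2L))
  all_empty <- make_dataset(list(lab[[2]], lab[[2]], NULL), "transmittance")
  expect_equal(nrow(filter_empty_tiles(all_empty)), 0L)
})

test_that("kept-tile count matches a brute-force scan of truth boxes over tile rectangles", {
  spec <- trap_spec()
  grid <- build_capture_grid(spec)
  scene <- sample_scene(scene_spec(mean_sd = 18, mean_ot = 2, seed = 11), spec)
  ann <- scene_annotations(scene, grid)
  kept_keys <- dplyr::distinct(ann[, c("col", "row", "tile_i", "tile_j")])

  # independent scan: global insect boxes against every pose/tile rectangle,
  # with the boxes re-derived from first principles (rotated-ellipse extents)
  s <- px_per_mm(spec)
  ins <- scene$insects
  hx <- sqrt((ins$length_mm / 2 * cos(ins$angle))^2 +
    (ins$width_mm / 2 * sin(ins$angle))^2) * s
  hy <- sqrt((ins$length_mm / 2 * sin(ins$angle))^2 +
    (ins$width_mm / 2 * cos(ins$angle))^2) * s
  boxes <- tibble::tibble(x = ins$x_mm * s - hx, y = ins$y_mm * s - hy,
    w = 2 * hx, h = 2 * hy)
  ratio <- 2912 / 2992
  hits <- 0L
  for (p in seq_len(nrow(grid$poses))) {
    ox <- grid$poses$origin_x_mm[p] * s
    oy <- grid$poses$origin_y_mm[p] * s
    for (ti in 0:6) {
      for (tj in 0:6) {
        tx0 <- ti * 416; ty0 <- tj * 416
        x0 <- pmax((boxes$x - ox) * ratio, tx0)
        y0 <- pmax((boxes$y - oy) * ratio, ty0)
        x1 <- pmin((boxes$x + boxes$w - ox) * ratio, tx0 + 416)
        y1 <- pmin((boxes$y + boxes$h - oy) * ratio, ty0 + 416)
        frag <- pmax(x1 - x0, 0) * pmax(y1 - y0, 0)
        if (any(frag >= 0.2 * boxes$w * boxes$h * ratio^2)) hits <- hits + 1L
      }
    }
  }
  expect_equal(nrow(kept_keys), hits)
})

test_that("70/20/10 splitting is exact, deterministic, and a partition", {
  items <- tibble::tibble(id = 1:100)
  out <- split_dataset(items, seed = 5)
  expect_equal(as.integer(table(out$split)), c(70L, 20L, 10L))
  expect_identical(out, split_dataset(items, seed = 5))
  other <- split_dataset(items, seed = 6)
  expect_equal(as.integer(table(other$split)), c(70L, 20L, 10L))
  expect_false(identical(out$split, other$split))

  ten <- split_dataset(tibble::tibble(id = 1:10), seed = 1)
  expect_equal(as.integer(table(ten$split)), c(7L, 2L, 1L))

  expect_error(split_dataset(items, ratios = c(.5, .5, .5)),
    class = "trapscan_bad_ratio")

  # property: every row lands in exactly one split, sizes floor + remainder
  withr::with_seed(99, {
    for (k in 1:1000) {
      n <- sample(1:60, 1)
      res <- split_dataset(tibble::tibble(id = seq_len(n)), seed = k)
      expect_false(anyNA(res$split))
      tab <- as.integer(table(res$split))
      expect_equal(sum(tab), n)
      expect_equal(tab[2:3], c(floor(.2 * n), floor(.1 * n)))
    }
  })
})

test_that("augmentation transforms records consistently with the raster", {
  rec <- tibble::tibble(class_id = 0L, cx = 0.2, cy = 0.3, w = 0.1, h = 0.2)
  expect_equal(trapscan:::augment_records(
    tibble::tibble(class_id = 0L, cx = 0.2, cy = 0.3, w = 0.1, h = 0.1),
    "hflip")[, 2:5],
  tibble::tibble(cx = 0.8, cy = 0.3, w = 0.1, h = 0.1))
  expect_equal(trapscan:::augment_records(rec, "rot90cw")[, 2:5],
    tibble::tibble(cx = 0.7, cy = 0.2, w = 0.2, h = 0.1))

  # raster oracle: paint the box, transform the image, re-extract its bounds
  n <- 200
  for (op in c("hflip", "vflip", "rot90cw", "rot90ccw", "rot180")) {
    img <- matrix(0, n, n)
    xs <- floor((rec$cx - rec$w / 2) * n):ceiling((rec$cx + rec$w / 2) * n - 1) + 1
    ys <- floor((rec$cy - rec$h / 2) * n):ceiling((rec$cy + rec$h / 2) * n - 1) + 1
    img[ys, xs] <- 1
    aug <- augment_tile(img, rec, op)
    idx <- which(aug$image == 1, arr.ind = TRUE)
    # pixel i spans [i-1, i): the blob centre is (min + max - 1) / 2
    got_cx <- (min(idx[, 2]) + max(idx[, 2]) - 1) / 2 / n
    got_cy <- (min(idx[, 1]) + max(idx[, 1]) - 1) / 2 / n
    expect_lt(abs(got_cx - aug$records$cx), 1.5 / n)
    expect_lt(abs(got_cy - aug$records$cy), 1.5 / n)
    expect_equal(diff(range(idx[, 2])) + 1, aug$records$w * n, tolerance = 1)
    expect_equal(diff(range(idx[, 1])) + 1, aug$records$h * n, tolerance = 1)
  }
})

test_that("augmentations compose as the square's symmetry group and preserve area", {
  withr::with_seed(7, {
    recs <- tibble::tibble(
      class_id = rep(0L, 20),
      cx = runif(20, .2, .8), cy = runif(20, .2, .8),
      w = runif(20, .05, .3), h = runif(20, .05, .3)
    )
  })
  img <- matrix(runif(64^2), 64, 64)
  hh <- augment_tile(augment_tile(img, recs, "hflip")$image,
    augment_tile(img, recs, "hflip")$records, "hflip")
  expect_equal(hh$image, img)
  expect_equal(hh$records, recs)
  r <- list(image = img, records = recs)
  for (k in 1:4) r <- augment_tile(r$image, r$records, "rot90cw")
  expect_equal(r$image, img)
  expect_equal(r$records, recs, tolerance = 1e-12)
  rot <- trapscan:::augment_records(recs, "rot90cw")
  expect_equal(rot$w * rot$h, recs$w * recs$h) # w/h swap preserves area
  expect_equal(rot$w, recs$h)
  inside <- function(r) all(r$cx - r$w / 2 >= -1e-12 & r$cx + r$w / 2 <= 1 + 1e-12 &
    r$cy - r$h / 2 >= -1e-12 & r$cy + r$h / 2 <= 1 + 1e-12)
  for (op in c("hflip", "vflip", "rot90cw", "rot90ccw", "rot180")) {
    expect_true(inside(trapscan:::augment_records(recs, op)))
  }
  expect_error(augment_tile(img, recs, "shear"))
})
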
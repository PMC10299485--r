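#' Read and write YOLO-format annotations
#'
#' One object per line: `class cx cy w h`, all geometry normalized to
#' `[0, 1]` of the tile, class index 0 = SD, 1 = OT. `write_yolo()`
#' serialises with fixed 6-decimal precision, so a write/read round trip is
#' lossless at that precision and preserves line order.
#'
#' @param path File path.
#' @return `read_yolo()`: a tibble with `class_id` (integer), `cx`, `cy`,
#'   `w`, `h`; zero rows for an empty file.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_yolo(tibble::tibble(class_id = 0L, cx = .5, cy = .5, w = .1, h = .1), f)
#' read_yolo(f)
#' @export
read_yolo <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(class_id = integer(), cx = double(), cy = double(),
      w = double(), h = double()))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n_fields <- lengths(fields)
  if (any(n_fields != 5L)) {
    bad <- which(n_fields != 5L)[1]
    abort(sprintf("parse error at line %d of %s: expected 5 fields, got %d.",
      bad, path, n_fields[bad]), class = "trapscan_parse_error")
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 5, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1, anyNA))[1]
    abort(sprintf("parse error at line %d of %s: non-numeric field.", bad, path),
      class = "trapscan_parse_error")
  }
  recs <- tibble(
    class_id = as.integer(vals[, 1]),
    cx = vals[, 2], cy = vals[, 3], w = vals[, 4], h = vals[, 5]
  )
  geom <- as.matrix(recs[, c("cx", "cy", "w", "h")])
  if (any(geom < 0 | geom > 1)) {
    bad <- which(apply(geom, 1, function(r) any(r < 0 | r > 1)))[1]
    abort(sprintf("range error at line %d of %s: coordinates outside [0, 1].",
      bad, path), class = "trapscan_range_error")
  }
  recs
}

check_records <- function(records) {
  need <- c("class_id", "cx", "cy", "w", "h")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort("annotation records need columns class_id, cx, cy, w, h.")
  }
  if (nrow(records)) {
    geom <- as.matrix(records[, c("cx", "cy", "w", "h")])
    if (any(geom < 0 | geom > 1) || any(records$w <= 0 | records$h <= 0)) {
      abort("annotation geometry must lie in [0, 1] with positive w, h.",
        class = "trapscan_range_error")
    }
    if (!all(records$class_id %in% c(0L, 1L))) {
      abort("class_id must be 0 (SD) or 1 (OT).")
    }
  }
  invisible(records)
}

#' @param records Annotation tibble as returned by `read_yolo()`.
#' @rdname read_yolo
#' @export
write_yolo <- function(records, path) {
  check_records(records)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
    records$class_id, records$cx, records$cy, records$w, records$h)
  writeLines(lines, path)
  invisible(path)
}

tile_key_cols <- c("trap_id", "col", "row", "tile_i", "tile_j")

check_dataset <- function(dataset, arg = "dataset") {
  need <- c(tile_key_cols, "lighting", "labels")
  if (!is.data.frame(dataset) || !all(need %in% names(dataset))) {
    abort(sprintf(
      "`%s` must be a tile table with columns %s.", arg, paste(need, collapse = ", ")
    ))
  }
  invisible(dataset)
}

#' Transfer annotations between superposable lighting datasets
#'
#' The two lighting regimes (transmittance: back-lit through the card;
#' reflectance: camera-side illumination) are captured at identical camera
#' poses, so their tiles superpose exactly. Labels drawn once on the
#' higher-contrast transmittance tiles are copied verbatim onto the matching
#' reflectance tiles.
#'
#' @param source,target Tile tables: one row per tile with key columns
#'   `trap_id`, `col`, `row`, `tile_i`, `tile_j`, a `lighting` tag, and a
#'   `labels` list-column of annotation tibbles. Keys must match one-to-one
#'   after dropping the lighting tag.
#' @return `target` with its `labels` column replaced by copies of the
#'   source labels; `source` is untouched.
#' @export
transfer_annotations <- function(source, target) {
  check_dataset(source, "source")
  check_dataset(target, "target")
  skey <- do.call(paste, c(source[tile_key_cols], sep = "\r"))
  tkey <- do.call(paste, c(target[tile_key_cols], sep = "\r"))
  if (anyDuplicated(skey) || anyDuplicated(tkey)) {
    abort("tile keys must be unique within each dataset.")
  }
  only_s <- setdiff(skey, tkey)
  only_t <- setdiff(tkey, skey)
  if (length(only_s) || length(only_t)) {
    abort(
      paste0(
        "datasets are not superposable; unmatched tiles:\n",
        paste0("  only in source: ", gsub("\r", "/", only_s), collapse = "\n"),
        if (length(only_s) && length(only_t)) "\n",
        paste0("  only in target: ", gsub("\r", "/", only_t), collapse = "\n")
      ),
      class = "trapscan_key_mismatch"
    )
  }
  target$labels <- source$labels[match(tkey, skey)]
  target
}

#' Drop tiles with no annotated insects
#'
#' Tiles that contain no whole thrips nor any part of one carry no training
#' signal and are filtered out before dataset splitting. A missing `labels`
#' entry counts as empty.
#'
#' @param dataset Tile table with a `labels` list-column (see
#'   [transfer_annotations()]).
#' @return The rows of `dataset` whose label table has at least one record,
#'   in the original order.
#' @export
filter_empty_tiles <- function(dataset) {
  check_dataset(dataset)
  keep <- purrr::map_lgl(dataset$labels, function(l) !is.null(l) && nrow(l) > 0)
  dataset[keep, , drop = FALSE]
}

#' Split items into train/validation/test partitions
#'
#' Randomly permutes the rows (deterministically for a given seed) and cuts
#' them into partitions of sizes `floor(ratio * n)`, with any remainder
#' assigned to the training split.
#'
#' @param items A data frame of items (tiles, images, ...).
#' @param ratios Length-3 positive numeric summing to 1; defaults to the
#'   70/20/10 train/validation/test convention.
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return `items` with an added `split` factor column with levels
#'   `train`, `val`, `test`.
#' @export
split_dataset <- function(items, ratios = c(0.70, 0.20, 0.10), seed = 1L) {
  if (!is.data.frame(items)) abort("`items` must be a data frame.")
  if (length(ratios) != 3 || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9) {
    abort("`ratios` must be 3 positive values summing to 1.",
      class = "trapscan_bad_ratio")
  }
  n <- nrow(items)
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  items$split <- factor(split, levels = c("train", "val", "test"))
  items
}

augment_ops <- c("hflip", "vflip", "rot90cw", "rot90ccw", "rot180")

# transform normalized (cx, cy, w, h) records under a square-tile symmetry
augment_records <- function(records, op) {
  check_records(records)
  op <- arg_match(op, augment_ops)
  out <- as_tibble(records)
  cx <- out$cx; cy <- out$cy; w <- out$w; h <- out$h
  res <- switch(op,
    hflip    = list(1 - cx, cy, w, h),
    vflip    = list(cx, 1 - cy, w, h),
    rot90cw  = list(1 - cy, cx, h, w),
    rot90ccw = list(cy, 1 - cx, h, w),
    rot180   = list(1 - cx, 1 - cy, w, h)
  )
  out$cx <- res[[1]]; out$cy <- res[[2]]; out$w <- res[[3]]; out$h <- res[[4]]
  out
}

#' Augment a tile and its annotations
#'
#' Applies one of the five area-preserving square symmetries used for
#' training augmentation — horizontal/vertical flips and 90-degree
#' clockwise, counterclockwise and 180-degree rotations — to a square tile
#' raster and, consistently, to its normalized annotation records (e.g.
#' under `hflip`, `cx` becomes `1 - cx`; under `rot90cw`, `(cx, cy, w, h)`
#' becomes `(1 - cy, cx, h, w)`).
#'
#' @param image Square numeric matrix (rows = y, columns = x).
#' @param records Annotation tibble (`class_id`, `cx`, `cy`, `w`, `h`).
#' @param op One of `"hflip"`, `"vflip"`, `"rot90cw"`, `"rot90ccw"`,
#'   `"rot180"`.
#' @return List with the transformed `image` and `records`.
#' @export
augment_tile <- function(image, records, op) {
  if (!is.matrix(image) || nrow(image) != ncol(image)) {
    abort("`image` must be a square matrix.")
  }
  op <- arg_match(op, augment_ops)
  img <- switch(op,
    hflip    = image[, ncol(image):1, drop = FALSE],
    vflip    = image[nrow(image):1, , drop = FALSE],
    rot90cw  = t(image[nrow(image):1, , drop = FALSE]),
    rot90ccw = t(image)[ncol(image):1, , drop = FALSE],
    rot180   = image[nrow(image):1, ncol(image):1, drop = FALSE]
  )
  list(image = img, records = augment_records(records, op))
}
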
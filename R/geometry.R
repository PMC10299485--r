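#' Physical trap and capture specification
#'
#' Describes a yellow sticky trap card and the square camera footprint used
#' to photograph it. The default values correspond to a 250 x 150 mm card
#' imaged as 2992 x 2992 px captures of a 50 x 50 mm field, on a 6 x 4
#' lattice of camera poses (24 captures per trap).
#'
#' @param trap_width_mm,trap_height_mm Card dimensions in mm.
#' @param footprint_mm Side of the square area covered by one capture, mm.
#' @param capture_px Side of a capture in pixels (square, 1:1 aspect).
#' @param n_cols,n_rows Number of camera poses along the horizontal and
#'   vertical axes.
#'
#' @details The pixel scale is uniform and square, `capture_px /
#'   footprint_mm` (59.84 px/mm at the defaults). Full coverage requires
#'   `n_cols * footprint_mm >= trap_width_mm` and the analogous condition
#'   vertically; the constructor enforces both.
#'
#' @return An object of class `trap_spec` (a named list).
#' @examples
#' spec <- trap_spec()
#' px_per_mm(spec)
#' @export
trap_spec <- function(trap_width_mm = 250, trap_height_mm = 150,
                      footprint_mm = 50, capture_px = 2992,
                      n_cols = 6, n_rows = 4) {
  check_number(trap_width_mm, "trap_width_mm", 0, strict = TRUE)
  check_number(trap_height_mm, "trap_height_mm", 0, strict = TRUE)
  check_number(footprint_mm, "footprint_mm", 0, strict = TRUE)
  check_number(capture_px, "capture_px", 0, strict = TRUE)
  check_number(n_cols, "n_cols", 1)
  check_number(n_rows, "n_rows", 1)
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  if (n_cols * footprint_mm < trap_width_mm || n_rows * footprint_mm < trap_height_mm) {
    abort(
      "invalid trap_spec: the pose lattice cannot cover the card (need n_cols * footprint_mm >= trap_width_mm and likewise vertically).",
      class = "trapscan_invalid_spec"
    )
  }
  structure(
    list(
      trap_width_mm = trap_width_mm, trap_height_mm = trap_height_mm,
      footprint_mm = footprint_mm, capture_px = as.integer(capture_px),
      n_cols = n_cols, n_rows = n_rows
    ),
    class = "trap_spec"
  )
}

#' @export
print.trap_spec <- function(x, ...) {
  cat(sprintf(
    "<trap_spec> %g x %g mm card, %g mm footprint @ %d px, %d x %d poses\n",
    x$trap_width_mm, x$trap_height_mm, x$footprint_mm, x$capture_px,
    x$n_cols, x$n_rows
  ))
  invisible(x)
}

#' Pixel scale of a trap specification
#'
#' @param spec A [trap_spec()].
#' @return Pixels per millimetre (`capture_px / footprint_mm`).
#' @export
px_per_mm <- function(spec) {
  stopifnot(inherits(spec, "trap_spec"))
  spec$capture_px / spec$footprint_mm
}

#' Build the capture-pose lattice for a trap
#'
#' Lays the camera poses out row-major, equally spaced end-to-end: the first
#' pose's footprint is flush with the trap's top-left corner and the last
#' pose's far edge coincides with the bottom-right corner. Adjacent poses
#' therefore overlap by `footprint - stride` on each axis, which at the
#' default geometry gives 10 mm (20%) horizontally and 50/3 mm (~33.3%)
#' vertically.
#'
#' @param spec A [trap_spec()] with at least 2 poses per axis.
#' @return An object of class `capture_grid`: the spec, a `poses` tibble
#'   (`pose`, `col`, `row`, `origin_x_mm`, `origin_y_mm`, row-major and
#'   0-based in `col`/`row`), and the stride/overlap per axis in mm.
#' @examples
#' grid <- build_capture_grid(trap_spec())
#' nrow(grid$poses) # 24
#' grid$stride_x_mm # 40
#' @export
build_capture_grid <- function(spec) {
  stopifnot(inherits(spec, "trap_spec"))
  if (spec$n_cols < 2 || spec$n_rows < 2) {
    abort("invalid trap_spec: need at least 2 poses per axis to span the card.",
      class = "trapscan_invalid_spec"
    )
  }
  stride_x <- (spec$trap_width_mm - spec$footprint_mm) / (spec$n_cols - 1)
  stride_y <- (spec$trap_height_mm - spec$footprint_mm) / (spec$n_rows - 1)
  poses <- tidyr::crossing(row = seq_len(spec$n_rows) - 1L, col = seq_len(spec$n_cols) - 1L) %>%
    mutate(
      pose = row_number(),
      origin_x_mm = .data$col * stride_x,
      origin_y_mm = .data$row * stride_y
    ) %>%
    select("pose", "col", "row", "origin_x_mm", "origin_y_mm")
  structure(
    list(
      spec = spec, poses = poses,
      stride_x_mm = stride_x, stride_y_mm = stride_y,
      overlap_x_mm = spec$footprint_mm - stride_x,
      overlap_y_mm = spec$footprint_mm - stride_y
    ),
    class = "capture_grid"
  )
}

#' @export
print.capture_grid <- function(x, ...) {
  cat(sprintf(
    "<capture_grid> %d poses (%d x %d), stride %.6g x %.6g mm, overlap %.6g x %.6g mm\n",
    nrow(x$poses), x$spec$n_cols, x$spec$n_rows,
    x$stride_x_mm, x$stride_y_mm, x$overlap_x_mm, x$overlap_y_mm
  ))
  invisible(x)
}

#' @describeIn build_capture_grid `tidy()` returns the pose tibble.
#' @param x A `capture_grid`.
#' @param ... Unused.
#' @export
tidy.capture_grid <- function(x, ...) x$poses

# resolve a pose argument to one row of grid$poses.
# accepts: a 1-based pose index, a length-2 c(col, row) 0-based pair, or a
# one-row data frame with col/row columns.
resolve_pose <- function(grid, pose) {
  poses <- grid$poses
  if (is.data.frame(pose)) {
    stopifnot(nrow(pose) == 1L, all(c("col", "row") %in% names(pose)))
    pose <- c(pose$col[[1]], pose$row[[1]])
  }
  if (length(pose) == 1L) {
    hit <- poses[poses$pose == as.integer(pose), ]
  } else if (length(pose) == 2L) {
    hit <- poses[poses$col == as.integer(pose[[1]]) & poses$row == as.integer(pose[[2]]), ]
  } else {
    abort("`pose` must be a pose index, c(col, row) pair, or one-row pose tibble.")
  }
  if (nrow(hit) != 1L) {
    abort("pose does not belong to this capture grid.", class = "trapscan_foreign_pose")
  }
  hit
}

#' Pixel offset between two capture poses
#'
#' Converts the difference in trap-frame origins of two poses of the same
#' grid to pixels at the capture scale. Antisymmetric in its arguments; the
#' offset of a pose from itself is `(0, 0)`.
#'
#' @param grid A [build_capture_grid()] result.
#' @param a,b Poses: a 1-based pose index, a 0-based `c(col, row)` pair, or
#'   a one-row pose tibble.
#' @return Named numeric `c(dx_px, dy_px)` equal to `origin(b) - origin(a)`
#'   times the pixel scale.
#' @examples
#' grid <- build_capture_grid(trap_spec())
#' neighbor_offset_px(grid, c(0, 0), c(1, 0)) # dx = 40 mm * 59.84 px/mm
#' @export
neighbor_offset_px <- function(grid, a, b) {
  stopifnot(inherits(grid, "capture_grid"))
  pa <- resolve_pose(grid, a)
  pb <- resolve_pose(grid, b)
  s <- px_per_mm(grid$spec)
  c(
    dx_px = (pb$origin_x_mm - pa$origin_x_mm) * s,
    dy_px = (pb$origin_y_mm - pa$origin_y_mm) * s
  )
}

check_boxes <- function(boxes) {
  if (!is.data.frame(boxes) || !all(c("x", "y", "w", "h") %in% names(boxes))) {
    abort("boxes must be a data frame with columns x, y, w, h.")
  }
  invisible(boxes)
}

#' Map tile-local boxes to the trap-global pixel frame
#'
#' Composes the affine maps that undo the capture resize and translate
#' through the tile origin and the pose origin. Boxes are `(x, y, w, h)` in
#' pixels with a half-open extent; tile-local coordinates live in the
#' resized capture (e.g. 2912 px when a 2992 px capture is resized to the
#' nearest lower multiple of 416). `global_to_tile()` is the exact inverse.
#'
#' @param boxes Data frame with columns `x`, `y`, `w`, `h` (tile-local px);
#'   extra columns pass through untouched.
#' @param grid A [build_capture_grid()] result.
#' @param pose The capture pose (index, `c(col, row)`, or one-row tibble).
#' @param tile_origin_px Length-2 `c(x, y)` of the tile's top-left corner
#'   within the resized capture, px.
#' @param resize_ratio Resized side / original side (2912/2992 by default
#'   geometry); 1 means no resize.
#' @return The boxes tibble with `x`, `y`, `w`, `h` rewritten in trap-global
#'   pixels (at the original capture scale).
#' @export
tile_to_global <- function(boxes, grid, pose, tile_origin_px = c(0, 0),
                           resize_ratio = 1) {
  stopifnot(inherits(grid, "capture_grid"))
  check_boxes(boxes)
  check_number(resize_ratio, "resize_ratio", 0, strict = TRUE)
  p <- resolve_pose(grid, pose)
  s <- px_per_mm(grid$spec)
  boxes <- as_tibble(boxes)
  if (nrow(boxes) == 0) return(boxes)
  # capture-local coordinates at the original (unresized) scale
  cx0 <- (tile_origin_px[[1]] + boxes$x) / resize_ratio
  cy0 <- (tile_origin_px[[2]] + boxes$y) / resize_ratio
  w <- boxes$w / resize_ratio
  h <- boxes$h / resize_ratio
  eps <- 1e-6
  if (any(cx0 < -eps | cy0 < -eps |
    cx0 + w > grid$spec$capture_px + eps |
    cy0 + h > grid$spec$capture_px + eps)) {
    abort("box exits the capture frame (negative or out-of-range capture-local coordinate).",
      class = "trapscan_negative_coordinate"
    )
  }
  boxes$x <- cx0 + p$origin_x_mm * s
  boxes$y <- cy0 + p$origin_y_mm * s
  boxes$w <- w
  boxes$h <- h
  boxes
}

#' @rdname tile_to_global
#' @export
global_to_tile <- function(boxes, grid, pose, tile_origin_px = c(0, 0),
                           resize_ratio = 1) {
  stopifnot(inherits(grid, "capture_grid"))
  check_boxes(boxes)
  check_number(resize_ratio, "resize_ratio", 0, strict = TRUE)
  p <- resolve_pose(grid, pose)
  s <- px_per_mm(grid$spec)
  boxes <- as_tibble(boxes)
  if (nrow(boxes) == 0) return(boxes)
  boxes$x <- (boxes$x - p$origin_x_mm * s) * resize_ratio - tile_origin_px[[1]]
  boxes$y <- (boxes$y - p$origin_y_mm * s) * resize_ratio - tile_origin_px[[2]]
  boxes$w <- boxes$w * resize_ratio
  boxes$h <- boxes$h * resize_ratio
  boxes
}

#' Coverage of the trap card by the capture footprints
#'
#' Rasterises the card on a square lattice of cells and counts, for each
#' cell, how many capture footprints contain its centre. Used to verify
#' that the pose lattice leaves no blind spots and that interior seams are
#' imaged at least twice.
#'
#' @param grid A [build_capture_grid()] result.
#' @param cell_mm Lattice pitch in mm.
#' @return A tibble with `x_mm`, `y_mm` (cell centres) and `n_captures`.
#' @export
coverage_map <- function(grid, cell_mm = 1) {
  stopifnot(inherits(grid, "capture_grid"))
  spec <- grid$spec
  centres <- tidyr::crossing(
    x_mm = seq(cell_mm / 2, spec$trap_width_mm - cell_mm / 2, by = cell_mm),
    y_mm = seq(cell_mm / 2, spec$trap_height_mm - cell_mm / 2, by = cell_mm)
  )
  f <- spec$footprint_mm
  counts <- purrr::map_int(seq_len(nrow(centres)), function(i) {
    sum(centres$x_mm[i] >= grid$poses$origin_x_mm &
      centres$x_mm[i] <= grid$poses$origin_x_mm + f &
      centres$y_mm[i] >= grid$poses$origin_y_mm &
      centres$y_mm[i] <= grid$poses$origin_y_mm + f)
  })
  centres$n_captures <- counts
  centres
}
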
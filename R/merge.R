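#' Duplicate-suppression configuration
#'
#' @param dup_iou Global-frame IoU at or above which two same-class boxes
#'   from distinct source tiles are declared the same insect.
#' @param geom_tol_px Pixel tolerance of the exact-geometry fast path (two
#'   boxes whose corners coincide within this tolerance are duplicates) and
#'   of the tile-border adjacency test for split fragments.
#' @param require_distinct_sources If `TRUE` (default) only boxes from
#'   different source tiles can be merged; set `FALSE` to also suppress
#'   near-identical boxes within one tile.
#' @return A `merge_config` object.
#' @export
merge_config <- function(dup_iou = 0.5, geom_tol_px = 2,
                         require_distinct_sources = TRUE) {
  if (!is.numeric(dup_iou) || dup_iou <= 0 || dup_iou > 1) {
    abort("`dup_iou` must be in (0, 1].")
  }
  check_number(geom_tol_px, "geom_tol_px", 0)
  structure(
    list(dup_iou = dup_iou, geom_tol_px = geom_tol_px,
      require_distinct_sources = isTRUE(require_distinct_sources)),
    class = "merge_config"
  )
}

#' Map per-tile detections into the trap-global frame
#'
#' Converts normalized tile-local detections to trap-global pixel boxes by
#' composing the tile and pose transforms of the capture grid. Counts,
#' classes and confidences are untouched; source tile keys are carried
#' along for the duplicate-suppression rules.
#'
#' @param detections Tibble as from [stub_detect()]: tile keys plus
#'   `class_id`, `cx`, `cy`, `w`, `h` (normalized), `confidence`.
#' @param grid A [build_capture_grid()] result.
#' @param tile_px Tile side in px.
#' @return Tibble of global detections: `trap_id`, `class`, `x`, `y`, `w`,
#'   `h` (trap-global px), `confidence`, and source keys `col`, `row`,
#'   `tile_i`, `tile_j`.
#' @export
to_global <- function(detections, grid, tile_px = 416) {
  stopifnot(inherits(grid, "capture_grid"))
  need <- c(tile_key_cols, "class_id", "cx", "cy", "w", "h", "confidence")
  if (!is.data.frame(detections) || !all(need %in% names(detections))) {
    abort(sprintf("`detections` needs columns %s.", paste(need, collapse = ", ")))
  }
  det <- as_tibble(detections)
  if (nrow(det) == 0) {
    return(tibble(trap_id = character(), class = character(), x = double(),
      y = double(), w = double(), h = double(), confidence = double(),
      col = integer(), row = integer(), tile_i = integer(), tile_j = integer()))
  }
  tiles <- capture_tile_grid(grid$spec$capture_px, tile_px)
  ratio <- tiles$resize_ratio[[1]]
  if (any(!(paste(det$col, det$row) %in%
    paste(grid$poses$col, grid$poses$row)))) {
    abort("detections reference a pose not in the grid.",
      class = "trapscan_foreign_pose")
  }
  s <- px_per_mm(grid$spec)
  origin <- grid$poses[match(paste(det$col, det$row),
    paste(grid$poses$col, grid$poses$row)), ]
  # tile-local px (resized scale), clipped to the tile to absorb jitter
  bx <- pmax((det$cx - det$w / 2) * tile_px, 0)
  by <- pmax((det$cy - det$h / 2) * tile_px, 0)
  bx1 <- pmin((det$cx + det$w / 2) * tile_px, tile_px)
  by1 <- pmin((det$cy + det$h / 2) * tile_px, tile_px)
  tibble(
    trap_id = det$trap_id,
    class = class_id_to_label(det$class_id),
    x = (det$tile_i * tile_px + bx) / ratio + origin$origin_x_mm * s,
    y = (det$tile_j * tile_px + by) / ratio + origin$origin_y_mm * s,
    w = (bx1 - bx) / ratio,
    h = (by1 - by) / ratio,
    confidence = det$confidence,
    col = det$col, row = det$row, tile_i = det$tile_i, tile_j = det$tile_j
  )
}

#' Same-insect test for boxes from adjacent overlapping captures
#'
#' Two capture-local boxes depict the same physical insect when, after
#' shifting the second box by the pixel offset between the two camera
#' poses, the boxes coincide corner-for-corner within a tolerance: with
#' edge distances a (first capture), c (second capture) and pose offset d,
#' the rule is a - d = c together with equal distances to the orthogonal
#' edge. Classes must match.
#'
#' @param d1,d2 One-row data frames (or lists) with `x`, `y`, `w`, `h` in
#'   their own capture-local pixels and a `class` label.
#' @param offset Length-2 pixel offset `c(dx, dy)` of capture 2's origin
#'   relative to capture 1's, as from [neighbor_offset_px()].
#' @param tol Tolerance in px.
#' @return `TRUE` if the boxes coincide in the shared frame.
#' @export
is_same_insect <- function(d1, d2, offset, tol = 2) {
  if (!is.null(d1$class) && !is.null(d2$class) &&
    !identical(as.character(d1$class[[1]]), as.character(d2$class[[1]]))) {
    return(FALSE)
  }
  g2x <- d2$x[[1]] + offset[[1]]
  g2y <- d2$y[[1]] + offset[[2]]
  all(abs(c(
    d1$x[[1]] - g2x,
    d1$y[[1]] - g2y,
    d1$x[[1]] + d1$w[[1]] - (g2x + d2$w[[1]]),
    d1$y[[1]] + d1$h[[1]] - (g2y + d2$h[[1]])
  )) <= tol)
}

# pairwise geometry helpers on box tibbles (x, y, w, h), index vectors i, j
pair_intersection <- function(b, i, j) {
  ix0 <- pmax(b$x[i], b$x[j])
  iy0 <- pmax(b$y[i], b$y[j])
  ix1 <- pmin(b$x[i] + b$w[i], b$x[j] + b$w[j])
  iy1 <- pmin(b$y[i] + b$h[i], b$y[j] + b$h[j])
  pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0)
}

# union-find with path compression
uf_find <- function(parent, i) {
  root <- i
  while (parent[root] != root) root <- parent[root]
  root
}

#' Suppress duplicate detections across overlapping captures
#'
#' Builds a graph over same-class global boxes and keeps, within each
#' connected component, only the most credible box. Two boxes (from
#' distinct source tiles, unless configured otherwise) are linked when any
#' of these holds:
#'
#' * their global IoU is at least `dup_iou` (the general duplicate rule);
#' * their corners coincide within `geom_tol_px` (the exact-geometry rule
#'   for jitter-free overlapping captures, cf. [is_same_insect()]);
#' * their intersection covers at least `dup_iou` of the smaller box (one
#'   box is a border-clipped fragment of the insect the other saw whole);
#' * they are edge-adjacent fragments: same capture, neighbouring tiles of
#'   the 7 x 7 split, abutting within `geom_tol_px` at the shared tile
#'   border with matching transverse extents — the signature of one insect
#'   cut in two by an intra-capture tile border, since both fragments of a
#'   box cut by a vertical line inherit the same vertical extent.
#'
#' Merging is transitive (connected components), so an insect seen in up to
#' four corner-overlapping captures still collapses to one box. The kept
#' box is the one with maximal confidence; ties broken by larger area, then
#' by row-major source tile order. Because fragments cut apart by tile
#' borders are partial views rather than duplicates, the kept box's
#' geometry is the union of its component's boxes from the kept box's own
#' capture — reassembling an insect cut in two (or four) by tile borders —
#' while its confidence stays that of the best fragment. Output is ordered
#' by descending confidence.
#'
#' @param globals Global detections from [to_global()].
#' @param cfg A [merge_config()].
#' @return The deduplicated subset of `globals`.
#' @export
deduplicate <- function(globals, cfg = merge_config()) {
  stopifnot(inherits(cfg, "merge_config"))
  g <- as_tibble(globals)
  n <- nrow(g)
  if (n <= 1) return(g)
  src <- paste(g$col, g$row, g$tile_i, g$tile_j)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]
  j <- pairs[, 2]
  ok <- g$class[i] == g$class[j]
  if (cfg$require_distinct_sources) ok <- ok & (src[i] != src[j])
  i <- i[ok]
  j <- j[ok]
  linked <- logical(length(i))
  if (length(i)) {
    inter <- pair_intersection(g, i, j)
    area_i <- g$w[i] * g$h[i]
    area_j <- g$w[j] * g$h[j]
    iou <- inter / (area_i + area_j - inter)
    iomin <- inter / pmin(area_i, area_j)
    corners <- pmax(
      abs(g$x[i] - g$x[j]), abs(g$y[i] - g$y[j]),
      abs(g$x[i] + g$w[i] - g$x[j] - g$w[j]),
      abs(g$y[i] + g$h[i] - g$y[j] - g$h[j])
    )
    linked <- iou >= cfg$dup_iou | corners <= cfg$geom_tol_px |
      iomin >= cfg$dup_iou
    # edge-adjacent fragments within one capture
    same_pose <- g$col[i] == g$col[j] & g$row[i] == g$row[j]
    adj_x <- same_pose & abs(g$tile_i[i] - g$tile_i[j]) == 1 &
      g$tile_j[i] == g$tile_j[j]
    adj_y <- same_pose & abs(g$tile_j[i] - g$tile_j[j]) == 1 &
      g$tile_i[i] == g$tile_i[j]
    # left/top box of the pair per axis
    lx <- ifelse(g$x[i] <= g$x[j], i, j)
    rx <- ifelse(g$x[i] <= g$x[j], j, i)
    ty <- ifelse(g$y[i] <= g$y[j], i, j)
    by <- ifelse(g$y[i] <= g$y[j], j, i)
    gap_x <- abs(g$x[rx] - (g$x[lx] + g$w[lx]))
    gap_y <- abs(g$y[by] - (g$y[ty] + g$h[ty]))
    # fragments of one box cut by a vertical line have identical y-extents
    # (and vice versa): demand matching transverse extents, not mere overlap
    same_yext <- abs(g$y[i] - g$y[j]) <= cfg$geom_tol_px &
      abs(g$y[i] + g$h[i] - g$y[j] - g$h[j]) <= cfg$geom_tol_px
    same_xext <- abs(g$x[i] - g$x[j]) <= cfg$geom_tol_px &
      abs(g$x[i] + g$w[i] - g$x[j] - g$w[j]) <= cfg$geom_tol_px
    frag_x <- adj_x & gap_x <= cfg$geom_tol_px & same_yext
    frag_y <- adj_y & gap_y <= cfg$geom_tol_px & same_xext
    linked <- linked | frag_x | frag_y
  }
  parent <- seq_len(n)
  for (k in which(linked)) {
    ri <- uf_find(parent, i[k])
    rj <- uf_find(parent, j[k])
    if (ri != rj) parent[min(ri, rj)] <- max(ri, rj)
  }
  comp <- vapply(seq_len(n), function(ii) uf_find(parent, ii), integer(1))
  # representative: max confidence, then larger area, then row-major source
  ord <- order(
    comp, -g$confidence, -(g$w * g$h), g$row, g$col, g$tile_j, g$tile_i,
    seq_len(n)
  )
  keep <- ord[!duplicated(comp[ord])]
  out <- g[keep, , drop = FALSE]
  # same-capture members of a component are border-cut fragments of one
  # insect, not duplicates: reassemble them as the kept box's geometry
  for (r in seq_along(keep)) {
    mates <- which(comp == comp[keep[r]] &
      g$col == out$col[r] & g$row == out$row[r])
    if (length(mates) > 1) {
      x1 <- max(g$x[mates] + g$w[mates])
      y1 <- max(g$y[mates] + g$h[mates])
      out$x[r] <- min(g$x[mates])
      out$y[r] <- min(g$y[mates])
      out$w[r] <- x1 - out$x[r]
      out$h[r] <- y1 - out$y[r]
    }
  }
  out[order(-out$confidence, keep), , drop = FALSE]
}

#' Count detections per class
#'
#' @param merged Deduplicated global detections ([deduplicate()]).
#' @return Named integer vector over `c("SD", "OT")`; the two entries sum
#'   to `nrow(merged)`.
#' @export
count_classes <- function(merged) {
  tab <- table(factor(merged$class, levels = trap_classes()))
  setNames(as.integer(tab), trap_classes())
}

#' Per-cell intensity map of a counted trap
#'
#' Collapses the overlapping capture footprints to their non-overlapping
#' seam-bisected rectangles (the Voronoi cells of the pose lattice), assigns
#' every merged detection to the cell containing its centre, and bins the
#' per-cell, per-class counts on the four-level display scale: 1-4 insects
#' map to bins 1-4, more than 4 saturate at 4. Cells holding both classes
#' are flagged as combinations.
#'
#' @param merged Deduplicated global detections.
#' @param grid A [build_capture_grid()] result.
#' @return An `intensity_map`: tibble with cell indices, cell bounds in mm,
#'   per-class counts `n_sd`, `n_ot`, display bins `bin_sd`, `bin_ot` and a
#'   `combination` flag; the grid is attached as an attribute.
#' @export
build_intensity_map <- function(merged, grid) {
  stopifnot(inherits(grid, "capture_grid"))
  spec <- grid$spec
  ox <- sort(unique(grid$poses$origin_x_mm))
  oy <- sort(unique(grid$poses$origin_y_mm))
  # seam-bisected cell boundaries: midpoints of successive footprint overlaps
  bx <- c(0, (head(ox, -1) + spec$footprint_mm + tail(ox, -1)) / 2, spec$trap_width_mm)
  by <- c(0, (head(oy, -1) + spec$footprint_mm + tail(oy, -1)) / 2, spec$trap_height_mm)
  cells <- tidyr::crossing(cell_row = seq_along(oy) - 1L, cell_col = seq_along(ox) - 1L) %>%
    mutate(
      x0_mm = bx[.data$cell_col + 1L], x1_mm = bx[.data$cell_col + 2L],
      y0_mm = by[.data$cell_row + 1L], y1_mm = by[.data$cell_row + 2L]
    )
  s <- px_per_mm(spec)
  n_sd <- integer(nrow(cells))
  n_ot <- integer(nrow(cells))
  if (nrow(merged)) {
    cx <- (merged$x + merged$w / 2) / s
    cy <- (merged$y + merged$h / 2) / s
    ci <- pmin(findInterval(cx, bx, rightmost.closed = TRUE), length(ox)) - 1L
    cj <- pmin(findInterval(cy, by, rightmost.closed = TRUE), length(oy)) - 1L
    key <- paste(ci, cj)
    ckey <- paste(cells$cell_col, cells$cell_row)
    for (cls in trap_classes()) {
      tab <- table(key[merged$class == cls])
      hit <- match(ckey, names(tab))
      counts <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
      if (cls == "SD") n_sd <- counts else n_ot <- counts
    }
  }
  cells$n_sd <- n_sd
  cells$n_ot <- n_ot
  cells$bin_sd <- pmin(n_sd, 4L)
  cells$bin_ot <- pmin(n_ot, 4L)
  cells$combination <- n_sd > 0L & n_ot > 0L
  structure(cells, class = c("intensity_map", class(cells)), grid = grid)
}

#' Merge, count and map one trap's detections
#'
#' Convenience wrapper chaining [to_global()], [deduplicate()],
#' [count_classes()] and [build_intensity_map()].
#'
#' @param detections Per-tile detections ([stub_detect()] or a real
#'   detector's output).
#' @param grid A [build_capture_grid()].
#' @param cfg A [merge_config()].
#' @param tile_px Tile side in px.
#' @return A `trap_result`: list with `merged` (global detections),
#'   `counts` (named per-class vector) and `intensity` (the intensity map).
#' @export
merge_and_count <- function(detections, grid, cfg = merge_config(),
                            tile_px = 416) {
  merged <- deduplicate(to_global(detections, grid, tile_px = tile_px), cfg)
  structure(
    list(
      merged = merged,
      counts = count_classes(merged),
      intensity = build_intensity_map(merged, grid)
    ),
    class = "trap_result"
  )
}

#' @export
print.trap_result <- function(x, ...) {
  cat(sprintf("<trap_result> %d detections after duplicate suppression: %d SD, %d OT\n",
    nrow(x$merged), x$counts[["SD"]], x$counts[["OT"]]))
  invisible(x)
}

#' @describeIn merge_and_count `tidy()` returns the merged detections.
#' @param x A `trap_result`.
#' @param ... Unused.
#' @export
tidy.trap_result <- function(x, ...) x$merged

#' @describeIn merge_and_count `glance()` returns a one-row count summary.
#' @export
glance.trap_result <- function(x, ...) {
  tibble(n_sd = x$counts[["SD"]], n_ot = x$counts[["OT"]],
    n_total = sum(x$counts))
}
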
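#' Largest multiple of m not exceeding n
#'
#' The resize target used before tile splitting: a 2992 px capture is
#' resized to 2912 px, the closest multiple of the 416 px tile side that
#' does not exceed the original.
#'
#' @param n Original side length (positive integer, `n >= m`).
#' @param m Tile side (positive integer).
#' @return `m * floor(n / m)` as an integer.
#' @examples
#' nearest_multiple_down(2992, 416) # 2912
#' @export
nearest_multiple_down <- function(n, m) {
  check_number(n, "n", 1)
  check_number(m, "m", 1)
  if (n < m) abort("`n` must be at least `m`.", class = "trapscan_domain_error")
  as.integer(m * floor(n / m))
}

#' Tile lattice of a resized capture
#'
#' Enumerates the k x k non-overlapping tiles a capture splits into after
#' resizing to the nearest lower multiple of `tile_px` (7 x 7 = 49 tiles at
#' the default 2992 px capture and 416 px tile). Pure bookkeeping: no pixels
#' are touched, so whole-study tile counts can be computed instantly.
#'
#' @param capture_px Side of the (square) capture before resizing.
#' @param tile_px Tile side in px.
#' @return Tibble with 0-based `tile_i` (column) and `tile_j` (row), the
#'   tile origin within the resized capture (`origin_x_px`, `origin_y_px`),
#'   and attributes-free columns `resized_px` and `resize_ratio`.
#' @examples
#' nrow(capture_tile_grid(2992, 416)) # 49
#' @export
capture_tile_grid <- function(capture_px, tile_px = 416) {
  resized <- nearest_multiple_down(capture_px, tile_px)
  k <- resized %/% tile_px
  tidyr::crossing(tile_j = seq_len(k) - 1L, tile_i = seq_len(k) - 1L) %>%
    mutate(
      origin_x_px = .data$tile_i * tile_px,
      origin_y_px = .data$tile_j * tile_px,
      resized_px = resized,
      resize_ratio = resized / capture_px
    ) %>%
    select("tile_i", "tile_j", "origin_x_px", "origin_y_px", "resized_px", "resize_ratio")
}

#' Enumerate every tile of a multi-trap study
#'
#' Crosses trap identifiers with the capture-pose lattice and the per-capture
#' tile lattice, yielding one row per tile. With the default geometry and 65
#' traps this is 65 x 24 x 49 = 76,440 tiles.
#'
#' @param spec A [trap_spec()].
#' @param trap_ids Character or integer vector of trap identifiers.
#' @param tile_px Tile side in px.
#' @param lighting `"transmittance"` or `"reflectance"` tag attached to each
#'   tile.
#' @return Tibble keyed by `trap_id`, `col`, `row` (pose), `tile_i`,
#'   `tile_j`, `lighting`.
#' @export
enumerate_tiles <- function(spec, trap_ids, tile_px = 416,
                            lighting = c("transmittance", "reflectance")) {
  stopifnot(inherits(spec, "trap_spec"))
  lighting <- arg_match(lighting)
  grid <- build_capture_grid(spec)
  tiles <- capture_tile_grid(spec$capture_px, tile_px)
  tidyr::crossing(
    trap_id = as.character(trap_ids),
    grid$poses %>% select("col", "row"),
    tiles %>% select("tile_i", "tile_j")
  ) %>%
    mutate(lighting = lighting, tile_px = as.integer(tile_px))
}

# bilinear resize of a numeric matrix to side x side
resize_bilinear <- function(image, side) {
  out <- EBImage::resize(EBImage::Image(image), w = side, h = side,
    filter = "bilinear"
  )
  EBImage::imageData(out)
}

#' Resize a capture and split it into detector tiles
#'
#' Resizes a square capture (bilinear) to the nearest lower multiple of
#' `tile_px`, then partitions it into non-overlapping `tile_px` x `tile_px`
#' tiles in row-major order. Reassembling the tiles reproduces the resized
#' image exactly.
#'
#' @param image Square numeric matrix (grayscale raster, any intensity
#'   scale).
#' @param tile_px Tile side in px.
#' @return Tibble: `tile_i`, `tile_j`, origin columns as in
#'   [capture_tile_grid()], plus a `raster` list-column of `tile_px` square
#'   matrices.
#' @export
split_capture <- function(image, tile_px = 416) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  if (nrow(image) != ncol(image)) {
    abort("`image` must be square.", class = "trapscan_nonsquare_image")
  }
  check_number(tile_px, "tile_px", 1)
  grid <- capture_tile_grid(nrow(image), tile_px)
  resized_px <- grid$resized_px[[1]]
  resized <- if (resized_px == nrow(image)) image else resize_bilinear(image, resized_px)
  grid$raster <- purrr::map2(grid$origin_x_px, grid$origin_y_px, function(ox, oy) {
    # matrix rows index y, columns index x
    resized[(oy + 1):(oy + tile_px), (ox + 1):(ox + tile_px), drop = FALSE]
  })
  grid
}

#' Reassemble split tiles into the resized capture
#'
#' Inverse of the partition step of [split_capture()].
#'
#' @param tiles A [split_capture()] result.
#' @return The resized capture as a matrix.
#' @export
reassemble_tiles <- function(tiles) {
  stopifnot(is.data.frame(tiles), "raster" %in% names(tiles))
  resized_px <- tiles$resized_px[[1]]
  tile_px <- nrow(tiles$raster[[1]])
  out <- matrix(0, resized_px, resized_px)
  for (i in seq_len(nrow(tiles))) {
    ox <- tiles$origin_x_px[i]
    oy <- tiles$origin_y_px[i]
    out[(oy + 1):(oy + tile_px), (ox + 1):(ox + tile_px)] <- tiles$raster[[i]]
  }
  out
}
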
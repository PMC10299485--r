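# display palettes: 4 shades light -> dark, as RGB in [0, 1]
sd_shades <- cbind(r = c(1.00, 0.95, 0.85, 0.65), g = c(0.80, 0.55, 0.30, 0.08),
  b = c(0.80, 0.55, 0.30, 0.08))
ot_shades <- cbind(r = c(0.80, 0.55, 0.30, 0.08), g = c(0.80, 0.55, 0.30, 0.08),
  b = c(1.00, 0.95, 0.85, 0.65))
map_background <- c(0.98, 0.96, 0.80) # pale trap yellow

cell_rgb <- function(bin_sd, bin_ot) {
  if (bin_sd > 0 && bin_ot > 0) {
    (sd_shades[bin_sd, ] + ot_shades[bin_ot, ]) / 2
  } else if (bin_sd > 0) {
    sd_shades[bin_sd, ]
  } else if (bin_ot > 0) {
    ot_shades[bin_ot, ]
  } else {
    map_background
  }
}

#' Write an intensity map as a PNG
#'
#' Renders the per-cell map with SD cells in four red shades, OT cells in
#' four blue shades (lighter to darker for 1 to 4 insects), mixed cells
#' alpha-blended, and a legend strip of the eight shades along the bottom.
#' Output bytes are a deterministic function of the map.
#'
#' @param map An [build_intensity_map()] result.
#' @param path Output PNG path.
#' @param cell_px Size of one display cell in px.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, cell_px = 60) {
  stopifnot(inherits(map, "intensity_map"))
  n_cols <- max(map$cell_col) + 1L
  n_rows <- max(map$cell_row) + 1L
  legend_px <- cell_px %/% 2
  width <- n_cols * cell_px
  height <- n_rows * cell_px + legend_px
  img <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) img[, , ch] <- map_background[ch]
  for (k in seq_len(nrow(map))) {
    rgb <- cell_rgb(map$bin_sd[k], map$bin_ot[k])
    rows <- map$cell_row[k] * cell_px + seq_len(cell_px)
    cols <- map$cell_col[k] * cell_px + seq_len(cell_px)
    # 1px gridline border left at background colour
    for (ch in 1:3) img[rows[-c(1, cell_px)], cols[-c(1, cell_px)], ch] <- rgb[ch]
  }
  # legend: 4 SD shades then 4 OT shades
  swatch <- max(1L, width %/% 8L)
  shades <- rbind(sd_shades, ot_shades)
  for (k in 1:8) {
    cols <- ((k - 1) * swatch + 1):min(k * swatch, width)
    rows <- (n_rows * cell_px + 1):height
    for (ch in 1:3) img[rows, cols, ch] <- shades[k, ch]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' @describeIn build_intensity_map `autoplot()` draws the map with ggplot2;
#'   red tiles are SD, blue are OT, purple-ish blends carry both classes.
#' @param object An `intensity_map`.
#' @param ... Unused.
#' @export
autoplot.intensity_map <- function(object, ...) {
  df <- as_tibble(object)
  df$fill <- vapply(seq_len(nrow(df)), function(k) {
    rgb <- cell_rgb(df$bin_sd[k], df$bin_ot[k])
    grDevices::rgb(rgb[1], rgb[2], rgb[3])
  }, character(1))
  df$label <- ifelse(df$n_sd + df$n_ot > 0,
    paste0(ifelse(df$n_sd > 0, paste0(df$n_sd, " SD"), ""),
      ifelse(df$n_sd > 0 & df$n_ot > 0, "\n", ""),
      ifelse(df$n_ot > 0, paste0(df$n_ot, " OT"), "")), "")
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x0_mm, xmax = .data$x1_mm,
      ymin = -.data$y1_mm, ymax = -.data$y0_mm
    ), fill = df$fill, colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$x0_mm + .data$x1_mm) / 2,
      y = -(.data$y0_mm + .data$y1_mm) / 2, label = .data$label
    ), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "mm", y = "mm",
      title = "Trap intensity map (red = SD, blue = OT; darker = more insects)"
    ) +
    ggplot2::theme_minimal()
}
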
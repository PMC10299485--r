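#' Bundled 65-trap manual census
#'
#' Per-trap manual counts of *S. dorsalis* (SD) and other thrips (OT) from a
#' 65-trap yellow-sticky-trap field census, counted under an optical
#' microscope. Totals: 2370 SD, 307 OT, 2677 overall. These counts are
#' strongly overdispersed (SD ranges 1-196 per trap) and anchor the default
#' parameters of [scene_spec()].
#'
#' @return Tibble with `trap`, `sd`, `ot`.
#' @export
manual_trap_counts <- function() {
  path <- system.file("extdata", "manual_trap_counts.tsv", package = "trapscan")
  as_tibble(read.delim(path))
}

# method-of-moments negative-binomial fit (mu, size) to a count vector
nb_moments <- function(x) {
  mu <- mean(x)
  v <- stats::var(x)
  size <- if (v > mu) mu^2 / (v - mu) else Inf
  c(mu = mu, size = size)
}

#' Synthetic trap-scene specification
#'
#' Parameters of the synthetic scene generator. Per-trap insect loads are
#' negative binomial — the bundled census ([manual_trap_counts()]) shows
#' variance far above the mean for both classes, so a Poisson load would be
#' indefensible — and the defaults are the census' method-of-moments fits
#' (SD: mean 36.46, size 0.77; OT: mean 4.72, size 0.67).
#'
#' @param mean_sd,mean_ot Expected insects per trap for each class.
#' @param dispersion_sd,dispersion_ot Negative-binomial size parameters
#'   (smaller = more overdispersed).
#' @param insect_len_mm Mean body length, mm. Adult thrips are about 1 mm.
#' @param insect_aspect Body length / width ratio of the rendered ellipse.
#' @param min_sep_mm Minimum centre-to-centre separation between insects.
#' @param seed Integer seed consumed by [sample_scene()].
#' @return A `scene_spec` object (named list).
#' @export
scene_spec <- function(mean_sd = NULL, dispersion_sd = NULL,
                       mean_ot = NULL, dispersion_ot = NULL,
                       insect_len_mm = 1.0, insect_aspect = 3,
                       min_sep_mm = 2, seed = 1L) {
  census <- manual_trap_counts()
  fit_sd <- nb_moments(census$sd)
  fit_ot <- nb_moments(census$ot)
  mean_sd <- mean_sd %||% unname(fit_sd["mu"])
  dispersion_sd <- dispersion_sd %||% unname(fit_sd["size"])
  mean_ot <- mean_ot %||% unname(fit_ot["mu"])
  dispersion_ot <- dispersion_ot %||% unname(fit_ot["size"])
  check_number(mean_sd, "mean_sd", 0)
  check_number(mean_ot, "mean_ot", 0)
  check_number(dispersion_sd, "dispersion_sd", 0, strict = TRUE)
  check_number(dispersion_ot, "dispersion_ot", 0, strict = TRUE)
  check_number(insect_len_mm, "insect_len_mm", 0, strict = TRUE)
  check_number(insect_aspect, "insect_aspect", 1)
  check_number(min_sep_mm, "min_sep_mm", 0)
  structure(
    list(
      mean_sd = mean_sd, dispersion_sd = dispersion_sd,
      mean_ot = mean_ot, dispersion_ot = dispersion_ot,
      insect_len_mm = insect_len_mm, insect_aspect = insect_aspect,
      min_sep_mm = min_sep_mm, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

rnbinom_mu <- function(n, mu, size) {
  if (mu == 0) return(integer(n))
  if (is.infinite(size)) return(rpois(n, mu))
  rnbinom(n, size = size, mu = mu)
}

#' Sample a synthetic trap scene
#'
#' Draws per-class insect counts from the negative binomials of `spec`,
#' places insect centres uniformly on the card with rejection sampling to
#' honour the minimum separation, and assigns each insect a body length
#' (normal around `insect_len_mm`, truncated at 40% of the mean), width
#' (length / aspect) and uniform orientation. The random stream is consumed
#' in a fixed order (counts, then positions, then sizes and angles), so a
#' scene is reproducible bit-for-bit from its seed.
#'
#' @param spec A [scene_spec()].
#' @param trap A [trap_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @param trap_id Identifier attached to the scene.
#' @return A `trap_scene`: list with `insects` (tibble `insect`, `class`,
#'   `x_mm`, `y_mm`, `length_mm`, `width_mm`, `angle`), the `trap` spec,
#'   `scene_spec` and `seed`.
#' @export
sample_scene <- function(spec, trap = trap_spec(), seed = spec$seed,
                         trap_id = "trap1") {
  stopifnot(inherits(spec, "scene_spec"), inherits(trap, "trap_spec"))
  insects <- with_seed(seed, {
    n_sd <- rnbinom_mu(1, spec$mean_sd, spec$dispersion_sd)
    n_ot <- rnbinom_mu(1, spec$mean_ot, spec$dispersion_ot)
    n <- n_sd + n_ot
    xs <- numeric(n)
    ys <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(10000L)) {
        x <- runif(1, 0, trap$trap_width_mm)
        y <- runif(1, 0, trap$trap_height_mm)
        if (i == 1L ||
          all((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2 >=
            spec$min_sep_mm^2)) {
          xs[i] <- x
          ys[i] <- y
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("could not place insect without violating min_sep_mm (10,000 attempts).",
          class = "trapscan_placement_failure")
      }
    }
    len <- pmax(rnorm(n, spec$insect_len_mm, 0.15 * spec$insect_len_mm),
      0.4 * spec$insect_len_mm)
    angle <- runif(n, 0, pi)
    tibble(
      insect = seq_len(n),
      class = rep(trap_classes(), c(n_sd, n_ot)),
      x_mm = xs, y_mm = ys,
      length_mm = len, width_mm = len / spec$insect_aspect,
      angle = angle
    )
  })
  structure(
    list(insects = insects, trap = trap, scene_spec = spec,
      seed = as.integer(seed), trap_id = trap_id),
    class = "trap_scene"
  )
}

#' @export
print.trap_scene <- function(x, ...) {
  n <- table(factor(x$insects$class, levels = trap_classes()))
  cat(sprintf("<trap_scene> %s: %d SD + %d OT insects (seed %d)\n",
    x$trap_id, n[["SD"]], n[["OT"]], x$seed))
  invisible(x)
}

#' @describeIn sample_scene `tidy()` returns the insect tibble.
#' @param x A `trap_scene`.
#' @param ... Unused.
#' @export
tidy.trap_scene <- function(x, ...) x$insects

#' True bounding boxes of a scene in the trap-global frame
#'
#' Axis-aligned bounding boxes of the scene's (rotated) elliptical insects,
#' in trap-global pixels — the reference against which merged detections
#' are scored. Boxes are clipped to the card: an insect overhanging the
#' trap edge is only observable (and only rendered) on-card, so the
#' off-card sliver is not part of the ground truth.
#'
#' @param scene A [sample_scene()] result.
#' @return Tibble with `insect`, `class`, `x`, `y`, `w`, `h`.
#' @export
scene_boxes <- function(scene) {
  stopifnot(inherits(scene, "trap_scene"))
  b <- scene_boxes_px(scene)
  s <- px_per_mm(scene$trap)
  x1 <- pmin(b$x + b$w, scene$trap$trap_width_mm * s)
  y1 <- pmin(b$y + b$h, scene$trap$trap_height_mm * s)
  b$x <- pmax(b$x, 0)
  b$y <- pmax(b$y, 0)
  b$w <- x1 - b$x
  b$h <- y1 - b$y
  b
}

# axis-aligned bounding boxes of the scene's insects, trap-global px
scene_boxes_px <- function(scene) {
  s <- px_per_mm(scene$trap)
  ins <- scene$insects
  a <- ins$length_mm / 2 * s
  b <- ins$width_mm / 2 * s
  hx <- sqrt((a * cos(ins$angle))^2 + (b * sin(ins$angle))^2)
  hy <- sqrt((a * sin(ins$angle))^2 + (b * cos(ins$angle))^2)
  tibble(
    insect = ins$insect, class = ins$class,
    x = ins$x_mm * s - hx, y = ins$y_mm * s - hy,
    w = 2 * hx, h = 2 * hy
  )
}

#' Ground-truth tile annotations of a scene
#'
#' Projects each insect's bounding box into every overlapping capture and
#' tile. Boxes are clipped at capture and tile borders; a clipped fragment
#' is kept only if its area is at least `min_frag` of the full box, so a
#' sliver of an insect peeking into a tile does not generate a label. An
#' insect lying in the overlap region of k captures yields labels in all k.
#'
#' @param scene A [sample_scene()] result.
#' @param grid The [build_capture_grid()] of the same trap spec.
#' @param tile_px Tile side in px.
#' @param min_frag Minimum kept fragment area as a fraction of the full box.
#' @return Tibble with one row per label: `trap_id`, `col`, `row` (pose),
#'   `tile_i`, `tile_j`, `insect`, `class_id`, and normalized `cx`, `cy`,
#'   `w`, `h`.
#' @export
scene_annotations <- function(scene, grid, tile_px = 416, min_frag = 0.2) {
  stopifnot(inherits(scene, "trap_scene"), inherits(grid, "capture_grid"))
  stopifnot(identical(scene$trap, grid$spec))
  boxes <- scene_boxes_px(scene)
  if (nrow(boxes) == 0) {
    return(tibble(trap_id = character(), col = integer(), row = integer(),
      tile_i = integer(), tile_j = integer(), insect = integer(),
      class_id = integer(), cx = double(), cy = double(),
      w = double(), h = double()))
  }
  spec <- grid$spec
  s <- px_per_mm(spec)
  tiles <- capture_tile_grid(spec$capture_px, tile_px)
  ratio <- tiles$resize_ratio[[1]]
  full_area <- boxes$w * boxes$h * ratio^2 # at the resized-capture scale
  out <- purrr::map(seq_len(nrow(grid$poses)), function(pi) {
    pose <- grid$poses[pi, ]
    ox <- pose$origin_x_mm * s
    oy <- pose$origin_y_mm * s
    # capture-local, resized-scale coordinates
    x0 <- (boxes$x - ox) * ratio
    y0 <- (boxes$y - oy) * ratio
    x1 <- x0 + boxes$w * ratio
    y1 <- y0 + boxes$h * ratio
    resized <- tiles$resized_px[[1]]
    vis <- x1 > 0 & y1 > 0 & x0 < resized & y0 < resized
    if (!any(vis)) return(NULL)
    idx <- which(vis)
    purrr::map(seq_len(nrow(tiles)), function(ti) {
      t <- tiles[ti, ]
      tx0 <- pmax(x0[idx], t$origin_x_px)
      ty0 <- pmax(y0[idx], t$origin_y_px)
      tx1 <- pmin(x1[idx], t$origin_x_px + tile_px)
      ty1 <- pmin(y1[idx], t$origin_y_px + tile_px)
      frag <- pmax(tx1 - tx0, 0) * pmax(ty1 - ty0, 0)
      keep <- frag >= min_frag * full_area[idx]
      if (!any(keep)) return(NULL)
      k <- idx[keep]
      tibble(
        trap_id = scene$trap_id, col = pose$col, row = pose$row,
        tile_i = t$tile_i, tile_j = t$tile_j,
        insect = boxes$insect[k],
        class_id = class_label_to_id(boxes$class[k]),
        cx = ((tx0[keep] + tx1[keep]) / 2 - t$origin_x_px) / tile_px,
        cy = ((ty0[keep] + ty1[keep]) / 2 - t$origin_y_px) / tile_px,
        w = (tx1[keep] - tx0[keep]) / tile_px,
        h = (ty1[keep] - ty0[keep]) / tile_px
      )
    }) %>% purrr::compact() %>% bind_rows()
  }) %>% purrr::compact() %>% bind_rows()
  out
}

#' Render the captures of a synthetic scene
#'
#' Draws each insect as a filled dark ellipse on a bright background, one
#' raster per camera pose. Transmittance lighting is high contrast
#' (background 230/255, insect 40/255); reflectance is low contrast (insect
#' 120/255) with additive Gaussian pixel noise (sigma 8/255), mimicking the
#' two lighting regimes of the imaging rig. Ground-truth labels come from
#' [scene_annotations()].
#'
#' @param scene A [sample_scene()] result.
#' @param grid Matching [build_capture_grid()].
#' @param lighting `"transmittance"` or `"reflectance"`.
#' @param tile_px Tile side used for the ground-truth labels.
#' @param seed Seed for the reflectance pixel noise.
#' @return List with `captures` (tibble `col`, `row`, `raster` list-column
#'   of `capture_px` square matrices in `[0, 1]`) and `annotations` (the
#'   [scene_annotations()] tibble).
#' @export
render_captures <- function(scene, grid, lighting = c("transmittance", "reflectance"),
                            tile_px = 416, seed = scene$seed) {
  stopifnot(inherits(scene, "trap_scene"), inherits(grid, "capture_grid"))
  lighting <- arg_match(lighting)
  spec <- grid$spec
  s <- px_per_mm(spec)
  bg <- 230 / 255
  fg <- if (lighting == "transmittance") 40 / 255 else 120 / 255
  ins <- scene$insects
  rasters <- with_seed(seed, purrr::map(seq_len(nrow(grid$poses)), function(pi) {
    pose <- grid$poses[pi, ]
    img <- matrix(bg, spec$capture_px, spec$capture_px)
    ox <- pose$origin_x_mm * s
    oy <- pose$origin_y_mm * s
    for (i in seq_len(nrow(ins))) {
      cx <- ins$x_mm[i] * s - ox
      cy <- ins$y_mm[i] * s - oy
      a <- ins$length_mm[i] / 2 * s
      if (cx < -a - 1 || cy < -a - 1 || cx > spec$capture_px + a + 1 ||
        cy > spec$capture_px + a + 1) next
      b <- ins$width_mm[i] / 2 * s
      th <- ins$angle[i]
      xr <- max(1L, ceiling(cx - a)):min(spec$capture_px, floor(cx + a))
      yr <- max(1L, ceiling(cy - a)):min(spec$capture_px, floor(cy + a))
      if (length(xr) == 0 || length(yr) == 0 || xr[1] > tail(xr, 1) ||
        yr[1] > tail(yr, 1)) next
      dx <- outer(yr - 0.5 - cy, xr - 0.5 - cx, function(Y, X) X)
      dy <- outer(yr - 0.5 - cy, xr - 0.5 - cx, function(Y, X) Y)
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      inside <- u^2 + v^2 <= 1
      sub <- img[yr, xr, drop = FALSE]
      sub[inside] <- fg
      img[yr, xr] <- sub
    }
    if (lighting == "reflectance") {
      img <- img + matrix(rnorm(length(img), 0, 8 / 255), nrow(img))
      img[img < 0] <- 0
      img[img > 1] <- 1
    }
    img
  }))
  captures <- grid$poses %>% select("col", "row")
  captures$raster <- rasters
  list(
    captures = captures,
    annotations = scene_annotations(scene, grid, tile_px = tile_px)
  )
}
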
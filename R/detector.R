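#' Noise model of the stub detector
#'
#' The stub detector perturbs ground-truth labels with a controllable error
#' model, standing in for a trained network so that downstream merging,
#' counting and evaluation can be exercised with known error rates.
#'
#' @param p_miss Per-insect probability of dropping a truth box (false
#'   negative rate of the detector).
#' @param fp_per_tile Expected number of spurious boxes per tile (Poisson).
#' @param jitter_px Standard deviation, in tile pixels, of the Gaussian
#'   noise added to box centres and sizes.
#' @param p_classflip Probability of reporting the wrong class for a
#'   detected insect.
#' @param conf_tp,conf_fp Beta shape parameters `c(shape1, shape2)` of the
#'   confidence distributions for true and false detections.
#' @param seed Integer seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(p_miss = 0, fp_per_tile = 0, jitter_px = 0,
                       p_classflip = 0, conf_tp = c(8, 2), conf_fp = c(2, 5),
                       seed = 1L) {
  for (p in c(p_miss, p_classflip)) {
    if (!is.numeric(p) || p < 0 || p > 1) abort("probabilities must be in [0, 1].")
  }
  check_number(fp_per_tile, "fp_per_tile", 0)
  check_number(jitter_px, "jitter_px", 0)
  stopifnot(length(conf_tp) == 2, all(conf_tp > 0),
    length(conf_fp) == 2, all(conf_fp > 0))
  structure(
    list(p_miss = p_miss, fp_per_tile = fp_per_tile, jitter_px = jitter_px,
      p_classflip = p_classflip, conf_tp = conf_tp, conf_fp = conf_fp,
      seed = as.integer(seed)),
    class = "noise_spec"
  )
}

# confidence draw that degenerates to exactly 1 for a point-mass request
rconf <- function(n, shape) {
  if (is.infinite(shape[1])) return(rep(1, n))
  rbeta(n, shape[1], shape[2])
}

#' Run the stub detector on ground-truth annotations
#'
#' Each truth box is independently dropped with probability `p_miss`;
#' survivors get Gaussian centre/size jitter, a class flip with probability
#' `p_classflip`, and a confidence drawn from the true-positive Beta.
#' Spurious boxes are then added per tile with Poisson rate `fp_per_tile`
#' and confidences from the false-positive Beta. With an all-zero noise
#' spec and `conf_tp = c(Inf, 1)` the output is exactly the ground truth at
#' confidence 1 (a noiseless oracle). The random stream is consumed in a
#' fixed order (misses, jitter, flips, confidences, then false positives),
#' so results are reproducible from the seed.
#'
#' @param truth Annotation tibble as from [scene_annotations()]: tile key
#'   columns plus `class_id`, `cx`, `cy`, `w`, `h` (normalized).
#' @param noise A [noise_spec()].
#' @param tile_px Tile side in px (converts `jitter_px` to the normalized
#'   scale).
#' @param tiles Optional tibble of tile keys over which false positives are
#'   generated; defaults to the distinct tiles present in `truth`.
#' @return Detection tibble: tile keys, `class_id`, `cx`, `cy`, `w`, `h`,
#'   `confidence`.
#' @export
stub_detect <- function(truth, noise = noise_spec(), tile_px = 416, tiles = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  need <- c(tile_key_cols, "class_id", "cx", "cy", "w", "h")
  if (!is.data.frame(truth) || !all(need %in% names(truth))) {
    abort(sprintf("`truth` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (is.null(tiles)) {
    tiles <- distinct(as_tibble(truth)[tile_key_cols])
  }
  with_seed(noise$seed, {
    n <- nrow(truth)
    kept <- truth[runif(n) >= noise$p_miss, , drop = FALSE]
    m <- nrow(kept)
    sj <- noise$jitter_px / tile_px
    if (m > 0) {
      if (sj > 0) {
        kept$cx <- kept$cx + rnorm(m, 0, sj)
        kept$cy <- kept$cy + rnorm(m, 0, sj)
        kept$w <- pmax(kept$w + rnorm(m, 0, sj), 1 / tile_px)
        kept$h <- pmax(kept$h + rnorm(m, 0, sj), 1 / tile_px)
        # keep the jittered box inside the tile
        kept$w <- pmin(kept$w, 1)
        kept$h <- pmin(kept$h, 1)
        kept$cx <- pmin(pmax(kept$cx, kept$w / 2), 1 - kept$w / 2)
        kept$cy <- pmin(pmax(kept$cy, kept$h / 2), 1 - kept$h / 2)
      }
      flip <- runif(m) < noise$p_classflip
      kept$class_id <- ifelse(flip, 1L - kept$class_id, kept$class_id)
      kept$confidence <- rconf(m, noise$conf_tp)
    } else {
      kept$confidence <- double()
    }
    kept <- kept[, c(tile_key_cols, "class_id", "cx", "cy", "w", "h", "confidence")]
    fps <- NULL
    if (noise$fp_per_tile > 0 && nrow(tiles) > 0) {
      n_fp <- rpois(nrow(tiles), noise$fp_per_tile)
      total <- sum(n_fp)
      if (total > 0) {
        fps <- tiles[rep(seq_len(nrow(tiles)), n_fp), , drop = FALSE]
        fps$class_id <- sample(c(0L, 1L), total, replace = TRUE)
        fps$w <- runif(total, 0.01, 0.06)
        fps$h <- runif(total, 0.01, 0.06)
        fps$cx <- runif(total, fps$w / 2, 1 - fps$w / 2)
        fps$cy <- runif(total, fps$h / 2, 1 - fps$h / 2)
        fps$confidence <- rconf(total, noise$conf_fp)
        fps <- fps[, c(tile_key_cols, "class_id", "cx", "cy", "w", "h", "confidence")]
      }
    }
    bind_rows(kept, fps)
  })
}

#' Noiseless detector oracle
#'
#' Convenience [noise_spec()] that reproduces the ground truth exactly with
#' confidence 1.
#'
#' @param seed Integer seed (unused by the noiseless path, kept for
#'   interface symmetry).
#' @return A `noise_spec`.
#' @export
noiseless_detector <- function(seed = 1L) {
  noise_spec(p_miss = 0, fp_per_tile = 0, jitter_px = 0, p_classflip = 0,
    conf_tp = c(Inf, 1), seed = seed)
}
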
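#' Assemble a pipeline run configuration
#'
#' @param geometry A [trap_spec()].
#' @param scene A [scene_spec()].
#' @param noise A [noise_spec()].
#' @param merge A [merge_config()].
#' @param tile_px Tile side in px.
#' @param lighting Lighting tag for rendered artifacts.
#' @param seed Master seed; scene and detector seeds derive from it.
#' @param out Optional output directory; when set, [run_pipeline()] writes
#'   stage artifacts there.
#' @param render Render capture rasters and the map PNG? (Geometry-only
#'   runs skip rasterisation and are much faster.)
#' @return A `run_config` object.
#' @export
run_config <- function(geometry = trap_spec(), scene = scene_spec(),
                       noise = noise_spec(), merge = merge_config(),
                       tile_px = 416, lighting = "transmittance",
                       seed = 1L, out = NULL, render = FALSE) {
  stopifnot(inherits(geometry, "trap_spec"), inherits(scene, "scene_spec"),
    inherits(noise, "noise_spec"), inherits(merge, "merge_config"))
  check_number(seed, "seed", 0)
  structure(
    list(geometry = geometry, scene = scene, noise = noise, merge = merge,
      tile_px = as.integer(tile_px), lighting = lighting,
      seed = as.integer(seed), out = out, render = isTRUE(render)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `geometry` (fields of [trap_spec()]), `scene`
#' ([scene_spec()]), `noise` ([noise_spec()]), `merge` ([merge_config()]),
#' and scalars `tile_px`, `lighting`, `seed`, `out`, `render`. Missing keys
#' fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(fun, fields) do.call(fun, fields %||% list())
  run_config(
    geometry = build(trap_spec, cfg$geometry),
    scene = build(scene_spec, cfg$scene),
    noise = build(noise_spec, cfg$noise),
    merge = build(merge_config, cfg$merge),
    tile_px = cfg$tile_px %||% 416L,
    lighting = cfg$lighting %||% "transmittance",
    seed = cfg$seed %||% 1L,
    out = cfg$out,
    render = cfg$render %||% FALSE
  )
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Run the full capture-to-count workflow on a synthetic trap
#'
#' Executes the whole pipeline: sample a scene, derive per-tile ground
#' truth, run the (stub) detector, map detections to the trap frame,
#' suppress cross-capture duplicates, count per class, build the intensity
#' map, and score the merged detections against the scene's true boxes.
#' Identical configuration and seed give identical outputs (byte-identical
#' JSON artifacts when `out` is set).
#'
#' @param config A [run_config()] or path to a YAML config.
#' @return A `pipeline_result`: list with `scene`, `truth` (per-tile
#'   labels), `detections`, `result` (a `trap_result`), and `eval` (an
#'   `eval_result`, or `NULL` with an empty scene where no ground truth
#'   exists).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  grid <- build_capture_grid(config$geometry)
  scene <- sample_scene(config$scene, config$geometry, seed = config$seed)
  truth <- scene_annotations(scene, grid, tile_px = config$tile_px)
  noise <- config$noise
  noise$seed <- config$seed + 1L
  detections <- stub_detect(truth, noise, tile_px = config$tile_px)
  result <- merge_and_count(detections, grid, config$merge,
    tile_px = config$tile_px)
  truth_global <- scene_boxes(scene)
  eval <- NULL
  if (nrow(truth_global) > 0 || nrow(result$merged) > 0) {
    eval <- evaluate_detections(result$merged, truth_global,
      iou_thresh = config$merge$dup_iou)
  }
  out <- structure(
    list(scene = scene, truth = truth, detections = detections,
      result = result, eval = eval, config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out)) write_pipeline_artifacts(out, config$out)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$scene)
  print(x$result)
  if (is.null(x$eval)) {
    cat("  (empty scene: no ground truth to evaluate)\n")
  } else {
    print(x$eval)
  }
  invisible(x)
}

write_pipeline_artifacts <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  write_json_artifact(res$scene$insects, file.path(out, "scene.json"))
  write_json_artifact(res$detections, file.path(out, "detections.json"))
  write_json_artifact(
    list(
      counts = as.list(res$result$counts),
      merged = res$result$merged
    ),
    file.path(out, "merged.json")
  )
  if (!is.null(res$eval)) {
    write_json_artifact(
      list(
        map = res$eval$map, ap = as.list(res$eval$ap),
        confusion = res$eval$confusion,
        thresholded = res$eval$thresholded
      ),
      file.path(out, "metrics.json")
    )
  }
  labdir <- file.path(out, "labels")
  dir.create(labdir, showWarnings = FALSE)
  truth <- res$truth
  if (nrow(truth)) {
    keys <- truth %>%
      mutate(file = sprintf("%s_p%d%d_t%d%d_%s.txt", .data$trap_id,
        .data$row, .data$col, .data$tile_j, .data$tile_i, cfg$lighting))
    for (f in unique(keys$file)) {
      write_yolo(keys[keys$file == f, c("class_id", "cx", "cy", "w", "h")],
        file.path(labdir, f))
    }
  }
  if (cfg$render) {
    grid <- build_capture_grid(cfg$geometry)
    rend <- render_captures(res$scene, grid, lighting = cfg$lighting,
      tile_px = cfg$tile_px, seed = cfg$seed + 2L)
    capdir <- file.path(out, "captures")
    dir.create(capdir, showWarnings = FALSE)
    for (i in seq_len(nrow(rend$captures))) {
      png::writePNG(
        rend$captures$raster[[i]],
        file.path(capdir, sprintf("%s_p%d%d_%s.png", res$scene$trap_id,
          rend$captures$row[i], rend$captures$col[i], cfg$lighting))
      )
    }
    render_map(res$result$intensity, file.path(out, "map.png"))
  }
  invisible(out)
}
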
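# internal helpers shared across modules

#' Detection class labels
#'
#' The two detection classes used throughout: `"SD"` (*Scirtothrips
#' dorsalis*, chilli thrips) and `"OT"` (other thrips). YOLO class indices
#' are fixed as 0 = SD, 1 = OT.
#'
#' @return Character vector `c("SD", "OT")`.
#' @export
trap_classes <- function() c("SD", "OT")

class_id_to_label <- function(id) {
  stopifnot(all(id %in% c(0L, 1L)))
  c("SD", "OT")[id + 1L]
}

class_label_to_id <- function(label) {
  stopifnot(all(label %in% trap_classes()))
  match(label, trap_classes()) - 1L
}

# an empty detection/box tibble with the canonical columns
empty_boxes <- function(extra = character()) {
  base <- tibble(x = double(), y = double(), w = double(), h = double())
  for (col in extra) base[[col]] <- vector(mode_for_column(col), 0L)
  base
}

mode_for_column <- function(col) {
  switch(col,
    class = "character",
    confidence = "double",
    trap_id = "character",
    lighting = "character",
    "double"
  )
}

check_number <- function(x, name, min = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric of length %d.", name, len))
  }
  bad <- if (strict) any(x <= min) else any(x < min)
  if (bad) {
    abort(sprintf(
      "`%s` must be %s %s.", name, if (strict) "greater than" else "at least", min
    ))
  }
  invisible(x)
}

# scoped RNG: run `expr` under `seed` without disturbing the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}
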
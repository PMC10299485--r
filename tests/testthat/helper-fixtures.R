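# shared fixtures: small geometries and random-box generators

# a small trap whose captures are cheap to rasterize (416 px, 2x2 poses)
small_spec <- function() {
  trap_spec(trap_width_mm = 90, trap_height_mm = 90, footprint_mm = 50,
    capture_px = 416, n_cols = 2, n_rows = 2)
}

random_boxes <- function(n, extent = 1000, wmax = 60) {
  tibble::tibble(
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    w = runif(n, 5, wmax), h = runif(n, 5, wmax)
  )
}

# random global detections with planted duplicate clusters: each cluster is
# one "insect" box replicated into 1-4 source tiles with small perturbation
random_dedup_instance <- function(n_clusters, max_copies = 4, extent = 5000) {
  base <- random_boxes(n_clusters, extent = extent)
  base$class <- sample(trap_classes(), n_clusters, replace = TRUE)
  rows <- lapply(seq_len(n_clusters), function(k) {
    copies <- sample.int(max_copies, 1)
    src <- sample.int(200, copies) # distinct source tiles
    tibble::tibble(
      trap_id = "t",
      class = base$class[k],
      x = base$x[k] + runif(copies, -1, 1),
      y = base$y[k] + runif(copies, -1, 1),
      w = pmax(base$w[k] + runif(copies, -1, 1), 2),
      h = pmax(base$h[k] + runif(copies, -1, 1), 2),
      confidence = runif(copies),
      col = src %% 6L, row = src %/% 50L,
      tile_i = (src * 7L) %% 7L, tile_j = (src * 3L) %% 7L
    )
  })
  dplyr::bind_rows(rows)[sample.int(sum(sapply(rows, nrow))), ]
}

# independent O(n^2) dedup oracle: same pairwise predicate re-derived from
# first principles, components via igraph, argmax confidence per component
oracle_dedup <- function(g, dup_iou = 0.5, tol = 2) {
  n <- nrow(g)
  if (n <= 1) return(g)
  adj <- matrix(FALSE, n, n)
  src <- paste(g$col, g$row, g$tile_i, g$tile_j)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (g$class[i] != g$class[j] || src[i] == src[j]) next
      ix <- max(0, min(g$x[i] + g$w[i], g$x[j] + g$w[j]) - max(g$x[i], g$x[j]))
      iy <- max(0, min(g$y[i] + g$h[i], g$y[j] + g$h[j]) - max(g$y[i], g$y[j]))
      inter <- ix * iy
      ai <- g$w[i] * g$h[i]; aj <- g$w[j] * g$h[j]
      iou <- inter / (ai + aj - inter)
      iomin <- inter / min(ai, aj)
      corners <- max(abs(g$x[i] - g$x[j]), abs(g$y[i] - g$y[j]),
        abs(g$x[i] + g$w[i] - g$x[j] - g$w[j]),
        abs(g$y[i] + g$h[i] - g$y[j] - g$h[j]))
      same_pose <- g$col[i] == g$col[j] && g$row[i] == g$row[j]
      frag <- FALSE
      if (same_pose) {
        same_y <- abs(g$y[i] - g$y[j]) <= tol &&
          abs(g$y[i] + g$h[i] - g$y[j] - g$h[j]) <= tol
        same_x <- abs(g$x[i] - g$x[j]) <= tol &&
          abs(g$x[i] + g$w[i] - g$x[j] - g$w[j]) <= tol
        if (abs(g$tile_i[i] - g$tile_i[j]) == 1 && g$tile_j[i] == g$tile_j[j]) {
          gap <- if (g$x[i] <= g$x[j]) abs(g$x[j] - g$x[i] - g$w[i]) else abs(g$x[i] - g$x[j] - g$w[j])
          frag <- gap <= tol && same_y
        } else if (abs(g$tile_j[i] - g$tile_j[j]) == 1 && g$tile_i[i] == g$tile_i[j]) {
          gap <- if (g$y[i] <= g$y[j]) abs(g$y[j] - g$y[i] - g$h[i]) else abs(g$y[i] - g$y[j] - g$h[j])
          frag <- gap <= tol && same_x
        }
      }
      adj[i, j] <- adj[j, i] <- iou >= dup_iou || corners <= tol ||
        iomin >= dup_iou || frag
    }
  }
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj, "undirected"))$membership
  keep <- vapply(unique(comp), function(cc) {
    members <- which(comp == cc)
    members[order(-g$confidence[members], -(g$w[members] * g$h[members]),
      g$row[members], g$col[members], g$tile_j[members], g$tile_i[members],
      members)][1]
  }, integer(1))
  out <- g[keep, ]
  # reassemble same-capture fragments of each component around the kept box
  for (r in seq_along(keep)) {
    mates <- which(comp == comp[keep[r]] &
      g$col == out$col[r] & g$row == out$row[r])
    if (length(mates) > 1) {
      out$x[r] <- min(g$x[mates])
      out$y[r] <- min(g$y[mates])
      out$w[r] <- max(g$x[mates] + g$w[mates]) - out$x[r]
      out$h[r] <- max(g$y[mates] + g$h[mates]) - out$y[r]
    }
  }
  out[order(-out$confidence), ]
}

# threshold + flood-fill blob finder (independent of the package's code
# paths) used to re-detect rendered insects
find_blobs <- function(img, thresh = 0.5) {
  mask <- img < thresh
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  n <- max(lab)
  if (n == 0) return(tibble::tibble(x = double(), y = double(), n_px = integer()))
  d <- EBImage::imageData(lab)
  purrr::map_dfr(seq_len(n), function(k) {
    idx <- which(d == k, arr.ind = TRUE)
    tibble::tibble(y = mean(idx[, 1]) - 0.5, x = mean(idx[, 2]) - 0.5,
      n_px = nrow(idx))
  })
}
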
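#' Intersection over union of bounding boxes
#'
#' Boxes are `(x, y, w, h)` with half-open pixel extent. Vectorised
#' elementwise over two box tables of equal length (or length one, which
#' recycles). Degenerate (zero-area) boxes have IoU 0 with everything,
#' including each other.
#'
#' @param a,b Data frames with columns `x`, `y`, `w`, `h`.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' bbox_iou(data.frame(x = 0, y = 0, w = 2, h = 2),
#'          data.frame(x = 1, y = 1, w = 2, h = 2)) # 1/7
#' @export
bbox_iou <- function(a, b) {
  check_boxes(a)
  check_boxes(b)
  ix0 <- pmax(a$x, b$x)
  iy0 <- pmax(a$y, b$y)
  ix1 <- pmin(a$x + a$w, b$x + b$w)
  iy1 <- pmin(a$y + a$h, b$y + b$h)
  inter <- pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0)
  union <- a$w * a$h + b$w * b$h - inter
  ifelse(union > 0, inter / union, 0)
}

# IoU matrix: rows = boxes of a, columns = boxes of b
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(0, nrow(a), nrow(b)))
  ix0 <- outer(a$x, b$x, pmax)
  iy0 <- outer(a$y, b$y, pmax)
  ix1 <- outer(a$x + a$w, b$x + b$w, pmin)
  iy1 <- outer(a$y + a$h, b$y + b$h, pmin)
  inter <- pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0)
  union <- outer(a$w * a$h, b$w * b$h, `+`) - inter
  out <- inter / union
  out[union <= 0] <- 0
  out
}

#' Greedy confidence-ordered detection matching
#'
#' Processes predictions in order of descending confidence (ties broken by
#' input order) and assigns each to the not-yet-matched ground truth with
#' the highest IoU at or above the threshold. Matching is one-to-one. With
#' `by_class = TRUE` predictions only match truths of the same class (the
#' protocol used for per-class AP); with `FALSE` localisation is
#' class-agnostic and both class labels are recorded per pair (the protocol
#' used for confusion matrices).
#'
#' @param preds Tibble with `x`, `y`, `w`, `h`, `class`, `confidence`.
#' @param truths Tibble with `x`, `y`, `w`, `h`, `class`.
#' @param iou_thresh Minimum IoU for a match.
#' @param by_class Restrict matches to equal class labels?
#' @return A `match_result`: `pairs` tibble (`pred`, `truth` row indices,
#'   `iou`, `pred_class`, `truth_class`), `unmatched_pred` and
#'   `unmatched_truth` index vectors.
#' @export
match_detections <- function(preds, truths, iou_thresh = 0.5, by_class = FALSE) {
  check_boxes(preds)
  check_boxes(truths)
  np <- nrow(preds)
  nt <- nrow(truths)
  ord <- order(-preds$confidence, seq_len(np))
  iou <- iou_matrix(preds, truths)
  truth_taken <- logical(nt)
  pair_pred <- integer(0)
  pair_truth <- integer(0)
  pair_iou <- double(0)
  for (p in ord) {
    cand <- which(!truth_taken & iou[p, ] >= iou_thresh)
    if (by_class) cand <- cand[truths$class[cand] == preds$class[p]]
    if (length(cand) == 0) next
    best <- cand[which.max(iou[p, cand])]
    truth_taken[best] <- TRUE
    pair_pred <- c(pair_pred, p)
    pair_truth <- c(pair_truth, best)
    pair_iou <- c(pair_iou, iou[p, best])
  }
  structure(
    list(
      pairs = tibble(
        pred = pair_pred, truth = pair_truth, iou = pair_iou,
        pred_class = preds$class[pair_pred],
        truth_class = truths$class[pair_truth]
      ),
      unmatched_pred = setdiff(seq_len(np), pair_pred),
      unmatched_truth = setdiff(seq_len(nt), pair_truth)
    ),
    class = "match_result"
  )
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, with the
#' convention that an empty denominator yields 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A value in `[0, 1]`.
#' @export
precision_score <- function(tp, fp) {
  check_number(tp, "tp", 0)
  check_number(fp, "fp", 0)
  if (tp + fp == 0) 0 else tp / (tp + fp)
}

#' @rdname precision_score
#' @export
recall_score <- function(tp, fn) {
  check_number(tp, "tp", 0)
  check_number(fn, "fn", 0)
  if (tp + fn == 0) 0 else tp / (tp + fn)
}

# precision-recall points of a confidence-sorted prediction list for one class
pr_points <- function(preds, truths, class, iou_thresh) {
  p <- preds[preds$class == class, , drop = FALSE]
  t <- truths[truths$class == class, , drop = FALSE]
  nt <- nrow(t)
  if (nt == 0) return(NULL)
  if (nrow(p) == 0) {
    return(tibble(confidence = double(), recall = 0, precision = 0)[0, ])
  }
  ord <- order(-p$confidence, seq_len(nrow(p)))
  p <- p[ord, , drop = FALSE]
  iou <- iou_matrix(p, t)
  taken <- logical(nt)
  is_tp <- logical(nrow(p))
  for (k in seq_len(nrow(p))) {
    cand <- which(!taken & iou[k, ] >= iou_thresh)
    if (length(cand)) {
      taken[cand[which.max(iou[k, cand])]] <- TRUE
      is_tp[k] <- TRUE
    }
  }
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  tibble(
    confidence = p$confidence,
    recall = tp / nt,
    precision = tp / (tp + fp)
  )
}

# all-points interpolated area under the precision envelope
ap_from_points <- function(pr) {
  if (nrow(pr) == 0) return(0)
  rec <- c(0, pr$recall)
  prec <- c(0, pr$precision)
  # precision envelope: running max from the right
  env <- rev(cummax(rev(prec)))
  sum(diff(rec) * env[-1])
}

#' Average precision for one class
#'
#' Sweeps the confidence ranking of the class-restricted predictions,
#' accumulates the precision-recall curve under greedy IoU matching, and
#' integrates the area under the interpolated precision envelope
#' (all-points interpolation). AP is undefined — returned as `NA` — when
#' the class has no ground-truth boxes, which is distinct from an AP of 0
#' (ground truth present but never matched).
#'
#' @inheritParams match_detections
#' @param class Class label to score.
#' @return AP in `[0, 1]`, or `NA_real_` if undefined.
#' @export
average_precision <- function(preds, truths, class, iou_thresh = 0.5) {
  pr <- pr_points(preds, truths, class, iou_thresh)
  if (is.null(pr)) return(NA_real_)
  ap_from_points(pr)
}

#' Mean average precision over classes
#'
#' Arithmetic mean of the defined per-class APs; classes whose AP is
#' undefined (no ground truth) are excluded. Errors if every AP is
#' undefined.
#'
#' @param per_class_ap Numeric vector of APs, possibly with `NA`s.
#' @return The mean, in `[0, 1]`.
#' @examples
#' mean_ap(c(0.907, 0.913)) # 0.910
#' @export
mean_ap <- function(per_class_ap) {
  ok <- !is.na(per_class_ap)
  if (!any(ok)) abort("all per-class APs are undefined.", class = "trapscan_no_ap")
  mean(per_class_ap[ok])
}

#' Compile an actual-versus-predicted confusion matrix
#'
#' Tallies the class labels of the matched pairs of a class-agnostic
#' [match_detections()] run: localisation decides which prediction explains
#' which ground truth, and the two class labels index the 2 x 2 cell. Row
#' sums therefore equal the number of localised ground-truth boxes per
#' actual class, and misclassified insects land off-diagonal. Unmatched
#' predictions and truths are attached as attributes rather than silently
#' dropped.
#'
#' @param match A [match_detections()] result (run with `by_class = FALSE`).
#' @return 2 x 2 integer matrix, rows = actual class, columns = predicted
#'   class, with `unmatched_pred` / `unmatched_truth` counts as attributes.
#' @export
compile_confusion <- function(match) {
  stopifnot(inherits(match, "match_result"))
  cls <- trap_classes()
  m <- matrix(0L, 2, 2, dimnames = list(actual = cls, predicted = cls))
  if (nrow(match$pairs)) {
    tab <- table(
      factor(match$pairs$truth_class, levels = cls),
      factor(match$pairs$pred_class, levels = cls)
    )
    m[] <- as.integer(tab)
  }
  attr(m, "unmatched_pred") <- length(match$unmatched_pred)
  attr(m, "unmatched_truth") <- length(match$unmatched_truth)
  m
}

#' Score detections against ground truth
#'
#' Computes, in one pass: per-class average precision and mAP at the IoU
#' threshold; the class-agnostic confusion matrix of localised pairs; and
#' per-class precision/recall at a stated confidence threshold. All boxes
#' must be in one common frame (tile-local or trap-global, as long as the
#' two tables agree).
#'
#' @inheritParams match_detections
#' @param conf_thresh Confidence cutoff for the thresholded
#'   precision/recall operating point.
#' @return An `eval_result`: list with `ap` (named per-class vector),
#'   `map` (mAP), `confusion`, `thresholded` (per-class tibble of tp/fp/fn,
#'   precision, recall at `conf_thresh`), `pr_curves` (per-class PR
#'   points), and the thresholds used.
#' @export
evaluate_detections <- function(preds, truths, iou_thresh = 0.5,
                                conf_thresh = 0.25) {
  cls <- trap_classes()
  curves <- lapply(setNames(cls, cls), function(cl) {
    pr_points(preds, truths, cl, iou_thresh)
  })
  ap <- vapply(curves, function(pr) if (is.null(pr)) NA_real_ else ap_from_points(pr),
    double(1))
  match_all <- match_detections(preds, truths, iou_thresh, by_class = FALSE)
  confusion <- compile_confusion(match_all)
  kept <- preds[preds$confidence >= conf_thresh, , drop = FALSE]
  thr <- purrr::map(cls, function(cl) {
    p <- kept[kept$class == cl, , drop = FALSE]
    t <- truths[truths$class == cl, , drop = FALSE]
    m <- match_detections(p, t, iou_thresh, by_class = TRUE)
    tp <- nrow(m$pairs)
    tibble(
      class = cl, tp = tp, fp = nrow(p) - tp, fn = nrow(t) - tp,
      precision = precision_score(tp, nrow(p) - tp),
      recall = recall_score(tp, nrow(t) - tp)
    )
  }) %>% bind_rows()
  structure(
    list(
      ap = ap, map = if (all(is.na(ap))) NA_real_ else mean_ap(ap),
      confusion = confusion, thresholded = thr, pr_curves = curves,
      iou_thresh = iou_thresh, conf_thresh = conf_thresh,
      n_pred = nrow(preds), n_truth = nrow(truths)
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> mAP@%.2g = %s over %d predictions / %d truths\n",
    x$iou_thresh,
    if (is.na(x$map)) "undefined" else sprintf("%.4f", x$map),
    x$n_pred, x$n_truth))
  for (cl in names(x$ap)) {
    cat(sprintf("  AP[%s] = %s\n", cl,
      if (is.na(x$ap[[cl]])) "undefined" else sprintf("%.4f", x$ap[[cl]])))
  }
  invisible(x)
}

#' @describeIn evaluate_detections `tidy()` returns one row per class with
#'   AP and the thresholded precision/recall.
#' @param x An `eval_result`.
#' @param ... Unused.
#' @export
tidy.eval_result <- function(x, ...) {
  ap <- tibble(class = names(x$ap), ap = unname(x$ap))
  left_join(ap, x$thresholded, by = "class")
}

#' @describeIn evaluate_detections `glance()` returns a one-row summary
#'   (mAP, thresholds, totals).
#' @export
glance.eval_result <- function(x, ...) {
  tibble(
    map = x$map, iou_thresh = x$iou_thresh, conf_thresh = x$conf_thresh,
    n_pred = x$n_pred, n_truth = x$n_truth,
    unmatched_pred = attr(x$confusion, "unmatched_pred"),
    unmatched_truth = attr(x$confusion, "unmatched_truth")
  )
}

#' @describeIn evaluate_detections `autoplot()` draws the per-class
#'   precision-recall curves.
#' @param object An `eval_result`.
#' @export
autoplot.eval_result <- function(object, ...) {
  df <- purrr::imap(object$pr_curves, function(pr, cl) {
    if (is.null(pr) || nrow(pr) == 0) return(NULL)
    pr$class <- cl
    pr
  }) %>% purrr::compact() %>% bind_rows()
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() + ggplot2::labs(title = "No defined PR curves"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$recall, .data$precision,
    colour = .data$class)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::scale_colour_manual(values = c(SD = "firebrick", OT = "steelblue")) +
    ggplot2::labs(
      title = sprintf("Precision-recall at IoU %.2g", object$iou_thresh),
      x = "Recall", y = "Precision", colour = "Class"
    ) +
    ggplot2::theme_minimal()
}

#' Bundled validation-set confusion counts and published per-class mAP
#'
#' Actual-versus-predicted bounding-box counts for two detector models
#' (YOLOv5 and EfficientDet-D0) evaluated on the two lighting datasets and
#' their combination, plus the corresponding published per-class mAP@0.5
#' percentages. Bundled so confusion-matrix arithmetic (per-class recall,
#' macro averages) can be recomputed and checked.
#'
#' @return `validation_confusion()`: tibble `dataset`, `model`, `actual`,
#'   `pred_sd`, `pred_ot`. `validation_map50()`: tibble `dataset`, `model`,
#'   `class`, `map50` (percent).
#' @export
validation_confusion <- function() {
  path <- system.file("extdata", "validation_confusion.tsv", package = "trapscan")
  as_tibble(read.delim(path))
}

#' @rdname validation_confusion
#' @export
validation_map50 <- function() {
  path <- system.file("extdata", "validation_map50.tsv", package = "trapscan")
  as_tibble(read.delim(path))
}

#' Per-class recall from bundled confusion counts
#'
#' @param confusion A tibble in the shape of [validation_confusion()].
#' @return The input with `n_actual`, `n_correct` and `recall_pct`
#'   (percent, recall of the diagonal cell) appended.
#' @export
confusion_recall <- function(confusion = validation_confusion()) {
  confusion %>%
    mutate(
      n_actual = .data$pred_sd + .data$pred_ot,
      n_correct = ifelse(.data$actual == "SD", .data$pred_sd, .data$pred_ot),
      recall_pct = 100 * purrr::map2_dbl(.data$n_correct, .data$n_actual,
        ~ recall_score(.x, .y - .x))
    )
}
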
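#' 1-D intersection over union of two frame intervals
#'
#' Frames are counted under the half-open convention; the union of two
#' disjoint intervals is the sum of their lengths.
#'
#' @param a,b one-row data frames (or lists) with `start` and `end`.
#' @return Ratio in `[0, 1]`.
#' @export
interval_iou <- function(a, b) {
  inter <- max(0, min(a$end, b$end) - max(a$start, b$start))
  union <- (a$end - a$start) + (b$end - b$start) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Match detections to ground-truth labels at one IoU threshold
#'
#' Greedy one-to-one matching by descending IoU. A matched pair with
#' IoU >= `tau` is a true positive; a matched pair with 0 < IoU < `tau`
#' consumes the detection but counts the label as a false negative (below
#' the quality bar, yet overlapping - so not a spurious detection). A
#' detection overlapping no label at all (IoU = 0 throughout) is a false
#' positive; every unmatched label is a false negative. This differs from
#' common object-detection practice, where a sub-threshold match also counts
#' as a false positive.
#'
#' @param detections data frame of detected events (`start`, `end`).
#' @param labels data frame of ground-truth intervals (`start`, `end`).
#' @param tau IoU threshold in `(0, 1]`.
#' @return Named vector `c(tp, fp, fn)`.
#' @export
match_detections <- function(detections, labels, tau) {
  stopifnot(tau > 0, tau <= 1)
  nd <- if (is.null(detections)) 0 else nrow(detections)
  nl <- if (is.null(labels)) 0 else nrow(labels)
  if (nd == 0) return(c(tp = 0, fp = 0, fn = nl))
  if (nl == 0) return(c(tp = 0, fp = nd, fn = 0))
  iou <- matrix(0, nd, nl)
  for (i in seq_len(nd))
    for (j in seq_len(nl))
      iou[i, j] <- interval_iou(detections[i, ], labels[j, ])
  det_used <- rep(FALSE, nd)
  lab_used <- rep(FALSE, nl)
  tp <- 0
  ord <- order(-iou)
  for (k in ord) {
    if (iou[k] <= 0) break
    i <- (k - 1) %% nd + 1
    j <- (k - 1) %/% nd + 1
    if (det_used[i] || lab_used[j]) next
    det_used[i] <- TRUE
    lab_used[j] <- TRUE
    if (iou[i, j] >= tau) tp <- tp + 1
  }
  # detections never overlapping any label are the false positives
  fp <- sum(!det_used & apply(iou, 1, max) == 0)
  fn <- nl - tp
  c(tp = tp, fp = fp, fn = fn)
}

#' Precision-recall curve over an IoU threshold sweep
#'
#' Sweeps `n_thresholds` equispaced IoU thresholds over `(0, 1]`, computes
#' precision `TP/(TP+FP)` and recall `TP/(TP+FN)` at each, and marks the
#' F1-maximising point as the optimal operating point (ties broken toward
#' the higher threshold).
#'
#' @inheritParams match_detections
#' @param n_thresholds number of thresholds, default 20.
#' @return An object of class `pr_curve`: `points` data frame
#'   (`iou_threshold`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`) and
#'   `optimal` (the selected row). With neither labels nor detections the
#'   metrics are `NA`.
#' @export
pr_curve <- function(detections, labels, n_thresholds = 20) {
  stopifnot(n_thresholds >= 2)
  taus <- seq_len(n_thresholds) / n_thresholds
  rows <- lapply(taus, function(tau) {
    m <- match_detections(detections, labels, tau)
    prec <- if (m["tp"] + m["fp"] > 0) m["tp"] / (m["tp"] + m["fp"]) else NA_real_
    rec <- if (m["tp"] + m["fn"] > 0) m["tp"] / (m["tp"] + m["fn"]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    data.frame(iou_threshold = tau, tp = m[["tp"]], fp = m[["fp"]], fn = m[["fn"]],
               precision = unname(prec), recall = unname(rec), f1 = unname(f1))
  })
  points <- do.call(rbind, rows)
  optimal <- if (all(is.na(points$f1))) NULL else {
    best <- max(points$f1, na.rm = TRUE)
    cand <- which(points$f1 == best)
    points[max(cand), , drop = FALSE] # tie -> higher threshold
  }
  structure(list(points = points, optimal = optimal), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve>\n")
  if (is.null(x$optimal)) {
    cat(" no labels and no detections: metrics undefined\n")
  } else {
    cat(sprintf(" optimal: IoU %.2f, precision %.3f, recall %.3f (F1 %.3f)\n",
                x$optimal$iou_threshold, x$optimal$precision,
                x$optimal$recall, x$optimal$f1))
  }
  invisible(x)
}

#' Evaluate a detection report against labelled errors
#'
#' Pools events per error type and computes one PR curve per type.
#'
#' @param report an [detect_errors()] report, or a plain event data frame.
#' @param labels data frame of ground-truth labels (`type`, `start`, `end`).
#' @param n_thresholds IoU sweep resolution.
#' @return Named list of [pr_curve()] objects per error type present in
#'   detections or labels.
#' @export
evaluate_report <- function(report, labels, n_thresholds = 20) {
  events <- if (inherits(report, "error_report")) report$events else report
  types <- union(unique(events$type), unique(labels$type))
  out <- list()
  for (tp in types) {
    out[[tp]] <- pr_curve(events[events$type == tp, , drop = FALSE],
                          labels[labels$type == tp, , drop = FALSE],
                          n_thresholds)
  }
  out
}

#' Read / write labelled error intervals as JSON
#'
#' Schema: `[{"type": string, "start": int, "end": int}, ...]`, half-open
#' 0-based frame intervals.
#'
#' @param path file path.
#' @export
read_labels <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0) return(data.frame(type = character(0), start = integer(0), end = integer(0)))
  stopifnot(all(c("type", "start", "end") %in% names(df)))
  df[, c("type", "start", "end")]
}

#' @rdname read_labels
#' @param labels label data frame.
#' @export
write_labels <- function(labels, path) {
  jsonlite::write_json(labels, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
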
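#' Pixel confusion counts
#'
#' Tallies true/false positive/negative pixels between a predicted and a
#' reference binary mask.
#'
#' @param pred,truth Binary arrays of identical shape (values 0/1).
#' @return A `museg_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("confusion: mask shapes differ (",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), ")")
  }
  if (any(!pred %in% c(0, 1)) || any(!truth %in% c(0, 1))) {
    stop("confusion: masks must be binary (0/1)")
  }
  p <- as.numeric(pred); t <- as.numeric(truth)
  tp <- sum(p * t)
  fp <- sum(p * (1 - t))
  fn <- sum((1 - p) * t)
  tn <- length(p) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "museg_counts")
}

counts_ok <- function(c) {
  if (any(unlist(c[c("tp", "fp", "fn", "tn")]) < 0)) {
    stop("confusion counts must be nonnegative")
  }
  invisible(c)
}

ratio_pct <- function(num, den, c) {
  if (den == 0) {
    if (c$tp == 0 && c$fp == 0 && c$fn == 0) return(100)
    warning("zero denominator in metric; returning 0")
    return(0)
  }
  100 * num / den
}

#' Pixel-count segmentation metrics
#'
#' Precision = TP/(TP+FP), IoU = TP/(TP+FP+FN), and
#' Dice = 2TP/((TP+FP)+(TP+FN)), each scaled to percent. A zero
#' denominator yields 0 with a warning, except the doubly-empty case
#' (tp = fp = fn = 0) which yields 100.
#'
#' @param c A `museg_counts` (or list with tp/fp/fn/tn).
#' @return Percentage in \[0, 100\].
#' @export
precision <- function(c) {
  counts_ok(c)
  ratio_pct(c$tp, c$tp + c$fp, c)
}

#' @rdname precision
#' @export
iou <- function(c) {
  counts_ok(c)
  ratio_pct(c$tp, c$tp + c$fp + c$fn, c)
}

#' @rdname precision
#' @export
dice <- function(c) {
  counts_ok(c)
  ratio_pct(2 * c$tp, (c$tp + c$fp) + (c$tp + c$fn), c)
}

#' Dice implied by an IoU value
#'
#' When Dice and IoU come from the same confusion counts they satisfy
#' Dice = 2 IoU / (1 + IoU). Used to audit reported metric tables for
#' internal consistency.
#'
#' @param iou_pct IoU on the percent scale, in \[0, 100\].
#' @param digits Decimals to round to (default 2, for table audits).
#' @return Dice on the percent scale.
#' @export
dice_from_iou <- function(iou_pct, digits = 2) {
  if (any(!is.finite(iou_pct)) || any(iou_pct < 0) || any(iou_pct > 100)) {
    stop("iou_pct must lie in [0, 100]")
  }
  i <- iou_pct / 100
  round(100 * 2 * i / (1 + i), digits)
}

#' Pooled evaluation of a model over a dataset
#'
#' Confusion counts are pooled (summed) over all pixels of all images and
#' the metrics computed once from the pooled counts (micro averaging), so
#' the reported Dice and IoU satisfy the shared-count identity exactly.
#'
#' @param model A `museg_model`, or a function `function(image) -> binary
#'   mask` (useful for oracle stubs).
#' @param dataset Nonempty list of samples with `$image` and `$mask`.
#' @param threshold Probability cutoff for binarization.
#' @param per_image Also return a per-image metric data frame.
#' @return A `museg_metrics` list: `precision`, `iou`, `dice` (percent),
#'   `counts`, and optionally `per_image`.
#' @export
evaluate <- function(model, dataset, threshold = 0.5, per_image = FALSE) {
  if (length(dataset) == 0) stop("evaluate: dataset is empty")
  preds <- if (is.function(model)) {
    lapply(dataset, function(s) model(s$image))
  } else {
    batched_predictions(model, dataset, threshold)
  }
  tot <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  rows <- NULL
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    cm <- confusion(preds[[i]], s$mask)
    tot$tp <- tot$tp + cm$tp; tot$fp <- tot$fp + cm$fp
    tot$fn <- tot$fn + cm$fn; tot$tn <- tot$tn + cm$tn
    if (per_image) {
      rows <- rbind(rows, data.frame(index = i,
                                     precision = suppressWarnings(precision(cm)),
                                     iou = suppressWarnings(iou(cm)),
                                     dice = suppressWarnings(dice(cm))))
    }
  }
  class(tot) <- "museg_counts"
  metrics_report(tot, per_image = rows)
}

# Forward images through the model in small batches (inference only).
batched_predictions <- function(model, dataset, threshold, batch = 4L) {
  preds <- vector("list", length(dataset))
  i <- 1L
  while (i <= length(dataset)) {
    idx <- i:min(i + batch - 1L, length(dataset))
    xs <- lapply(dataset[idx], function(s) to_model_input(s$image))
    d <- dim(xs[[1]])
    xb <- array(0, c(d[2], d[3], 3L, length(idx)))
    for (k in seq_along(idx)) xb[, , , k] <- aperm(xs[[k]], c(2, 3, 1))
    p <- model_forward(model, xb, training = FALSE)
    for (k in seq_along(idx)) {
      preds[[idx[k]]] <- matrix(as.integer(p[, , 1L, k] >= threshold),
                                nrow = dim(p)[1])
    }
    i <- i + batch
  }
  preds
}

#' Build a metrics report from confusion counts
#'
#' @param counts A `museg_counts`.
#' @param per_image Optional per-image data frame to attach.
#' @return A `museg_metrics` list.
#' @export
metrics_report <- function(counts, per_image = NULL) {
  out <- list(precision = suppressWarnings(precision(counts)),
              iou = suppressWarnings(iou(counts)),
              dice = suppressWarnings(dice(counts)),
              counts = counts)
  if (!is.null(per_image)) out$per_image <- per_image
  structure(out, class = "museg_metrics")
}

#' @export
print.museg_metrics <- function(x, ...) {
  cat(sprintf("Pre %.2f%% | IoU %.2f%% | Dice %.2f%%  (tp %s fp %s fn %s tn %s)\n",
              x$precision, x$iou, x$dice,
              format(x$counts$tp, big.mark = ","), format(x$counts$fp, big.mark = ","),
              format(x$counts$fn, big.mark = ","), format(x$counts$tn, big.mark = ",")))
  invisible(x)
}

#' Audit a table of reported metrics for IoU-Dice consistency
#'
#' For each row of a transcribed results table, recomputes Dice from the
#' printed IoU via the shared-count identity and compares against the
#' printed Dice at the precision it was printed with (half a unit in the
#' last printed decimal).
#'
#' @param path CSV with columns `table`, `model`, `pre`, `iou`, `dice`
#'   (dice kept as printed, including trailing precision). Defaults to the
#'   transcription bundled with the package.
#' @return Data frame with computed Dice, printed Dice, tolerance and a
#'   `pass` flag per row.
#' @export
audit_reported_tables <- function(path = system.file("extdata", "reported_metrics.csv",
                                                     package = "museg")) {
  tab <- utils::read.csv(path, colClasses = c(dice = "character"))
  printed <- as.numeric(tab$dice)
  decs <- vapply(strsplit(tab$dice, ".", fixed = TRUE), function(p) {
    if (length(p) > 1) nchar(p[2]) else 0L
  }, integer(1))
  tol <- 0.5 * 10^(-decs)
  computed <- dice_from_iou(tab$iou)
  data.frame(table = tab$table, model = tab$model, iou = tab$iou,
             dice_printed = printed, dice_computed = computed,
             tolerance = tol, pass = abs(computed - printed) <= tol + 1e-9)
}
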
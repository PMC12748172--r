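# Pixel-level segmentation metrics: F1, accuracy, sensitivity, specificity,
# derived from TP/TN/FP/FN pixel tallies.

#' Binarize a probability map
#'
#' Pixel is vessel (1) iff its probability is greater than or equal to the
#' threshold.
#'
#' @param prob_map (H, W) matrix with entries in [0, 1].
#' @param threshold scalar threshold in [0, 1]; default 0.5.
#' @return integer (H, W) matrix in {0, 1}.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  stopifnot(is.matrix(prob_map))
  if (any(!is.finite(prob_map)) || min(prob_map) < 0 || max(prob_map) > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  out <- matrix(0L, nrow(prob_map), ncol(prob_map))
  out[prob_map >= threshold] <- 1L
  out
}

.check_mask <- function(m, what) {
  if (!is.matrix(m) || !all(m %in% c(0, 1))) {
    stop(what, " must be a binary (H, W) matrix", call. = FALSE)
  }
}

#' Confusion counts between predicted and ground-truth masks
#'
#' @param pred,gt binary (H, W) matrices of identical shape; 1 = vessel.
#' @return object of class `confusion_counts` with integer fields
#'   `tp`, `tn`, `fp`, `fn` summing to the pixel count.
#' @export
confusion <- function(pred, gt) {
  .check_mask(pred, "pred"); .check_mask(gt, "gt")
  if (!all(dim(pred) == dim(gt))) {
    stop("pred and gt have different shapes", call. = FALSE)
  }
  tp <- sum(pred == 1 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Combine confusion counts (micro-average pooling)
#' @param ... `confusion_counts` objects, or a single list of them.
#' @export
pool_confusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && !inherits(cs[[1L]], "confusion_counts")) {
    cs <- cs[[1L]]
  }
  out <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  for (cc in cs) for (f in names(out)) out[[f]] <- out[[f]] + cc[[f]]
  structure(out, class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' F1 = 2TP / (2TP + FP + FN); Acc = (TP + TN) / total; Se = TP / (TP + FN);
#' Sp = TN / (TN + FP). A zero denominator yields NA with the corresponding
#' name recorded in the `undefined` attribute (never a silent 0).
#'
#' @param c a `confusion_counts` object (or list with tp/tn/fp/fn).
#' @return object of class `metrics_report`: list(f1, acc, se, sp).
#' @export
compute_metrics <- function(c) {
  stopifnot(all(c(c$tp, c$tn, c$fp, c$fn) >= 0))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(f1 = safe(2 * c$tp, 2 * c$tp + c$fp + c$fn),
              acc = (c$tp + c$tn) / total,
              se = safe(c$tp, c$tp + c$fn),
              sp = safe(c$tn, c$tn + c$fp))
  undef <- names(out)[vapply(out, is.na, logical(1))]
  structure(out, undefined = undef, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("F1 %.4f | Acc %.4f | Se %.4f | Sp %.4f\n",
              x$f1, x$acc, x$se, x$sp))
  if (length(attr(x, "undefined"))) {
    cat("undefined:", paste(attr(x, "undefined"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a metrics report to JSON and CSV
#' @param report a `metrics_report`.
#' @param stem output path without extension; writes `<stem>.json` and
#'   `<stem>.csv`.
#' @export
write_metrics <- function(report, stem) {
  lst <- lapply(unclass(report), function(v) if (is.na(v)) NULL else v)
  jsonlite::write_json(lst, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  utils::write.csv(
    data.frame(metric = names(unclass(report)),
               value = unlist(unclass(report), use.names = FALSE)),
    paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}
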
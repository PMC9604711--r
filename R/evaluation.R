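#' Pixelwise confusion counts
#'
#' Tallies true/false positives and negatives of a predicted mask against a
#' ground-truth mask, optionally restricted to a field-of-view mask (when
#' `fov` is supplied only pixels where it is `TRUE` are counted; by default
#' every pixel counts, and reports should state which convention was used).
#'
#' @param pred,truth [BinaryMask-class] objects (or logical matrices) of
#'   one common shape.
#' @param fov optional [BinaryMask-class] of the same shape.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth, fov = NULL) {
  p <- .asMaskMatrix(pred); tr <- .asMaskMatrix(truth)
  if (!identical(dim(p), dim(tr)))
    stop(sprintf("shape mismatch: pred is %s, truth is %s",
                 paste(dim(p), collapse = " x "),
                 paste(dim(tr), collapse = " x ")))
  if (!is.null(fov)) {
    f <- .asMaskMatrix(fov)
    if (!identical(dim(f), dim(p)))
      stop(sprintf("shape mismatch: fov is %s, pred is %s",
                   paste(dim(f), collapse = " x "),
                   paste(dim(p), collapse = " x ")))
    p <- p[f]; tr <- tr[f]
  }
  ConfusionCounts(tp = sum(p & tr), fp = sum(p & !tr),
                  tn = sum(!p & !tr), fn = sum(!p & tr))
}

#' Sensitivity, specificity and accuracy in percent
#'
#' The TP rate (sensitivity), TN rate (specificity) and accuracy
#' conventional in the vessel-segmentation literature, on the 0-100 percent
#' scale. A rate whose denominator is zero (no positive, or no negative,
#' truth pixels) is reported as `NA` rather than 0.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named list with `tpRate`, `tnRate`, `accuracy` (percent).
#' @examples
#' segMetrics(ConfusionCounts(tp = 1, fp = 1, tn = 2, fn = 0))
#' @export
segMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  total <- tp + fp + tn + fn
  if (total == 0L) stop("no evaluated pixels: all counts are zero")
  list(
    tpRate = if (tp + fn > 0L) 100 * tp / (tp + fn) else NA_real_,
    tnRate = if (tn + fp > 0L) 100 * tn / (tn + fp) else NA_real_,
    accuracy = 100 * (tp + tn) / total
  )
}

#' Per-image metrics table
#'
#' Convenience wrapper producing one data.frame row per prediction/truth
#' pair plus an aggregate row (counts pooled over all images), in the
#' layout used for CSV reports: image_id, tp, fp, tn, fn, tp_rate,
#' tn_rate, accuracy.
#'
#' @param preds,truths lists of masks (or single masks) of matching length.
#' @param fovs optional list of field-of-view masks (or `NULL`).
#' @param ids character image identifiers.
#' @return a data.frame.
#' @export
metricsTable <- function(preds, truths, fovs = NULL, ids = NULL) {
  if (is(preds, "BinaryMask") || is.matrix(preds)) preds <- list(preds)
  if (is(truths, "BinaryMask") || is.matrix(truths)) truths <- list(truths)
  stopifnot(length(preds) == length(truths))
  if (is.null(ids)) ids <- sprintf("image_%02d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    cc <- confusionCounts(preds[[i]], truths[[i]],
                          if (is.null(fovs)) NULL else fovs[[i]])
    m <- segMetrics(cc)
    data.frame(image_id = ids[i], tp = cc@tp, fp = cc@fp, tn = cc@tn,
               fn = cc@fn, tp_rate = m$tpRate, tn_rate = m$tnRate,
               accuracy = m$accuracy, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  agg <- ConfusionCounts(sum(tab$tp), sum(tab$fp), sum(tab$tn), sum(tab$fn))
  am <- segMetrics(agg)
  rbind(tab, data.frame(image_id = "aggregate", tp = agg@tp, fp = agg@fp,
                        tn = agg@tn, fn = agg@fn, tp_rate = am$tpRate,
                        tn_rate = am$tnRate, accuracy = am$accuracy,
                        stringsAsFactors = FALSE))
}
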
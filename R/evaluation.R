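#' Epsilon-guarded Pearson correlation
#'
#' Pearson's r between predictions and targets over unmasked positions, with
#' a small epsilon added to the denominator so constant inputs yield 0
#' instead of a division by zero:
#' \deqn{r = \frac{\sum_i (x_i-\bar x)(y_i-\bar y)}
#'   {\sqrt{\sum_i (x_i-\bar x)^2 \sum_i (y_i-\bar y)^2} + \epsilon}}
#'
#' @param x,y Numeric vectors of equal length.
#' @param mask Optional logical vector; `TRUE` positions enter the
#'   computation (padded or flagged positions are excluded this way).
#' @param eps Denominator guard, default `1e-8`.
#' @return Correlation in `[-1, 1]` (infinitesimally shrunk by the guard).
#' @export
pearson_r <- function(x, y, mask = NULL, eps = 1e-8) {
  stopifnot(length(x) == length(y))
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(x))
    x <- x[mask]; y <- y[mask]
  }
  if (length(x) < 2L) stop("need at least 2 unmasked positions")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / (sqrt(sum(dx * dx) * sum(dy * dy)) + eps)
}

#' Base-wise confusion counts between predicted and experimental peaks
#'
#' Positions are compared one by one: a base inside both masks is a true
#' positive, inside only the prediction a false positive, inside only the
#' experiment a false negative. Positions where `valid_mask` is `FALSE`
#' (e.g. on flagged sequences) are excluded entirely.
#'
#' @param pred_mask,exp_mask Logical per-base peak indicators.
#' @param valid_mask Optional logical; `FALSE` positions are dropped.
#' @return List with integer counts `tp`, `fp`, `fn`.
#' @export
base_confusion <- function(pred_mask, exp_mask, valid_mask = NULL) {
  stopifnot(length(pred_mask) == length(exp_mask))
  if (!is.null(valid_mask)) {
    stopifnot(length(valid_mask) == length(pred_mask))
    pred_mask <- pred_mask[valid_mask]
    exp_mask <- exp_mask[valid_mask]
  }
  list(tp = sum(pred_mask & exp_mask),
       fp = sum(pred_mask & !exp_mask),
       fn = sum(!pred_mask & exp_mask))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2*precision*recall/(precision+recall)`; whenever a denominator is
#' zero the corresponding value is defined as 0 (so F1 is 0 when TP is 0,
#' never NaN).
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List with `precision`, `recall`, `f1`.
#' @export
prf1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Default peak-calling cutoff grids
#'
#' The grids used when sweeping the peak-calling threshold for
#' precision-recall curves: a fine ATAC grid (1..25 step 1), a wide ATAC
#' grid (1, then 5..200 step 5) and the ChIP grid (1, then 5..100 step 5).
#'
#' @param kind One of `"atac_fine"`, `"atac_wide"`, `"chip"`.
#' @return Sorted numeric vector of cutoffs.
#' @export
default_cutoffs <- function(kind = c("atac_fine", "atac_wide", "chip")) {
  kind <- match.arg(kind)
  switch(kind,
         atac_fine = as.numeric(1:25),
         atac_wide = c(1, seq(5, 200, by = 5)),
         chip = c(1, seq(5, 100, by = 5)))
}

#' Precision-recall curve over a peak-calling cutoff sweep
#'
#' For each cutoff, peaks are called on the track with [call_peaks()], the
#' base-wise confusion against the experimental peak mask is computed and
#' one (recall, precision) point is recorded. The area under the curve is
#' the trapezoidal integral over recall-sorted points.
#'
#' @param values Numeric per-base track (e.g. strand-averaged predicted
#'   rates, optionally smoothed).
#' @param exp_mask Logical experimental peak indicator, same length.
#' @param cutoffs Non-empty, sorted numeric vector of cutoffs.
#' @param min_length,max_gap Peak-calling parameters (see [call_peaks()]).
#' @param valid_mask Optional logical; `FALSE` positions excluded.
#' @return List with `prc` (data frame `cutoff`, `recall`, `precision`),
#'   `auprc` and `baseline` (fraction of positive bases).
#' @export
pr_curve <- function(values, exp_mask, cutoffs, min_length = 1L,
                     max_gap = 0L, valid_mask = NULL) {
  stopifnot(length(cutoffs) > 0L, !is.unsorted(cutoffs),
            length(values) == length(exp_mask))
  pts <- lapply(cutoffs, function(ct) {
    pk <- call_peaks(values, ct, min_length = min_length, max_gap = max_gap)
    pm <- peaks_to_mask(pk, length(values))
    cf <- base_confusion(pm, exp_mask, valid_mask)
    pr <- prf1(cf$tp, cf$fp, cf$fn)
    c(recall = pr$recall, precision = pr$precision)
  })
  pts <- do.call(rbind, pts)
  prc <- data.frame(cutoff = cutoffs, recall = pts[, "recall"],
                    precision = pts[, "precision"])
  list(prc = prc,
       auprc = auprc_trapezoid(prc$recall, prc$precision),
       baseline = baseline_auprc(exp_mask, valid_mask))
}

#' Trapezoidal area under a precision-recall curve
#'
#' @param recall,precision Numeric vectors of PR points (any order; sorted
#'   by recall internally).
#' @return Area in `[0, 1]`.
#' @export
auprc_trapezoid <- function(recall, precision) {
  stopifnot(length(recall) == length(precision))
  o <- order(recall, precision)
  r <- recall[o]; p <- precision[o]
  if (length(r) < 2L) return(0)
  sum(diff(r) * (head(p, -1L) + tail(p, -1L)) / 2)
}

#' Baseline AUPRC: the fraction of positive bases
#'
#' An uninformative predictor attains an AUPRC equal to the fraction of
#' positives (peak bases among valid bases); model AUPRC is compared
#' against this.
#'
#' @param exp_mask Logical peak indicator.
#' @param valid_mask Optional logical; `FALSE` positions excluded.
#' @return Fraction in `[0, 1]`.
#' @export
baseline_auprc <- function(exp_mask, valid_mask = NULL) {
  if (!is.null(valid_mask)) {
    stopifnot(length(valid_mask) == length(exp_mask))
    exp_mask <- exp_mask[valid_mask]
  }
  if (length(exp_mask) == 0L) stop("no valid positions")
  mean(exp_mask)
}

#' Meta-profile: mean coverage around anchor positions
#'
#' Average coverage as a function of offset from a set of anchors (typically
#' transcription start sites), over a window of `±window` bp. Minus-strand
#' anchors are read right-to-left so "downstream" always points away from
#' the anchor in transcription direction. Offsets falling outside the
#' sequence are clipped (that anchor simply does not contribute there).
#'
#' @param values Numeric per-base track.
#' @param anchors Integer vector of 0-based anchor positions.
#' @param strands Optional character vector (`"+"`/`"-"`) per anchor;
#'   default all plus.
#' @param window Half-window in bp (default 3000).
#' @return A `meta_profile` object: list with `offsets` (-window..window),
#'   `mean_coverage` and `n_anchors`.
#' @export
meta_profile <- function(values, anchors, strands = NULL, window = 3000L) {
  if (length(anchors) == 0L) stop("need at least one anchor")
  window <- as.integer(window)
  if (is.null(strands)) strands <- rep("+", length(anchors))
  stopifnot(length(strands) == length(anchors))
  n <- length(values)
  offs <- seq.int(-window, window)
  acc <- numeric(length(offs))
  cnt <- numeric(length(offs))
  for (i in seq_along(anchors)) {
    pos <- if (strands[i] == "-") anchors[i] - offs else anchors[i] + offs
    ok <- pos >= 0L & pos < n
    acc[ok] <- acc[ok] + values[pos[ok] + 1L]
    cnt[ok] <- cnt[ok] + 1
  }
  mean_cov <- ifelse(cnt > 0, acc / cnt, NA_real_)
  structure(list(offsets = offs, mean_coverage = mean_cov,
                 n_anchors = length(anchors)),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> %d anchors, offsets %d..%d, peak %.3f\n",
              x$n_anchors, min(x$offsets), max(x$offsets),
              max(x$mean_coverage, na.rm = TRUE)))
  invisible(x)
}

#' Enrichment quality control on a meta-profile
#'
#' A dataset passes QC when the average peak coverage around the anchors is
#' at least `min_ratio` (default 2.5) times the background. Background is
#' estimated as the median over the two outermost quarters of the window
#' (the flanks, far from the anchor); this definition is configurable via
#' `flank_fraction`.
#'
#' @param profile A `meta_profile`.
#' @param min_ratio Pass threshold on peak/background (default 2.5).
#' @param flank_fraction Fraction of the window, on each side, used as
#'   background (default 0.25).
#' @return List with `ratio` (Inf when the background is zero), `background`,
#'   `peak` and logical `pass`.
#' @export
qc_enrichment <- function(profile, min_ratio = 2.5, flank_fraction = 0.25) {
  stopifnot(inherits(profile, "meta_profile"))
  v <- profile$mean_coverage
  m <- length(v)
  if (m == 0L) stop("empty profile")
  k <- max(1L, floor(m * flank_fraction))
  background <- median(c(head(v, k), tail(v, k)), na.rm = TRUE)
  peak <- max(v, na.rm = TRUE)
  ratio <- if (background == 0) Inf else peak / background
  list(ratio = ratio, background = background, peak = peak,
       pass = ratio >= min_ratio)
}
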
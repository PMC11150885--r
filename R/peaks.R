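#' Rolling-mean smoothing of a per-base track
#'
#' Centred moving average used as a post-processing step on predicted
#' coverage. Near the edges the mean is taken over the available, truncated
#' window, so output length equals input length and no NA is produced.
#' Typical window sizes are 50/100/250 bp for ATAC-like signal and
#' 250/500/750 bp for the broader H3K4me3 signal.
#'
#' @param values Numeric per-base track.
#' @param window Window size in bp (`1` is the identity).
#' @return Numeric vector of the same length.
#' @export
rolling_mean <- function(values, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  n <- length(values)
  if (window == 1L || n == 0L) return(as.numeric(values))
  lo <- (window - 1L) %/% 2L
  hi <- window - 1L - lo
  cs <- c(0, cumsum(as.numeric(values)))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

#' Threshold peak calling with minimum length and maximum gap
#'
#' bedGraph-level peak calling: (1) find maximal runs of positions with
#' value `>= cutoff` (ties at the cutoff are included); (2) merge runs
#' separated by at most `max_gap` below-cutoff positions; (3) discard merged
#' regions shorter than `min_length`. The merge step runs before the length
#' filter, so short runs can survive by joining neighbours. Peak score is
#' the maximum track value inside the peak.
#'
#' @param values Numeric per-base track (finite).
#' @param cutoff Minimum value for a position to seed a peak.
#' @param min_length Minimum peak length in bp (>= 1).
#' @param max_gap Maximum below-cutoff gap, in bp, bridged when merging
#'   (>= 0).
#' @param seq_id Sequence identifier attached to the peaks.
#' @return Data frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open, sorted, non-overlapping) and `score`.
#' @export
call_peaks <- function(values, cutoff, min_length = 1L, max_gap = 0L,
                       seq_id = "seq") {
  stopifnot(all(is.finite(values)), min_length >= 1L, max_gap >= 0L)
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  n <- length(values)
  if (n == 0L) return(empty)
  above <- values >= cutoff
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths       # 0-based starts
  run_s <- starts[r$values]
  run_e <- ends[r$values]
  if (length(run_s) == 0L) return(empty)
  # merge runs whose separating gap is <= max_gap
  ms <- run_s[1L]; me <- run_e[1L]
  out_s <- integer(); out_e <- integer()
  if (length(run_s) > 1L) {
    for (i in 2L:length(run_s)) {
      if (run_s[i] - me <= max_gap) {
        me <- run_e[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- run_s[i]; me <- run_e[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  keep <- (out_e - out_s) >= min_length
  out_s <- out_s[keep]; out_e <- out_e[keep]
  if (length(out_s) == 0L) return(empty)
  score <- vapply(seq_along(out_s),
                  function(i) max(values[(out_s[i] + 1L):out_e[i]]),
                  numeric(1L))
  data.frame(seq_id = seq_id, start = out_s, end = out_e, score = score,
             stringsAsFactors = FALSE)
}

#' Convert disjoint peaks to a per-base logical mask
#'
#' Base-wise evaluation denotes called peaks with 1 and everything else
#' with 0; this builds that indicator.
#'
#' @param peaks Data frame with 0-based half-open `start`, `end` columns
#'   (disjoint, within bounds).
#' @param seq_length Sequence length in bp.
#' @return Logical vector of length `seq_length`, `TRUE` inside peaks.
#' @export
peaks_to_mask <- function(peaks, seq_length) {
  mask <- logical(seq_length)
  if (nrow(peaks) == 0L) return(mask)
  stopifnot(all(peaks$start >= 0), all(peaks$end <= seq_length),
            all(peaks$start < peaks$end))
  o <- order(peaks$start)
  s <- peaks$start[o]; e <- peaks$end[o]
  if (any(s[-1L] < e[-length(e)])) stop("overlapping peaks")
  for (i in seq_along(s)) mask[(s[i] + 1L):e[i]] <- TRUE
  mask
}

#' Recover disjoint peak intervals from a logical mask
#'
#' Inverse of [peaks_to_mask()] (scores are not recoverable and set to NA).
#'
#' @param mask Logical per-base vector.
#' @param seq_id Sequence identifier.
#' @return Data frame with `seq_id`, `start`, `end`, `score` columns.
#' @export
mask_to_peaks <- function(mask, seq_id = "seq") {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(seq_id = seq_id, start = starts[r$values], end = ends[r$values],
             score = NA_real_, stringsAsFactors = FALSE)
}
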
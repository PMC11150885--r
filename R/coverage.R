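#' Sentinel used for padded positions in per-chunk coverage targets
#'
#' Padded positions carry no experimental signal; they are stored with this
#' sentinel and excluded from every loss and metric through masks.
#'
#' @format Numeric scalar.
#' @export
PAD_SENTINEL <- -1

#' Construct a per-base coverage track
#'
#' @param values Numeric vector of non-negative, finite per-base read
#'   coverage (reads per bp), one entry per base of the sequence.
#' @param seq_id Sequence identifier the track belongs to.
#' @param kind Dataset kind, `"atac"` or `"chip"` (H3K4me3).
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(values, seq_id, kind = c("atac", "chip")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("coverage values must be finite and non-negative")
  }
  structure(list(seq_id = seq_id, kind = kind, values = values),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s [%s] length=%d mean=%.3f\n",
              x$seq_id, x$kind, length(x$values), mean(x$values)))
  invisible(x)
}

#' Shift ATAC-seq read intervals to the Tn5 binding-site centre
#'
#' Tn5 inserts adapters 9 bp apart; moving plus-strand reads +4 bp and
#' minus-strand reads -5 bp centres the read start on the transposase
#' binding site. The whole interval is moved so downstream pileup stays
#' consistent. The shift is truncated where it would push the interval
#' outside `[0, seq_length)`, preserving read length.
#'
#' @param reads Data frame with columns `start`, `end` (0-based half-open)
#'   and `strand` (`"+"`/`"-"`); other columns are passed through.
#' @param seq_length Optional sequence length used to truncate plus-strand
#'   shifts at the right edge.
#' @return The data frame with shifted `start`/`end`.
#' @export
shift_atac <- function(reads, seq_length = NULL) {
  stopifnot(all(c("start", "end", "strand") %in% names(reads)))
  if (nrow(reads) == 0L) return(reads)
  stopifnot(all(reads$start < reads$end), all(reads$start >= 0))
  shift <- ifelse(reads$strand == "+", 4L, -5L)
  # truncate so the read stays in bounds, keeping its length
  shift <- pmax(shift, -reads$start)
  if (!is.null(seq_length)) shift <- pmin(shift, seq_length - reads$end)
  reads$start <- reads$start + shift
  reads$end <- reads$end + shift
  reads
}

#' Per-base pileup of read intervals
#'
#' `values[i]` counts the reads whose interval covers base `i` (0-based).
#' Intervals are clipped to `[0, seq_length)`. Coverage is computed from
#' whole read bodies, not cut sites, matching tracks reported as reads/bp.
#'
#' @param reads Data frame with 0-based half-open `start`, `end` columns, all
#'   on one sequence.
#' @param seq_length Length of the sequence in bp.
#' @param seq_id Sequence identifier for the resulting track.
#' @param kind Dataset kind (see [coverage_track()]).
#' @return A `coverage_track` of length `seq_length`.
#' @export
pileup <- function(reads, seq_length, seq_id = "seq", kind = "atac") {
  seq_length <- as.integer(seq_length)
  if (is.na(seq_length) || seq_length <= 0L) {
    stop("seq_length must be a positive integer")
  }
  delta <- numeric(seq_length + 1L)
  if (nrow(reads) > 0L) {
    s <- pmax(reads$start, 0L)
    e <- pmin(reads$end, seq_length)
    keep <- s < e
    s <- s[keep]; e <- e[keep]
    for (i in seq_along(s)) {
      delta[s[i] + 1L] <- delta[s[i] + 1L] + 1
      delta[e[i] + 1L] <- delta[e[i] + 1L] - 1
    }
  }
  coverage_track(cumsum(delta[seq_len(seq_length)]), seq_id, kind)
}

#' Average replicate coverage tracks into one track
#'
#' Experimental samples of one dataset kind are averaged element-wise into a
#' single target track per species and dataset; values stay floating point
#' (no rounding, no depth normalisation).
#'
#' @param tracks List of `coverage_track` objects with identical `seq_id`,
#'   `kind` and length.
#' @return A single averaged `coverage_track`.
#' @export
average_samples <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  ref <- tracks[[1L]]
  for (tr in tracks) {
    if (!inherits(tr, "coverage_track")) stop("expected coverage_track objects")
    if (tr$seq_id != ref$seq_id || tr$kind != ref$kind ||
        length(tr$values) != length(ref$values)) {
      stop("tracks must share seq_id, kind and length to be averaged")
    }
  }
  vals <- Reduce(`+`, lapply(tracks, `[[`, "values")) / length(tracks)
  coverage_track(vals, ref$seq_id, ref$kind)
}

#' Align a coverage track to encoded chunks
#'
#' Coverage is unstranded (the libraries are PCR-amplified), so the same
#' per-base values serve both strands: a plus-strand chunk receives
#' `values[start:end]`, a minus-strand chunk the same values reversed so
#' they run with the chunk's matrix rows. Padded positions receive
#' [PAD_SENTINEL] and are excluded from losses and metrics via masks.
#'
#' @param track A `coverage_track` (or bare numeric vector).
#' @param chunks List of `encoded_chunk` objects on `track$seq_id`.
#' @param sentinel Fill value for padded positions.
#' @return List of numeric vectors, one per chunk, each of the chunk length.
#' @export
track_to_chunks <- function(track, chunks, sentinel = PAD_SENTINEL) {
  values <- if (inherits(track, "coverage_track")) track$values else track
  sid <- if (inherits(track, "coverage_track")) track$seq_id else NULL
  lapply(chunks, function(ch) {
    if (!is.null(sid) && ch$seq_id != sid) {
      stop("chunk seq_id '", ch$seq_id, "' does not match track '", sid, "'")
    }
    if (ch$end > length(values)) {
      stop("track shorter than chunk extent on ", ch$seq_id)
    }
    v <- values[(ch$start + 1L):ch$end]
    if (ch$strand == "-") v <- rev(v)
    L <- nrow(ch$matrix)
    c(v, rep(sentinel, L - length(v)))
  })
}

#' Read mapped primary alignments from a BAM file
#'
#' Upstream preprocessing (trimming, mapping, duplicate removal) is assumed
#' done; flags are still asserted defensively: unmapped, secondary and
#' supplementary records are dropped.
#'
#' @param path Path to a coordinate-sorted, indexed BAM file.
#' @return Data frame with `seq_id`, `start`, `end` (0-based half-open,
#'   reference space) and `strand`, one row per read.
#' @export
read_alignments <- function(path) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag)
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  data.frame(
    seq_id = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    stringsAsFactors = FALSE
  )
}

#' Read a per-base coverage track from a bedGraph file
#'
#' @param path Path to a bedGraph file.
#' @param seq_id Sequence to extract.
#' @param seq_length Length of that sequence in bp (positions not covered by
#'   any interval are 0).
#' @param kind Dataset kind (see [coverage_track()]).
#' @return A `coverage_track`.
#' @export
read_bedgraph_track <- function(path, seq_id, seq_length, kind = "atac") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == seq_id]
  values <- numeric(seq_length)
  if (length(gr) > 0L) {
    s <- GenomicRanges::start(gr)     # 1-based after import
    e <- GenomicRanges::end(gr)
    v <- gr$score
    for (i in seq_along(s)) {
      values[s[i]:min(e[i], seq_length)] <- v[i]
    }
  }
  coverage_track(values, seq_id, kind)
}
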
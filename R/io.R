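# Writers/readers for the public track formats, thin wrappers over
# rtracklayer. Internal coordinates are 0-based half-open; emitted
# bedGraph/BED/bigWig follow their own standards via GRanges conversion.

tracks_to_granges <- function(tracks, keep_zero = TRUE) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  sid_all <- character(); s_all <- integer(); e_all <- integer()
  v_all <- numeric()
  for (tr in tracks) {
    values <- tr$values
    if (length(values) == 0L) next
    r <- rle(values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- if (keep_zero) rep(TRUE, length(r$values)) else r$values != 0
    sid_all <- c(sid_all, rep(tr$seq_id, sum(keep)))
    s_all <- c(s_all, starts[keep])
    e_all <- c(e_all, ends[keep])
    v_all <- c(v_all, r$values[keep])
  }
  if (length(s_all) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = sid_all,
    ranges = IRanges::IRanges(start = s_all + 1L, end = e_all),
    score = v_all)
}

#' Write per-base coverage as bedGraph
#'
#' Runs of equal values are merged into single 0-based half-open intervals
#' (zero runs included, so the round trip through [read_bedgraph_track()] is
#' lossless). An empty track yields a header-only file.
#'
#' @param tracks A `coverage_track` or a list of them (one per sequence).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  gr <- tracks_to_granges(tracks)
  if (length(gr) == 0L) {
    writeLines("track type=bedGraph", path)
    return(invisible(path))
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write per-base coverage as bigWig
#'
#' @param tracks A `coverage_track` or a list of them.
#' @param chrom_sizes Named integer vector of sequence lengths; every track
#'   sequence must be covered.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bigwig <- function(tracks, chrom_sizes, path) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  sids <- vapply(tracks, `[[`, character(1L), "seq_id")
  missing <- setdiff(sids, names(chrom_sizes))
  if (length(missing) > 0L) {
    stop("no chrom size for sequence(s): ", paste(missing, collapse = ", "))
  }
  gr <- tracks_to_granges(tracks)
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(as.integer(chrom_sizes))
  rtracklayer::export(gr, path, format = "BigWig")
  invisible(path)
}

#' Read a per-base track from a bigWig file
#'
#' @param path Path to a bigWig file.
#' @param seq_id Sequence to extract.
#' @param seq_length Sequence length in bp.
#' @param kind Dataset kind.
#' @return A `coverage_track`.
#' @export
read_bigwig_track <- function(path, seq_id, seq_length, kind = "atac") {
  gr <- rtracklayer::import(path, format = "BigWig")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == seq_id]
  values <- numeric(seq_length)
  if (length(gr) > 0L) {
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    v <- gr$score
    for (i in seq_along(s)) values[s[i]:min(e[i], seq_length)] <- v[i]
  }
  coverage_track(values, seq_id, kind)
}

#' Write intervals (peaks, motif sites, anchors) as BED
#'
#' @param intervals Data frame with `seq_id`, `start`, `end` (0-based
#'   half-open) and optional `strand`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  df <- data.frame(
    chrom = if (n) intervals$seq_id else character(),
    start = if (n) intervals$start else integer(),
    end = if (n) intervals$end else integer(),
    name = rep(".", n),
    score = if (!is.null(intervals$score) && n) {
      ifelse(is.na(intervals$score), 0, intervals$score)
    } else rep(0, n),
    strand = if (!is.null(intervals$strand) && n) {
      intervals$strand
    } else rep(".", n)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return Data frame with `seq_id`, `start`, `end` (0-based half-open) and,
#'   when present, `score` and `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- ifelse(st == "*", "+", st)
  out
}
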
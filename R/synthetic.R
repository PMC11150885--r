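#' Specification for a synthetic chromatin-signal dataset
#'
#' Describes a desk-scale genome with known ground truth: uniform random
#' background sequence with a fixed motif planted at random sites, a narrow
#' ATAC-like coverage peak centred on each site and a broader H3K4me3-like
#' peak shifted downstream of it (downstream in the site's strand
#' direction), mirroring the canonical promoter geometry of accessible
#' chromatin at the transcription start flanked by H3K4me3 over the gene
#' body start. Observed coverage is Poisson-sampled per base around the
#' expected rate over a low uniform background.
#'
#' Defaults are sized for CPU work: 64 sequences of 8192 bp, to be chunked
#' at 1024 bp (the production default of 21384 bp stays available through
#' [model_config()]). Two sites per sequence with a 400 bp accessible peak
#' keep the positive (peak) fraction of bases in the mid-single-digit
#' percent range typical of real accessibility data, with the broader
#' ChIP-like mark roughly twice as abundant.
#'
#' @param n_sequences Number of sequences.
#' @param seq_length Length of each sequence in bp.
#' @param motif Planted motif (string over ACGT, default a 12-bp idealized
#'   core element; length >= 12 makes chance hits negligible).
#' @param n_sites Motif sites per sequence.
#' @param atac_peak_width Width (4 sigma support) of the accessibility bump
#'   in bp.
#' @param chip_peak_width Width of the histone-mark bump in bp.
#' @param chip_offset Downstream shift of the histone bump relative to the
#'   site, in bp.
#' @param peak_height Expected excess coverage at the bump maximum
#'   (reads/bp).
#' @param background_rate Expected background coverage (reads/bp).
#' @param seed Seed making the whole dataset reproducible.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_sequences = 64L, seq_length = 8192L,
                           motif = "TGACGTCATCGA", n_sites = 2L,
                           atac_peak_width = 400L, chip_peak_width = 1000L,
                           chip_offset = 400L, peak_height = 8,
                           background_rate = 0.5, seed = 1234L) {
  stopifnot(n_sequences >= 1L, seq_length > 0L, nchar(motif) >= 1L,
            grepl("^[ACGT]+$", motif), n_sites >= 0L,
            atac_peak_width < seq_length, chip_peak_width < seq_length,
            peak_height > background_rate, background_rate >= 0)
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length), motif = motif,
                 n_sites = as.integer(n_sites),
                 atac_peak_width = as.integer(atac_peak_width),
                 chip_peak_width = as.integer(chip_peak_width),
                 chip_offset = as.integer(chip_offset),
                 peak_height = peak_height,
                 background_rate = background_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic genome with planted motif sites
#'
#' Sequences are i.i.d. uniform over ACGT; `n_sites` copies of the motif are
#' planted per sequence at random non-overlapping positions (kept away from
#' the edges so the coverage bumps fit) on random strands (minus-strand
#' sites carry the reverse complement). Reproducible given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `genome` (named residue vector) and `sites` (data
#'   frame `seq_id`, `start`, `end` 0-based half-open, `strand`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  mlen <- nchar(spec$motif)
  margin <- max(spec$atac_peak_width,
                spec$chip_peak_width + spec$chip_offset)
  min_sep <- margin + max(spec$atac_peak_width, spec$chip_peak_width)
  lo <- margin
  hi <- spec$seq_length - margin - mlen
  if (spec$n_sites > 0L && (hi <= lo ||
      (spec$n_sites - 1L) * min_sep > (hi - lo))) {
    stop("cannot place ", spec$n_sites,
         " non-overlapping sites in a sequence of ", spec$seq_length, " bp")
  }
  genome <- character(spec$n_sequences)
  names(genome) <- sprintf("synth_%02d", seq_len(spec$n_sequences))
  sites <- NULL
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  for (i in seq_len(spec$n_sequences)) {
    chars <- sample(c("A", "C", "G", "T"), spec$seq_length, replace = TRUE)
    if (spec$n_sites > 0L) {
      pos <- integer()
      for (tries in 1:1000) {
        cand <- sort(sample(lo:hi, spec$n_sites))
        if (spec$n_sites == 1L || all(diff(cand) >= min_sep)) {
          pos <- cand
          break
        }
      }
      if (length(pos) == 0L) {
        stop("failed to place non-overlapping sites after 1000 attempts")
      }
      strands <- sample(c("+", "-"), spec$n_sites, replace = TRUE)
      for (s in seq_along(pos)) {
        m <- if (strands[s] == "+") spec$motif else rc(spec$motif)
        chars[(pos[s] + 1L):(pos[s] + mlen)] <- strsplit(m, "")[[1L]]
      }
      sites <- rbind(sites, data.frame(
        seq_id = names(genome)[i], start = pos, end = pos + mlen,
        strand = strands, stringsAsFactors = FALSE))
    }
    genome[i] <- paste(chars, collapse = "")
  }
  if (is.null(sites)) {
    sites <- data.frame(seq_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  list(genome = genome, sites = sites)
}

#' Expected-coverage bump shape
#'
#' Gaussian density truncated at two standard deviations, with
#' `sigma = width/4` (so `width` is the full support). Scaled to 1 at the
#' centre.
#'
#' @param offsets Integer offsets from the bump centre, in bp.
#' @param width Full bump width in bp.
#' @return Numeric vector in `[0, 1]`.
#' @export
peak_bump <- function(offsets, width) {
  sigma <- width / 4
  out <- exp(-offsets^2 / (2 * sigma^2))
  out[abs(offsets) > 2 * sigma] <- 0
  out
}

#' Generate synthetic ATAC- and ChIP-like coverage for planted sites
#'
#' Builds the expected per-base rate (background plus a bump per site:
#' site-centred for the accessibility track, shifted `chip_offset` bp
#' downstream — strand-aware — and broader for the histone track) and draws
#' the observed coverage as independent Poisson counts per base.
#'
#' @param genome Named residue vector (only lengths and names are used).
#' @param sites Site table from [generate_genome()].
#' @param spec The [synthetic_spec()].
#' @return List with `expected` and `observed`, each holding named lists
#'   `atac` and `chip` of per-sequence numeric vectors (observed values are
#'   [coverage_track] objects).
#' @export
generate_coverage <- function(genome, sites, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  mlen <- nchar(spec$motif)
  expected <- list(atac = list(), chip = list())
  observed <- list(atac = list(), chip = list())
  for (sid in names(genome)) {
    n <- nchar(genome[[sid]])
    base_pos <- seq_len(n) - 1L
    atac <- rep(spec$background_rate, n)
    chip <- rep(spec$background_rate, n)
    ss <- sites[sites$seq_id == sid, , drop = FALSE]
    for (j in seq_len(nrow(ss))) {
      centre <- ss$start[j] + mlen %/% 2L
      atac <- atac + spec$peak_height *
        peak_bump(base_pos - centre, spec$atac_peak_width)
      chip_centre <- if (ss$strand[j] == "+") {
        centre + spec$chip_offset
      } else {
        centre - spec$chip_offset
      }
      chip <- chip + spec$peak_height *
        peak_bump(base_pos - chip_centre, spec$chip_peak_width)
    }
    expected$atac[[sid]] <- atac
    expected$chip[[sid]] <- chip
    observed$atac[[sid]] <- coverage_track(rpois(n, atac), sid, "atac")
    observed$chip[[sid]] <- coverage_track(rpois(n, chip), sid, "chip")
  }
  list(expected = expected, observed = observed)
}

#' Ground-truth peaks of a synthetic dataset
#'
#' Truth peaks are the regions where the noiseless expected rate reaches at
#' least half the bump height above background (the full width at half
#' maximum), obtained by thresholding the expectation track.
#'
#' @param expected Named list of expected-rate vectors (one kind).
#' @param spec The [synthetic_spec()].
#' @return Data frame of peaks (`seq_id`, `start`, `end`, `score`).
#' @export
truth_peaks <- function(expected, spec) {
  cutoff <- spec$background_rate + spec$peak_height / 2
  do.call(rbind, lapply(names(expected), function(sid) {
    call_peaks(expected[[sid]], cutoff, min_length = 1L, max_gap = 0L,
               seq_id = sid)
  }))
}

#' Generate and persist a full synthetic dataset
#'
#' Emits everything downstream steps consume: the genome FASTA, observed
#' coverage as bedGraph (one file per kind), motif-site and truth-peak BED
#' files, and the HDF5 container with both-strand encoded chunks and
#' coverage targets.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @param chunk_len Chunk length for the container (default 1024 bp; the
#'   sequences must be divisible into it only via padding, which is
#'   handled).
#' @return List with file `paths`, the in-memory `genome`, `sites`,
#'   `coverage` and truth peak tables `truth` (per kind), invisibly usable
#'   by tests.
#' @export
generate_dataset <- function(spec, out_dir, chunk_len = 1024L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(spec)
  cov <- generate_coverage(gen$genome, gen$sites, spec)
  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    sites = file.path(out_dir, "sites.bed"),
    atac_bedgraph = file.path(out_dir, "atac.bedGraph"),
    chip_bedgraph = file.path(out_dir, "chip.bedGraph"),
    truth_atac = file.path(out_dir, "truth_peaks_atac.bed"),
    truth_chip = file.path(out_dir, "truth_peaks_chip.bed"),
    container = file.path(out_dir, "dataset.h5")
  )
  dss <- Biostrings::DNAStringSet(gen$genome)
  Biostrings::writeXStringSet(dss, paths$fasta)
  write_bed(gen$sites, paths$sites)
  write_bedgraph(cov$observed$atac, paths$atac_bedgraph)
  write_bedgraph(cov$observed$chip, paths$chip_bedgraph)
  truth <- list(atac = truth_peaks(cov$expected$atac, spec),
                chip = truth_peaks(cov$expected$chip, spec))
  write_bed(truth$atac, paths$truth_atac)
  write_bed(truth$chip, paths$truth_chip)
  chunks <- chunk_genome_all(gen$genome, chunk_len)
  write_container(paths$container, chunks,
                  coverage = list(atac = cov$observed$atac,
                                  chip = cov$observed$chip))
  invisible(list(paths = paths, spec = spec, genome = gen$genome,
                 sites = gen$sites, coverage = cov, truth = truth))
}
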
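# Independent reference implementations used as oracles in the tests.
# They are deliberately naive (explicit loops / direct formula evaluation)
# and never share code with the package internals they check.

# Poisson NLL by direct two-loop summation over unmasked positions.
naive_poisson_loss <- function(x, y, mask) {
  total <- 0
  n <- 0L
  for (i in seq_along(x)) {
    if (mask[i]) {
      total <- total + exp(x[i]) - y[i] * x[i]
      n <- n + 1L
    }
  }
  total / n
}

# Textbook Pearson correlation without the epsilon guard.
naive_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Per-base membership count pileup.
naive_pileup <- function(reads, seq_length) {
  v <- numeric(seq_length)
  for (i in seq_len(seq_length)) {
    pos <- i - 1L
    for (r in seq_len(nrow(reads))) {
      if (reads$start[r] <= pos && pos < reads$end[r]) v[i] <- v[i] + 1
    }
  }
  v
}

# Brute-force threshold peak caller: explicit position scan that marks
# above-cutoff bases, bridges gaps of at most max_gap, then filters by
# length. Returns a 2-column matrix of 0-based half-open intervals.
naive_call_peaks <- function(values, cutoff, min_length, max_gap) {
  n <- length(values)
  above <- values >= cutoff
  if (!any(above)) return(matrix(integer(), ncol = 2L))
  # mark bases bridged: any below-cutoff run of length <= max_gap strictly
  # between two above-cutoff bases
  merged <- above
  i <- 1L
  while (i <= n) {
    if (!above[i]) {
      j <- i
      while (j <= n && !above[j]) j <- j + 1L
      gap_len <- j - i
      if (i > 1L && j <= n && gap_len <= max_gap) {
        merged[i:(j - 1L)] <- TRUE
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (merged[i]) {
      j <- i
      while (j <= n && merged[j]) j <- j + 1L
      if ((j - i) >= min_length) out <- rbind(out, c(i - 1L, j - 1L))
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) matrix(integer(), ncol = 2L) else out
}

# Count exact matches of a motif on both strands of a residue string.
scan_motif <- function(residues, motif) {
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(motif, "")[[1L]]), collapse = ""))
  cnt <- function(pat) {
    m <- gregexpr(pat, residues, fixed = TRUE)[[1L]]
    sum(m > 0)
  }
  cnt(motif) + if (rc == motif) 0L else cnt(rc)
}

random_genome <- function(n, with_n = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else
    c("A", "C", "G", "T")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_fasta_file <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  path
}
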
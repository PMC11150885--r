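#' @useDynLib seq2cov, .registration = TRUE
#' @importFrom stats rpois runif setNames median cor sd
#' @importFrom utils head tail write.table read.table
NULL

#' Channel order of the four-dimensional nucleotide encoding
#'
#' Nucleotides are encoded as four-dimensional unit vectors in the fixed
#' channel order C, A, T, G (single source of truth for the whole package).
#' `N` encodes as the uniform vector `c(0.25, 0.25, 0.25, 0.25)`, which keeps
#' real-base rows summing to one while staying distinguishable from padding
#' rows, which are all-zero `c(0, 0, 0, 0)`.
#'
#' A convenient consequence of this order is that complementing a base is a
#' reversal of the channel axis (C<->G, A<->T), so the reverse complement of
#' an encoded matrix is `m[nrow(m):1, 4:1]`.
#'
#' @format Character vector of length 4.
#' @export
SEQ2COV_CHANNELS <- c("C", "A", "T", "G")

#' Default model input length in base pairs
#'
#' Genomes are tiled into fixed-length subsequences ("chunks") of this many
#' base pairs before encoding. The default, 21384 bp, is long enough to span
#' typical plant gene lengths and is divisible by ten of the integers from
#' 1 to 20, which makes repeated strided down- and upsampling inside the
#' network land on integer lengths.
#'
#' @format Integer scalar.
#' @export
DEFAULT_CHUNK_LEN <- 21384L

#' Encode a single residue as a four-dimensional vector
#'
#' @param residue Single character in `A`, `C`, `G`, `T`, `N` (case
#'   insensitive).
#' @return Numeric vector of length 4 in channel order [SEQ2COV_CHANNELS]:
#'   a unit vector for an unambiguous base, `rep(0.25, 4)` for `N`.
#' @examples
#' encode_base("C")
#' encode_base("N")
#' @export
encode_base <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L, nchar(residue) == 1L)
  encode_seq(residue)[1L, ]
}

#' Encode a residue string as an L x 4 matrix
#'
#' Vectorised encoder for a whole sequence. Padding positions are not bases
#' and are not produced here; they are appended as all-zero rows by
#' [chunk_genome()].
#'
#' @param residues Character scalar (residue string) or character vector of
#'   single residues.
#' @return Numeric matrix with one row per residue, 4 columns in channel
#'   order C, A, T, G.
#' @export
encode_seq <- function(residues) {
  chars <- if (length(residues) == 1L && nchar(residues) != 1L) {
    strsplit(residues, "", fixed = TRUE)[[1L]]
  } else {
    as.character(residues)
  }
  chars <- toupper(chars)
  L <- length(chars)
  m <- matrix(0, nrow = L, ncol = 4L,
              dimnames = list(NULL, SEQ2COV_CHANNELS))
  ch <- match(chars, SEQ2COV_CHANNELS)
  is_n <- chars == "N"
  bad <- is.na(ch) & !is_n
  if (any(bad)) {
    stop("cannot encode residue(s): ",
         paste(unique(chars[bad]), collapse = ", "),
         " (allowed: A, C, G, T, N)")
  }
  ok <- !is.na(ch)
  if (any(ok)) m[cbind(which(ok), ch[ok])] <- 1
  if (any(is_n)) m[is_n, ] <- 0.25
  m
}

#' Read a multi-record FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]. Residues are
#' uppercased (soft-masked lowercase is kept, not filtered), record order is
#' preserved and duplicate sequence identifiers are an error. The identifier
#' is the first whitespace-delimited word of the header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one residue string per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, n = 50L)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonempty[1L]]), ">")) {
    stop("malformed FASTA: line ", nonempty[1L],
         " of ", path, " should start with '>'")
  }
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  setNames(toupper(as.character(dss)), ids)
}

new_encoded_chunk <- function(seq_id, start, end, strand, matrix, pad_mask,
                              is_gap) {
  structure(
    list(seq_id = seq_id, start = start, end = end, strand = strand,
         matrix = matrix, pad_mask = pad_mask, is_gap = is_gap),
    class = "encoded_chunk"
  )
}

#' @export
print.encoded_chunk <- function(x, ...) {
  cat(sprintf("<encoded_chunk> %s:%d-%d (%s) L=%d real=%d%s\n",
              x$seq_id, x$start, x$end, x$strand, nrow(x$matrix),
              sum(x$pad_mask), if (x$is_gap) " [gap]" else ""))
  invisible(x)
}

#' Cut one genome sequence into fixed-length encoded chunks
#'
#' Tiles `[0, nchar(residues))` with non-overlapping windows of `chunk_len`
#' base pairs. Coordinates are 0-based half-open on the plus-strand
#' coordinate system regardless of `strand`. Only the terminal chunk may be
#' padded; padding rows are all-zero and marked `FALSE` in `pad_mask`.
#' Minus-strand chunks carry the reverse complement of the real bases (rows
#' reversed, channels complemented), with padding kept at the tail of the
#' matrix. A chunk whose real bases are all `N` is flagged `is_gap`; such
#' "gap subsequences" carry no trainable signal and are dropped by
#' [filter_chunks()].
#'
#' @param residues Residue string for one sequence.
#' @param seq_id Sequence identifier.
#' @param chunk_len Window length in bp (default [DEFAULT_CHUNK_LEN]).
#' @param strand `"+"` or `"-"`.
#' @return List of `encoded_chunk` objects in genomic order.
#' @export
chunk_genome <- function(residues, seq_id, chunk_len = DEFAULT_CHUNK_LEN,
                         strand = "+") {
  stopifnot(is.character(residues), length(residues) == 1L)
  chunk_len <- as.integer(chunk_len)
  if (is.na(chunk_len) || chunk_len <= 0L) {
    stop("chunk_len must be a positive integer")
  }
  strand <- match.arg(strand, c("+", "-"))
  n <- nchar(residues)
  if (n == 0L) stop("empty sequence: ", seq_id)
  n_chunks <- ceiling(n / chunk_len)
  lapply(seq_len(n_chunks), function(i) {
    start <- (i - 1L) * chunk_len
    end <- min(i * chunk_len, n)
    real_len <- end - start
    sub <- substr(residues, start + 1L, end)
    chars <- strsplit(sub, "", fixed = TRUE)[[1L]]
    enc <- encode_seq(chars)
    if (strand == "-") enc <- enc[real_len:1L, 4L:1L, drop = FALSE]
    pad <- chunk_len - real_len
    if (pad > 0L) enc <- rbind(enc, matrix(0, nrow = pad, ncol = 4L))
    colnames(enc) <- SEQ2COV_CHANNELS
    pad_mask <- c(rep(TRUE, real_len), rep(FALSE, pad))
    is_gap <- all(toupper(chars) == "N")
    new_encoded_chunk(seq_id, start, end, strand, enc, pad_mask, is_gap)
  })
}

#' Chunk every sequence of a genome on both strands
#'
#' Both strands are used as model input: open and closed chromatin apply to
#' both strands, so presenting each window forward and reverse-complemented
#' acts as built-in data augmentation.
#'
#' @param genome Named character vector as returned by [read_fasta()].
#' @param chunk_len Window length in bp.
#' @param strands Strands to emit (default both).
#' @return Flat list of `encoded_chunk` objects, plus strand first per
#'   sequence.
#' @export
chunk_genome_all <- function(genome, chunk_len = DEFAULT_CHUNK_LEN,
                             strands = c("+", "-")) {
  stopifnot(!is.null(names(genome)))
  out <- list()
  for (sid in names(genome)) {
    for (s in strands) {
      out <- c(out, chunk_genome(genome[[sid]], sid, chunk_len, s))
    }
  }
  out
}

#' Drop blacklisted and gap chunks
#'
#' Removes chunks whose `seq_id` is on the blacklist (flagged unplaced
#' scaffolds and organellar sequences) and, if `drop_gaps`, chunks consisting
#' entirely of `N` bases. Relative order is preserved.
#'
#' @param chunks List of `encoded_chunk` objects.
#' @param blacklist Character vector of flagged sequence identifiers (see
#'   [load_blacklist()]).
#' @param drop_gaps Drop all-`N` chunks? Default `TRUE`.
#' @return Filtered list of chunks.
#' @export
filter_chunks <- function(chunks, blacklist = character(), drop_gaps = TRUE) {
  keep <- vapply(chunks, function(ch) {
    !(ch$seq_id %in% blacklist) && !(drop_gaps && ch$is_gap)
  }, logical(1L))
  chunks[keep]
}

#' Load a blacklist of flagged sequence identifiers
#'
#' Two formats are accepted and auto-detected:
#' \itemize{
#'   \item a plain-text list, one sequence identifier per line (blank lines
#'     and `#` comments ignored);
#'   \item JSON-lines of sequence-report records (one JSON object per line).
#'     A record is flagged when its placement/role marks it as an unplaced
#'     scaffold or a non-nuclear (organellar) sequence: `role` containing
#'     "unplaced", `assignedMoleculeLocationType` in Mitochondrion /
#'     Chloroplast / Plastid / Apicoplast, or `assemblyUnit == "non-nuclear"`.
#'     The identifier is taken from the first available of `sequenceName`,
#'     `genbankAccession`, `refseqAccession`, `seq_id`, `name`.
#' }
#'
#' @param path Path to the blacklist file.
#' @return Character vector of flagged sequence identifiers (possibly empty).
#' @export
load_blacklist <- function(path) {
  if (!file.exists(path)) stop("blacklist file not found: ", path)
  lines <- readLines(path)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#")
  if (!any(keep)) return(character())
  if (any(startsWith(trimmed[keep], "{"))) {
    ids <- character()
    for (i in which(keep)) {
      rec <- tryCatch(jsonlite::fromJSON(trimmed[i]),
                      error = function(e) {
                        stop("blacklist ", path, ": cannot parse JSON on line ",
                             i, ": ", conditionMessage(e), call. = FALSE)
                      })
      if (blacklist_flagged(rec)) {
        id_field <- c("sequenceName", "genbankAccession", "refseqAccession",
                      "seq_id", "name")
        id <- NULL
        for (f in id_field) {
          if (!is.null(rec[[f]]) && nzchar(rec[[f]])) { id <- rec[[f]]; break }
        }
        if (is.null(id)) {
          stop("blacklist ", path, ": flagged record on line ", i,
               " carries no sequence identifier")
        }
        ids <- c(ids, id)
      }
    }
    unique(ids)
  } else {
    unique(trimmed[keep])
  }
}

blacklist_flagged <- function(rec) {
  role <- tolower(as.character(rec[["role"]] %||% ""))
  loc <- tolower(as.character(rec[["assignedMoleculeLocationType"]] %||% ""))
  unit <- tolower(as.character(rec[["assemblyUnit"]] %||% ""))
  grepl("unplaced", role) ||
    loc %in% c("mitochondrion", "chloroplast", "plastid", "apicoplast") ||
    unit == "non-nuclear"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct the residue string covered by a plus-strand chunk
#'
#' Inverse of the encoder for real (non-padded) rows; used to verify the
#' tiling property. Rows equal to the uniform vector decode to `N`.
#'
#' @param chunk An `encoded_chunk` (plus strand).
#' @return Character scalar of length `sum(chunk$pad_mask)`.
#' @export
decode_chunk <- function(chunk) {
  stopifnot(inherits(chunk, "encoded_chunk"), chunk$strand == "+")
  m <- chunk$matrix[chunk$pad_mask, , drop = FALSE]
  chars <- vapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    if (all(r == 0.25)) return("N")
    SEQ2COV_CHANNELS[which(r == 1)]
  }, character(1L))
  paste(chars, collapse = "")
}
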
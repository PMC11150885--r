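#' @section Container schema:
#' The dataset container is a plain HDF5 file with the following layout
#' (schema version 1):
#' \preformatted{
#' /                   root attributes:
#'   schema            "seq2cov-container"
#'   version           "1"
#'   metadata          JSON: chunk_len, chunk table (seq_id, start, end,
#'                     strand, is_gap), seq_lengths, coverage kinds,
#'                     blacklisted seq_ids
#' /encoded/matrix     n_chunks x L x 4 double  (channel order C,A,T,G)
#' /encoded/pad_mask   n_chunks x L double 0/1  (1 = real base)
#' /encoded/is_gap     n_chunks double 0/1
#' /blacklist          n_chunks double 0/1      (1 = chunk on a flagged seq)
#' /coverage/<kind>    n_chunks x L double      (PAD_SENTINEL at padding;
#'                     optional -- absent in prediction-only containers)
#' }
#' Axis order is as written above when the file is read by row-major tools.
#'
#' @name container-schema
NULL

CONTAINER_SCHEMA <- "seq2cov-container"
CONTAINER_VERSION <- "1"

#' Write chunks (and optional coverage) to an HDF5 container
#'
#' Persists encoded chunks, masks, a per-chunk blacklist flag and per-kind
#' coverage targets under the documented schema (see
#' \link{container-schema}). The round trip through [read_container()] is
#' lossless for all arrays.
#'
#' @param path Output file path.
#' @param chunks List of `encoded_chunk` objects (all the same length).
#' @param coverage Named list, one element per dataset kind (`"atac"`,
#'   `"chip"`), each a list of `coverage_track` objects covering the chunked
#'   sequences. May be empty for a prediction-only container.
#' @param blacklist Character vector of flagged sequence identifiers.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, chunks, coverage = list(),
                            blacklist = character()) {
  stopifnot(length(chunks) > 0L)
  n <- length(chunks)
  L <- nrow(chunks[[1L]]$matrix)
  for (ch in chunks) {
    if (nrow(ch$matrix) != L) stop("all chunks must have the same length")
  }
  mat <- array(0, dim = c(n, L, 4L))
  pad <- matrix(0, n, L)
  gap <- numeric(n)
  for (i in seq_len(n)) {
    mat[i, , ] <- chunks[[i]]$matrix
    pad[i, ] <- as.numeric(chunks[[i]]$pad_mask)
    gap[i] <- as.numeric(chunks[[i]]$is_gap)
  }
  sid <- vapply(chunks, `[[`, character(1L), "seq_id")
  bl_flag <- as.numeric(sid %in% blacklist)

  names_out <- c("encoded/matrix", "encoded/pad_mask", "encoded/is_gap",
                 "blacklist")
  arrays <- list(mat, pad, gap, bl_flag)

  kinds <- names(coverage)
  for (k in kinds) {
    tracks <- coverage[[k]]
    by_seq <- setNames(tracks, vapply(tracks, `[[`, character(1L), "seq_id"))
    cov <- matrix(PAD_SENTINEL, n, L)
    for (i in seq_len(n)) {
      tr <- by_seq[[sid[i]]]
      if (is.null(tr)) stop("no ", k, " track for sequence ", sid[i])
      cov[i, ] <- track_to_chunks(tr, chunks[i])[[1L]]
    }
    names_out <- c(names_out, paste0("coverage/", k))
    arrays <- c(arrays, list(cov))
  }

  meta <- list(
    chunk_len = L,
    chunk_table = list(
      seq_id = sid,
      start = vapply(chunks, `[[`, numeric(1L), "start"),
      end = vapply(chunks, `[[`, numeric(1L), "end"),
      strand = vapply(chunks, `[[`, character(1L), "strand")
    ),
    seq_lengths = as.list(tapply(
      vapply(chunks, `[[`, numeric(1L), "end"), sid, max
    )),
    kinds = as.list(kinds),
    blacklist = as.list(blacklist)
  )
  attrs <- c(schema = CONTAINER_SCHEMA, version = CONTAINER_VERSION,
             metadata = jsonlite::toJSON(meta, auto_unbox = TRUE))
  .Call(C_h5_write, path.expand(path), names_out, arrays,
        names(attrs), unname(attrs))
  invisible(path)
}

#' Read an HDF5 dataset container
#'
#' Rebuilds the encoded chunks, the per-chunk blacklist flag and any stored
#' coverage targets. A container written without coverage groups is readable
#' in prediction-only mode (`coverage` is then an empty list). A file whose
#' schema or version attribute does not match is rejected with an explicit
#' error, as is a file that is not HDF5.
#'
#' @param path Path to a container written by [write_container()].
#' @return List with elements `chunks` (list of `encoded_chunk`),
#'   `coverage` (named list of n_chunks x L matrices), `blacklist_flag`
#'   (logical per chunk), `blacklist` (flagged seq_ids) and `meta`.
#' @export
read_container <- function(path) {
  path <- path.expand(path)
  if (!file.exists(path)) stop("container not found: ", path)
  schema <- .Call(C_h5_read_attr, path, "schema")
  if (!identical(schema, CONTAINER_SCHEMA)) {
    stop("not a seq2cov container (schema attribute is '", schema, "')")
  }
  version <- .Call(C_h5_read_attr, path, "version")
  if (!identical(version, CONTAINER_VERSION)) {
    stop("container schema version mismatch: file has '", version,
         "', this package reads '", CONTAINER_VERSION, "'")
  }
  meta <- jsonlite::fromJSON(.Call(C_h5_read_attr, path, "metadata"),
                             simplifyVector = TRUE)
  mat <- .Call(C_h5_read, path, "encoded/matrix")
  pad <- .Call(C_h5_read, path, "encoded/pad_mask")
  gap <- .Call(C_h5_read, path, "encoded/is_gap")
  bl <- .Call(C_h5_read, path, "blacklist")
  tab <- meta$chunk_table
  n <- dim(mat)[1L]
  chunks <- lapply(seq_len(n), function(i) {
    m <- mat[i, , ]
    colnames(m) <- SEQ2COV_CHANNELS
    new_encoded_chunk(tab$seq_id[i], as.integer(tab$start[i]),
                      as.integer(tab$end[i]), tab$strand[i], m,
                      pad[i, ] > 0.5, gap[i] > 0.5)
  })
  coverage <- list()
  for (k in unlist(meta$kinds)) {
    dname <- paste0("coverage/", k)
    if (.Call(C_h5_exists, path, dname)) {
      coverage[[k]] <- .Call(C_h5_read, path, dname)
    }
  }
  list(chunks = chunks, coverage = coverage, blacklist_flag = bl > 0.5,
       blacklist = as.character(unlist(meta$blacklist)), meta = meta)
}
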
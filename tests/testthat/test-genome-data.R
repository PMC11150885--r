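test_that("read_fasta parses multi-record files with wrapped lines", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGT", ">b", "acgt", "NNNN"), f)
  g <- read_fasta(f)
  expect_identical(names(g), c("chr1", "b"))
  expect_identical(unname(g["chr1"]), "ACGT")
  expect_identical(unname(g["b"]), "ACGTNNNN")  # uppercased, lines joined
})

test_that("read_fasta rejects duplicate headers, empty and malformed files", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")

  writeLines(c("ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("base encoding uses the C,A,T,G channel order and sums to one", {
  expect_identical(encode_base("C"), c(C = 1, A = 0, T = 0, G = 0))
  expect_identical(encode_base("A"), c(C = 0, A = 1, T = 0, G = 0))
  expect_identical(encode_base("T"), c(C = 0, A = 0, T = 1, G = 0))
  expect_identical(encode_base("G"), c(C = 0, A = 0, T = 0, G = 1))
  expect_identical(encode_base("N"), c(C = 0.25, A = 0.25, T = 0.25,
                                       G = 0.25))
  m <- encode_seq(random_genome(500, with_n = TRUE, seed = 11))
  expect_true(all(abs(rowSums(m) - 1) < 1e-15))
  expect_error(encode_seq("ACXGT"), "X")
})

test_that("chunking tiles the sequence and pads only the terminal chunk", {
  seqres <- random_genome(50000, seed = 3)
  chunks <- chunk_genome(seqres, "chr1", 21384L)
  expect_length(chunks, 3L)
  expect_equal(chunks[[3L]]$start, 42768)
  expect_equal(chunks[[3L]]$end, 50000)
  expect_equal(sum(!chunks[[3L]]$pad_mask), 3L * 21384L - 50000L)  # 14152
  expect_true(all(chunks[[1L]]$pad_mask), all(chunks[[2L]]$pad_mask))
  # padded rows are exactly [0,0,0,0]
  padded <- chunks[[3L]]$matrix[!chunks[[3L]]$pad_mask, , drop = FALSE]
  expect_true(all(padded == 0))
})

test_that("a sequence of exactly one chunk length needs no padding", {
  chunks <- chunk_genome(random_genome(1024, seed = 4), "s", 1024L)
  expect_length(chunks, 1L)
  expect_true(all(chunks[[1L]]$pad_mask))
})

test_that("all-N chunks are flagged as gap subsequences", {
  chunks <- chunk_genome(strrep("N", 1024L), "s", 1024L)
  expect_true(chunks[[1L]]$is_gap)
  mixed <- chunk_genome(paste0(strrep("N", 1024L),
                               random_genome(100, seed = 5)), "s", 1024L)
  expect_true(mixed[[1L]]$is_gap)
  expect_false(mixed[[2L]]$is_gap)
  expect_error(chunk_genome("ACGT", "s", 0L), "positive")
})

test_that("tiling property: masked plus-strand chunks reconstruct the genome", {
  set.seed(42)
  for (rep in 1:5) {
    L <- 64L
    n <- sample.int(5L * L, 1L)
    seqres <- random_genome(n, with_n = TRUE)
    chunks <- chunk_genome(seqres, "s", L)
    rebuilt <- paste(vapply(chunks, decode_chunk, character(1L)),
                     collapse = "")
    expect_identical(rebuilt, seqres)
  }
})

test_that("strand duality: minus matrix is the reverse complement", {
  set.seed(7)
  seqres <- random_genome(256)
  plus <- chunk_genome(seqres, "s", 256L, strand = "+")[[1L]]
  minus <- chunk_genome(seqres, "s", 256L, strand = "-")[[1L]]
  # complement is a channel reversal under the C,A,T,G order
  expect_equal(unname(minus$matrix), unname(plus$matrix[256:1, 4:1]))
})

test_that("gap rule: is_gap iff all real bases encode N", {
  set.seed(8)
  for (rep in 1:10) {
    n_real <- sample.int(20L, 1L)
    res <- paste(sample(c("A", "C", "G", "T", "N"), n_real, replace = TRUE),
                 collapse = "")
    ch <- chunk_genome(res, "s", 32L)[[1L]]
    real_rows <- ch$matrix[ch$pad_mask, , drop = FALSE]
    all_n <- all(apply(real_rows, 1L, function(r) all(r == 0.25)))
    expect_identical(ch$is_gap, all_n)
  }
})

test_that("filter_chunks drops blacklisted sequences and gap chunks", {
  g <- c(keep = random_genome(200, seed = 1),
         scaf = random_genome(150, seed = 2),
         gappy = strrep("N", 130))
  chunks <- chunk_genome_all(g, 64L, strands = "+")
  expect_length(filter_chunks(chunks, blacklist = "scaf",
                              drop_gaps = FALSE),
                length(chunks) - 3L)
  expect_identical(filter_chunks(chunks, drop_gaps = FALSE), chunks)
  no_gaps <- filter_chunks(chunks)
  expect_false(any(vapply(no_gaps, `[[`, logical(1L), "is_gap")))
  # relative order is preserved
  expect_identical(vapply(no_gaps, `[[`, character(1L), "seq_id"),
                   vapply(chunks, `[[`, character(1L), "seq_id")[
                     !vapply(chunks, `[[`, logical(1L), "is_gap")])
})

test_that("blacklists load from plain lists and JSON-lines reports", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("scaf_12", "chrM", "", "# comment"), f)
  expect_setequal(load_blacklist(f), c("scaf_12", "chrM"))

  j <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"sequenceName":"chr1","role":"assembled-molecule","assignedMoleculeLocationType":"Chromosome"}',
    '{"sequenceName":"chrMT","assignedMoleculeLocationType":"Mitochondrion"}',
    '{"genbankAccession":"KZ0001.1","role":"unplaced-scaffold"}',
    '{"sequenceName":"chrC","assemblyUnit":"non-nuclear"}'
  ), j)
  expect_setequal(load_blacklist(j), c("chrMT", "KZ0001.1", "chrC"))

  empty <- tempfile()
  writeLines(character(), empty)
  expect_identical(load_blacklist(empty), character())

  bad <- tempfile(fileext = ".jsonl")
  writeLines(c('{"sequenceName":"a","role":"assembled-molecule"}',
               '{broken json'), bad)
  expect_error(load_blacklist(bad), "line 2")
})
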
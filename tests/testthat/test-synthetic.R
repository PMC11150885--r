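# A reduced spec keeps most synthetic-data tests fast; the full default
# spec is exercised by the end-to-end acceptance suite.
small_spec <- function(...) {
  synthetic_spec(n_sequences = 4L, seq_length = 8192L, ...)
}

test_that("genome generation is reproducible and plants exact motifs", {
  spec <- small_spec(seed = 101L)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1, g2)
  g3 <- generate_genome(small_spec(seed = 102L))
  expect_false(identical(g1$genome, g3$genome))
  # planted count equals the exact-match scan count (chance hits ~ 0 for a
  # 12-bp motif)
  expect_gte(nchar(spec$motif), 12L)
  total_hits <- sum(vapply(g1$genome, scan_motif, integer(1L),
                           motif = spec$motif))
  expect_equal(total_hits, nrow(g1$sites))
  expect_equal(nrow(g1$sites), spec$n_sequences * spec$n_sites)
  # sites fall within bounds with the motif fully inside
  expect_true(all(g1$sites$end <= spec$seq_length))
  expect_true(all(g1$sites$end - g1$sites$start == nchar(spec$motif)))
})

test_that("a zero-site spec contains no motif", {
  spec <- small_spec(n_sites = 0L, seed = 103L)
  g <- generate_genome(spec)
  expect_equal(nrow(g$sites), 0L)
  expect_equal(sum(vapply(g$genome, scan_motif, integer(1L),
                          motif = spec$motif)), 0L)
})

test_that("impossible site placements error out", {
  expect_error(generate_genome(synthetic_spec(
    n_sequences = 1L, seq_length = 4096L, n_sites = 40L, seed = 104L)),
    "cannot place")
})

test_that("flat coverage matches the background rate within Poisson noise", {
  spec <- small_spec(n_sites = 0L, background_rate = 2, seed = 105L)
  g <- generate_genome(spec)
  cov <- generate_coverage(g$genome, g$sites, spec)
  v <- unlist(lapply(cov$observed$atac, `[[`, "values"))
  n <- length(v)
  # mean within 3 sigma of the Poisson expectation
  expect_lt(abs(mean(v) - 2), 3 * sqrt(2 / n))
  # index of dispersion ~ 1 on flat regions (chi-square, 1% level)
  disp <- (n - 1) * var(v) / mean(v)
  expect_gt(disp, qchisq(0.005, n - 1))
  expect_lt(disp, qchisq(0.995, n - 1))
})

test_that("meta-profile over sites recovers the planted bump shape", {
  spec <- synthetic_spec(n_sequences = 16L, seed = 106L)
  g <- generate_genome(spec)
  cov <- generate_coverage(g$genome, g$sites, spec)
  w <- 600L
  centre_of <- function(s) s$start + nchar(spec$motif) %/% 2L
  profs <- lapply(names(g$genome), function(sid) {
    ss <- g$sites[g$sites$seq_id == sid, ]
    meta_profile(cov$observed$atac[[sid]]$values, centre_of(ss),
                 strands = ss$strand, window = w)
  })
  prof <- Reduce(`+`, lapply(profs, `[[`, "mean_coverage")) / length(profs)
  truth <- spec$background_rate +
    spec$peak_height * peak_bump(-w:w, spec$atac_peak_width)
  expect_gte(pearson_r(prof, truth), 0.9)
  # the ChIP bump maximum sits chip_offset bp downstream of the ATAC one
  profs_chip <- lapply(names(g$genome), function(sid) {
    ss <- g$sites[g$sites$seq_id == sid, ]
    meta_profile(cov$observed$chip[[sid]]$values, centre_of(ss),
                 strands = ss$strand, window = w)
  })
  prof_chip <- Reduce(`+`, lapply(profs_chip, `[[`, "mean_coverage")) /
    length(profs_chip)
  sm <- rolling_mean(prof_chip, 101L)
  expect_lt(abs((which.max(sm) - (w + 1L)) - spec$chip_offset), 60L)
  # and the planted-peak profile passes the 2.5x enrichment QC
  qc <- qc_enrichment(structure(list(offsets = -w:w, mean_coverage = prof,
                                     n_anchors = 1L),
                                class = "meta_profile"))
  expect_true(qc$pass)
})

test_that("truth peaks are recovered from the expectation track", {
  spec <- small_spec(seed = 107L)
  g <- generate_genome(spec)
  cov <- generate_coverage(g$genome, g$sites, spec)
  truth <- truth_peaks(cov$expected$atac, spec)
  expect_equal(nrow(truth), nrow(g$sites))
  # calling peaks on the noiseless track at a mid cutoff reproduces them
  called <- do.call(rbind, lapply(names(g$genome), function(sid) {
    call_peaks(cov$expected$atac[[sid]],
               spec$background_rate + spec$peak_height / 2, seq_id = sid)
  }))
  jac <- function(a, b, n) {
    ma <- peaks_to_mask(a, n); mb <- peaks_to_mask(b, n)
    sum(ma & mb) / sum(ma | mb)
  }
  for (sid in names(g$genome)) {
    expect_gte(jac(truth[truth$seq_id == sid, ],
                   called[called$seq_id == sid, ], spec$seq_length), 0.9)
  }
})

test_that("generated datasets persist and parse back losslessly", {
  spec <- small_spec(seed = 108L)
  dir <- tempfile("synthds")
  ds <- generate_dataset(spec, dir, chunk_len = 1024L)
  expect_true(all(file.exists(unlist(ds$paths))))
  # FASTA round trip
  g <- read_fasta(ds$paths$fasta)
  expect_identical(unname(g), unname(ds$genome))
  # bedGraph round trip
  tr <- read_bedgraph_track(ds$paths$atac_bedgraph, names(g)[1L],
                            nchar(g[[1L]]))
  expect_equal(tr$values, ds$coverage$observed$atac[[1L]]$values)
  # truth BED round trip
  tb <- read_bed(ds$paths$truth_atac)
  expect_equal(tb$start, ds$truth$atac$start)
  expect_equal(tb$end, ds$truth$atac$end)
  # container round trip of coverage targets
  cc <- read_container(ds$paths$container)
  expect_setequal(names(cc$coverage), c("atac", "chip"))
  # two seeds: same schema, different tracks
  ds2 <- generate_dataset(small_spec(seed = 109L), tempfile("synthds"),
                          chunk_len = 1024L)
  expect_identical(names(ds2$paths), names(ds$paths))
  expect_false(identical(ds2$coverage$observed$atac[[1L]]$values,
                         ds$coverage$observed$atac[[1L]]$values))
})
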
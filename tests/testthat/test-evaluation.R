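test_that("guarded Pearson handles identical, constant and random inputs", {
  set.seed(71)
  x <- rnorm(100)
  expect_equal(pearson_r(x, x), 1, tolerance = 1e-6)
  # constant input: zero numerator over the epsilon-guarded denominator
  expect_identical(pearson_r(rep(2, 50), rnorm(50)), 0)
  for (rep in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(pearson_r(a, b), naive_pearson(a, b), tolerance = 1e-6)
    # symmetry and shift/positive-scale invariance
    expect_equal(pearson_r(a, b), pearson_r(b, a))
    expect_equal(pearson_r(2.5 * a + 7, b), pearson_r(a, b),
                 tolerance = 1e-6)
  }
  expect_error(pearson_r(1, 1), "2 unmasked")
  # masked positions are excluded
  m <- c(rep(TRUE, 50), rep(FALSE, 50))
  x2 <- c(x[1:50], rnorm(50) * 100)
  expect_equal(pearson_r(x2, c(x[1:50], rnorm(50)), mask = m), 1,
               tolerance = 1e-6)
})

test_that("base-wise confusion counts match a position loop", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(base_confusion(a, a), list(tp = 2L, fp = 0L, fn = 0L))
  expect_equal(base_confusion(a, !a), list(tp = 0L, fp = 2L, fn = 2L))
  set.seed(72)
  for (rep in 1:20) {
    n <- sample.int(200L, 1L)
    p <- runif(n) < 0.3; e <- runif(n) < 0.3; v <- runif(n) < 0.8
    cf <- base_confusion(p, e, v)
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_len(n)) {
      if (!v[i]) next
      if (p[i] && e[i]) tp <- tp + 1L
      if (p[i] && !e[i]) fp <- fp + 1L
      if (!p[i] && e[i]) fn <- fn + 1L
    }
    expect_equal(cf, list(tp = tp, fp = fp, fn = fn))
  }
})

test_that("precision/recall/F1 follow their definitions with 0-denominators", {
  expect_equal(prf1(2, 1, 1), list(precision = 2/3, recall = 2/3, f1 = 2/3))
  expect_equal(prf1(5, 0, 0), list(precision = 1, recall = 1, f1 = 1))
  expect_equal(prf1(0, 5, 5), list(precision = 0, recall = 0, f1 = 0))
  expect_equal(prf1(0, 0, 0), list(precision = 0, recall = 0, f1 = 0))
  # never NaN on random counts
  set.seed(73)
  for (rep in 1:30) {
    r <- prf1(sample(0:5, 1), sample(0:5, 1), sample(0:5, 1))
    expect_false(any(is.nan(unlist(r))))
  }
})

test_that("PR curve endpoints behave at extreme cutoffs", {
  set.seed(74)
  track <- rpois(500, 2) + 0.5
  exp_mask <- peaks_to_mask(
    data.frame(seq_id = "s", start = c(50L, 300L), end = c(120L, 380L)),
    500L)
  res <- pr_curve(track, exp_mask, cutoffs = c(min(track) - 1, max(track) + 1))
  expect_equal(res$prc$recall[1L], 1)    # everything called at low cutoff
  expect_equal(res$prc$recall[2L], 0)    # nothing called above the maximum
  expect_equal(res$prc$precision[2L], 0)
  expect_gte(res$auprc, 0); expect_lte(res$auprc, 1)
})

test_that("PR points match per-cutoff recomputation on a toy track", {
  track <- c(0, 1, 3, 3, 1, 0, 0, 5, 5, 5, 2, 0)
  exp_mask <- c(rep(FALSE, 7), rep(TRUE, 4), FALSE)
  cutoffs <- c(1, 2, 3, 4, 5)
  res <- pr_curve(track, exp_mask, cutoffs, min_length = 2L, max_gap = 1L)
  for (i in seq_along(cutoffs)) {
    pk <- call_peaks(track, cutoffs[i], min_length = 2L, max_gap = 1L)
    cf <- base_confusion(peaks_to_mask(pk, 12L), exp_mask)
    pr <- prf1(cf$tp, cf$fp, cf$fn)
    expect_equal(res$prc$precision[i], pr$precision)
    expect_equal(res$prc$recall[i], pr$recall)
  }
  # trapezoid over recall-sorted points, cross-checked directly
  o <- order(res$prc$recall)
  r <- res$prc$recall[o]; p <- res$prc$precision[o]
  expect_equal(res$auprc, sum(diff(r) * (p[-1] + p[-length(p)]) / 2))
})

test_that("the baseline AUPRC is the fraction of positive valid bases", {
  expect_equal(baseline_auprc(c(rep(TRUE, 6), rep(FALSE, 94))), 0.06)
  expect_equal(baseline_auprc(rep(TRUE, 10)), 1.0)
  set.seed(75)
  e <- runif(200) < 0.3; v <- runif(200) < 0.7
  expect_equal(baseline_auprc(e, v), sum(e & v) / sum(v))
  expect_error(baseline_auprc(logical(), NULL), "no valid")
})

test_that("meta-profiles average coverage around anchors, strand-aware", {
  const <- rep(3, 9000)
  mp <- meta_profile(const, anchors = 4500L, window = 100L)
  expect_equal(mp$mean_coverage, rep(3, 201))
  # single anchor returns the window itself
  ramp <- seq_len(9000)
  mp1 <- meta_profile(ramp, anchors = 500L, window = 10L)
  expect_equal(mp1$mean_coverage, ramp[(491L):(511L)])
  # two anchors on a ramp: means computed by hand
  mp2 <- meta_profile(ramp, anchors = c(100L, 200L), window = 5L)
  expect_equal(mp2$mean_coverage, (ramp[96:106] + ramp[196:206]) / 2)
  # minus-strand anchors read right to left
  mpm <- meta_profile(ramp, anchors = 500L, strands = "-", window = 10L)
  expect_equal(mpm$mean_coverage, rev(mp1$mean_coverage))
  # clipped anchors contribute only in-bounds offsets
  mpc <- meta_profile(ramp, anchors = 2L, window = 5L)
  expect_true(all(is.na(mpc$mean_coverage[1:3])))
  expect_equal(mpc$mean_coverage[4:11], ramp[1:8])
  expect_error(meta_profile(ramp, integer()), "anchor")
})

test_that("enrichment QC compares the profile peak to flank background", {
  # peak exactly 2.5x the background passes
  prof <- structure(list(offsets = -100:100,
                         mean_coverage = c(rep(2, 50), rep(5, 101),
                                           rep(2, 50)),
                         n_anchors = 10L), class = "meta_profile")
  qc <- qc_enrichment(prof)
  expect_equal(qc$ratio, 2.5)
  expect_true(qc$pass)
  # constant profile fails
  prof$mean_coverage <- rep(1, 201)
  qc2 <- qc_enrichment(prof)
  expect_equal(qc2$ratio, 1.0)
  expect_false(qc2$pass)
  # zero background reports an infinite ratio and passes
  prof$mean_coverage <- c(rep(0, 90), rep(4, 21), rep(0, 90))
  qc3 <- qc_enrichment(prof)
  expect_identical(qc3$ratio, Inf)
  expect_true(qc3$pass)
})

test_that("cutoff grids match the documented sweeps", {
  expect_equal(default_cutoffs("atac_fine"), as.numeric(1:25))
  expect_equal(default_cutoffs("atac_wide"), c(1, seq(5, 200, 5)))
  expect_equal(default_cutoffs("chip"), c(1, seq(5, 100, 5)))
})
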
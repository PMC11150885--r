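# Architecture variants mirroring the published model family: the base
# U-Net, the (Bi)Hybrid versions, and the augmentations with batch
# normalization and dropout.
variant_configs <- function(subseq_len = 1024L) {
  list(
    unet = model_config("unet", subseq_len, filters = c(4L, 8L, 16L),
                        kernel = 9L, step = 2L, batch_norm = FALSE,
                        dropout_p = 0),
    hybrid = model_config("hybrid", subseq_len, filters = c(4L, 8L, 16L),
                          kernel = 9L, step = 2L, n_lstm = 2L,
                          lstm_units = 8L, batch_norm = FALSE,
                          dropout_p = 0),
    bihybrid = model_config("bihybrid", subseq_len, filters = c(4L, 8L, 16L),
                            kernel = 9L, step = 2L, n_lstm = 2L,
                            lstm_units = 8L, batch_norm = FALSE,
                            dropout_p = 0),
    bihybrid_bn = model_config("bihybrid", subseq_len,
                               filters = c(4L, 8L, 16L), kernel = 9L,
                               step = 2L, n_lstm = 2L, lstm_units = 8L,
                               batch_norm = TRUE, dropout_p = 0),
    bihybrid_bn_do3 = model_config("bihybrid", subseq_len,
                                   filters = c(4L, 8L, 16L), kernel = 9L,
                                   step = 2L, n_lstm = 2L, lstm_units = 8L,
                                   batch_norm = TRUE, dropout_p = 0.3),
    bihybrid_bn_do5 = model_config("bihybrid", subseq_len,
                                   filters = c(4L, 8L, 16L), kernel = 9L,
                                   step = 2L, n_lstm = 2L, lstm_units = 8L,
                                   batch_norm = TRUE, dropout_p = 0.5)
  )
}

test_that("conv geometry maps L to L/step exactly and mirrors back", {
  g <- conv_geometry(21384L, 9L, 2L)
  expect_equal(g$L_out, 10692L)
  # three levels halve down to the bottleneck length
  expect_equal(21384L / 2L^3L, 2673L)
  # step 1 is same-padding
  g1 <- conv_geometry(100L, 9L, 1L)
  expect_equal(g1$L_out, 100L)
  expect_error(conv_geometry(10L, 3L, 3L), "not divisible")
  expect_error(conv_geometry(12L, 2L, 3L), "kernel >= step")
})

test_that("layer census matches each architecture variant", {
  cen <- function(cfg) layer_census(build_model(cfg, seed = 1))
  cc <- variant_configs()
  expect_equal(cen(cc$unet)[c("n_conv", "n_tconv", "n_lstm", "n_batchnorm")],
               list(n_conv = 3L, n_tconv = 3L, n_lstm = 0L,
                    n_batchnorm = 0L))
  h <- cen(cc$hybrid)
  expect_equal(h$n_lstm, 2L)
  expect_equal(h$n_bilstm, 0L)
  b <- cen(cc$bihybrid)
  expect_equal(b$n_bilstm, 2L)
  expect_equal(b$n_dropout, 0L)
  bn <- cen(cc$bihybrid_bn)
  expect_equal(bn$n_batchnorm, 6L)
  full <- cen(cc$bihybrid_bn_do3)
  expect_equal(full[c("n_conv", "n_tconv", "n_bilstm", "n_batchnorm",
                      "n_dropout")],
               list(n_conv = 3L, n_tconv = 3L, n_bilstm = 2L,
                    n_batchnorm = 6L, n_dropout = 1L))
  expect_equal(full$dropout_p, 0.3)
  expect_equal(cen(cc$bihybrid_bn_do5)$dropout_p, 0.5)
})

test_that("forward output length equals input length for every variant", {
  set.seed(51)
  x <- array(rnorm(1024L * 4L), c(1L, 1024L, 4L))
  for (nm in names(variant_configs())) {
    cfg <- variant_configs()[[nm]]
    m <- build_model(cfg, seed = 2)
    out <- model_forward(m, x)
    expect_identical(dim(out), c(1L, 1024L, 1L), info = nm)
    expect_true(all(is.finite(out)), info = nm)
  }
})

test_that("invalid inputs and configs are rejected", {
  cfg <- variant_configs()$unet
  m <- build_model(cfg, seed = 1)
  expect_error(model_forward(m, array(0, c(1L, 1024L, 5L))), "4 channels")
  expect_error(model_forward(m, array(0, c(1L, 512L, 4L))), "subseq_len")
  expect_error(model_config("unet", subseq_len = 1000L, step = 3L,
                            filters = c(4L, 8L, 16L)), "divisible")
  expect_error(build_model(structure(list(family = "perceptron"),
                                     class = "model_config")))
})

test_that("evaluation-mode forward is deterministic and padding-safe", {
  cfg <- variant_configs()$bihybrid_bn_do3
  m <- build_model(cfg, seed = 3)
  # fully padded (all-zero) input stays finite
  out0 <- model_forward(m, array(0, c(1L, 1024L, 4L)))
  expect_true(all(is.finite(out0)))
  # duplicated batch rows give identical outputs in eval mode
  set.seed(52)
  x1 <- encode_seq(random_genome(1024))
  x <- array(0, c(2L, 1024L, 4L))
  x[1L, , ] <- x1; x[2L, , ] <- x1
  out <- model_forward(m, x, train = FALSE)
  expect_identical(out[1L, , ], out[2L, , ])
  # bit-stable repeat with fixed weights and input
  expect_identical(model_forward(m, x), out)
})

test_that("rates are strictly positive under the exponential link", {
  m <- build_model(variant_configs()$bihybrid_bn, seed = 4)
  set.seed(53)
  x <- array(sample(c(0, 1), 1024L * 4L, replace = TRUE), c(1L, 1024L, 4L))
  rates <- exp(model_forward(m, x))
  expect_true(all(rates > 0) && all(is.finite(rates)))
})

test_that("analytic gradients match finite differences on a tiny bihybrid", {
  cfg <- model_config("bihybrid", subseq_len = 32L, filters = c(3L, 4L),
                      kernel = 5L, step = 2L, lstm_units = 3L,
                      batch_norm = TRUE, dropout_p = 0)
  m <- build_model(cfg, seed = 5)
  set.seed(54)
  x <- array(rnorm(2L * 32L * 4L), c(2L, 32L, 4L))
  y <- array(as.numeric(rpois(2L * 32L, 2)), c(2L, 32L, 1L))
  fwd_loss <- function() {
    out <- model_forward(m, x, train = TRUE)
    sum(exp(out) - y * out) / length(out)
  }
  out <- model_forward(m, x, train = TRUE)
  model_backward(m, (exp(out) - y) / length(out))
  grad_of <- function(ly, path, idx) {
    g <- ly$grads
    for (nm in path) g <- g[[nm]]
    g[idx]
  }
  fd_of <- function(ly, path, idx, eps = 1e-6) {
    get_set <- function(v = NULL) {
      p <- ly$params
      if (length(path) == 1L) {
        if (is.null(v)) return(p[[path]][idx])
        p[[path]][idx] <- v
      } else {
        if (is.null(v)) return(p[[path[1L]]][[path[2L]]][idx])
        p[[path[1L]]][[path[2L]]][idx] <- v
      }
      ly$params <- p
      NULL
    }
    p0 <- get_set()
    get_set(p0 + eps); lp <- fwd_loss()
    get_set(p0 - eps); lm <- fwd_loss()
    get_set(p0)
    (lp - lm) / (2 * eps)
  }
  types <- vapply(m$layers, function(l) l$type, character(1L))
  cases <- list(
    list(which(types == "conv")[1L], "W", 7L),
    list(which(types == "conv")[2L], "b", 2L),
    list(which(types == "tconv")[1L], "W", 5L),
    list(which(types == "tconv")[2L], "b", 1L),
    list(which(types == "batchnorm")[1L], "gamma", 2L),
    list(which(types == "batchnorm")[4L], "beta", 1L),
    list(which(types == "lstm")[1L], c("fwd", "Wx"), 4L),
    list(which(types == "lstm")[2L], c("bwd", "Wh"), 2L)
  )
  for (cs in cases) {
    ly <- m$layers[[cs[[1L]]]]
    expect_equal(grad_of(ly, cs[[2L]], cs[[3L]]),
                 fd_of(ly, cs[[2L]], cs[[3L]]),
                 tolerance = 1e-5)
  }
})

test_that("checkpoints restore an identical model", {
  cfg <- variant_configs()$bihybrid_bn
  m <- build_model(cfg, seed = 6)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  set.seed(55)
  x <- array(rnorm(1024L * 4L), c(1L, 1024L, 4L))
  expect_identical(model_forward(m, x), model_forward(m2, x))
  expect_error(load_checkpoint({
    p <- tempfile(); saveRDS(list(a = 1), p); p
  }), "checkpoint")
})

test_that("predict_rates averages re-oriented strand predictions", {
  # a model whose weights are all zero emits log rate 0, i.e. rate 1
  cfg <- model_config("unet", subseq_len = 64L, filters = c(2L, 2L),
                      kernel = 4L, step = 2L, batch_norm = FALSE,
                      dropout_p = 0)
  m <- build_model(cfg, seed = 7)
  w <- model_weights(m)
  w <- rapply(w, function(p) p * 0, how = "replace")
  set_model_weights(m, w)
  set.seed(56)
  g <- c(s1 = random_genome(100))
  chunks <- chunk_genome_all(g, 64L)
  pred <- predict_rates(m, chunks)
  expect_equal(nrow(pred$s1$mean), 100L)  # padding dropped on stitching
  expect_true(all(pred$s1$mean == 1))
  # random weights: mean equals (plus + re-reversed minus)/2
  m2 <- build_model(cfg, seed = 8)
  pred2 <- predict_rates(m2, chunks)
  expect_equal(pred2$s1$mean, (pred2$s1$plus + pred2$s1$minus) / 2)
  expect_false(isTRUE(all.equal(pred2$s1$plus, pred2$s1$minus)))
  # unpaired strands are rejected
  plus_only <- Filter(function(ch) ch$strand == "+", chunks)
  expect_error(predict_rates(m2, plus_only), "pairs")
})
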
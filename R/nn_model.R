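#' Model configuration for the sequence-to-coverage architectures
#'
#' Three architecture families are supported. `unet` is a stack of strided
#' convolutions (downsampling) mirrored by transposed convolutions
#' (upsampling back to base resolution). `hybrid` inserts a block of
#' unidirectional LSTM layers at the bottleneck, between the two stacks;
#' `bihybrid` uses bidirectional LSTMs there instead. Every convolutional
#' and transposed convolutional layer is followed by a ReLU and, when
#' `batch_norm` is on, a batch-normalization layer (placed after the
#' activation); with dropout enabled, one dropout layer follows each
#' recurrent layer except the last. The last transposed convolution emits
#' the output: base-wise predictions in log space, so actual coverage
#' predictions are their exponential (see [predict_rates()]).
#'
#' @param family `"unet"`, `"hybrid"` or `"bihybrid"`.
#' @param subseq_len Model input length in bp; must be divisible by
#'   `step^n_conv`.
#' @param filters Integer vector of channel counts, one per convolution
#'   level (`n_conv = length(filters)`; the transposed stack mirrors it).
#' @param kernel Kernel width of all (transposed) convolutions (odd kernels
#'   give symmetric padding).
#' @param step Stride per convolution level; doubles as pooling factor.
#' @param n_lstm Number of recurrent layers at the bottleneck (ignored for
#'   `unet`, where it is 0).
#' @param lstm_units Hidden units per recurrent layer (per direction).
#' @param batch_norm Add batch normalization after each (t)conv activation?
#' @param dropout_p Dropout probability after each recurrent layer except
#'   the last; 0 disables dropout.
#' @param n_outputs Number of coverage tracks predicted simultaneously
#'   (1 for a single dataset kind, 2 for ATAC + ChIP combined).
#' @return A `model_config` object (validated list).
#' @export
model_config <- function(family = c("bihybrid", "hybrid", "unet"),
                         subseq_len = DEFAULT_CHUNK_LEN,
                         filters = c(16L, 32L, 64L),
                         kernel = 9L, step = 2L,
                         n_lstm = 2L, lstm_units = 32L,
                         batch_norm = TRUE, dropout_p = 0.3,
                         n_outputs = 1L) {
  family <- match.arg(family)
  filters <- as.integer(filters)
  n_conv <- length(filters)
  stopifnot(n_conv >= 1L, all(filters > 0L), kernel >= 1L, step >= 1L,
            n_outputs >= 1L, dropout_p >= 0, dropout_p < 1)
  if (family == "unet") n_lstm <- 0L
  if (family != "unet") stopifnot(n_lstm >= 1L, lstm_units >= 1L)
  if (subseq_len %% step^n_conv != 0L) {
    stop("subseq_len ", subseq_len, " is not divisible by step^n_conv = ",
         step^n_conv)
  }
  structure(list(family = family, subseq_len = as.integer(subseq_len),
                 filters = filters, n_conv = n_conv, n_tconv = n_conv,
                 kernel = as.integer(kernel), step = as.integer(step),
                 n_lstm = as.integer(n_lstm),
                 lstm_units = as.integer(lstm_units),
                 batch_norm = isTRUE(batch_norm), dropout_p = dropout_p,
                 n_outputs = as.integer(n_outputs)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config> %s L=%d filters=%s kernel=%d step=%d lstm=%dx%d bn=%s dropout=%.2f outputs=%d\n",
    x$family, x$subseq_len, paste(x$filters, collapse = ","), x$kernel,
    x$step, x$n_lstm, x$lstm_units, x$batch_norm, x$dropout_p, x$n_outputs))
  invisible(x)
}

#' Build a sequence-to-coverage model
#'
#' Instantiates the layer stack described by a [model_config()]. Weight
#' initialisation draws from R's RNG, so call `set.seed()` beforehand (or
#' pass `seed`) for reproducible models.
#'
#' @param cfg A `model_config`.
#' @param seed Optional integer seed for the weight initialisation.
#' @return A `seq2cov_model`: list with `cfg` and `layers`.
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (!cfg$family %in% c("unet", "hybrid", "bihybrid")) {
    stop("unknown model family: ", cfg$family)
  }
  if (!is.null(seed)) set.seed(seed)
  layers <- list()
  L <- cfg$subseq_len
  cin <- 4L
  for (i in seq_len(cfg$n_conv)) {
    layers <- c(layers, list(new_conv(L, cin, cfg$filters[i], cfg$kernel,
                                      cfg$step)))
    layers <- c(layers, list(new_relu()))
    if (cfg$batch_norm) {
      layers <- c(layers, list(new_batchnorm(cfg$filters[i])))
    }
    cin <- cfg$filters[i]
    L <- L %/% cfg$step
  }
  if (cfg$family != "unet") {
    bidir <- cfg$family == "bihybrid"
    for (j in seq_len(cfg$n_lstm)) {
      layers <- c(layers, list(new_lstm(cin, cfg$lstm_units, bidir)))
      cin <- if (bidir) 2L * cfg$lstm_units else cfg$lstm_units
      if (cfg$dropout_p > 0 && j < cfg$n_lstm) {
        layers <- c(layers, list(new_dropout(cfg$dropout_p)))
      }
    }
  }
  up_channels <- c(rev(cfg$filters)[-1L], cfg$n_outputs)
  for (i in seq_len(cfg$n_tconv)) {
    L <- L * cfg$step
    layers <- c(layers, list(new_tconv(L, cin, up_channels[i], cfg$kernel,
                                       cfg$step)))
    layers <- c(layers, list(new_relu()))
    if (cfg$batch_norm) {
      layers <- c(layers, list(new_batchnorm(up_channels[i])))
    }
    cin <- up_channels[i]
  }
  structure(list(cfg = cfg, layers = layers), class = "seq2cov_model")
}

#' @export
print.seq2cov_model <- function(x, ...) {
  cen <- layer_census(x)
  cat(sprintf(
    "<seq2cov_model> %s: %d conv + %d tconv + %d %s + %d batchnorm + %d dropout, %d parameters\n",
    x$cfg$family, cen$n_conv, cen$n_tconv, cen$n_lstm,
    if (x$cfg$family == "bihybrid") "BiLSTM" else "LSTM",
    cen$n_batchnorm, cen$n_dropout, n_parameters(x)))
  invisible(x)
}

#' Count layers by type
#'
#' Census of the instantiated layer stack, used to check that a built model
#' matches its intended architecture variant (e.g. 3 conv + 3 tconv +
#' 2 BiLSTM + 6 batch-norm + 1 dropout).
#'
#' @param model A `seq2cov_model`.
#' @return List with `n_conv`, `n_tconv`, `n_lstm`, `n_bilstm`,
#'   `n_batchnorm`, `n_dropout`, `dropout_p`.
#' @export
layer_census <- function(model) {
  types <- vapply(model$layers, function(l) l$type, character(1L))
  bidir <- vapply(model$layers,
                  function(l) identical(l$type, "lstm") && l$bidirectional,
                  logical(1L))
  list(n_conv = sum(types == "conv"),
       n_tconv = sum(types == "tconv"),
       n_lstm = sum(types == "lstm"),
       n_bilstm = sum(bidir),
       n_batchnorm = sum(types == "batchnorm"),
       n_dropout = sum(types == "dropout"),
       dropout_p = model$cfg$dropout_p)
}

n_parameters <- function(model) {
  total <- 0L
  walk <- function(p) {
    if (is.list(p)) for (q in p) walk(q) else total <<- total + length(p)
  }
  for (ly in model$layers) walk(ly$params)
  total
}

#' Forward pass
#'
#' Runs a batch through the network. The output is in log space (the
#' Poisson loss is evaluated on log predictions); exponentiate to get
#' coverage rates. In evaluation mode (`train = FALSE`) the pass is
#' deterministic: dropout is the identity and batch normalization uses its
#' running statistics.
#'
#' @param model A `seq2cov_model`.
#' @param x Input array `B x L x 4` with `L == cfg$subseq_len` (an encoded
#'   matrix from a single chunk may be passed as `L x 4`).
#' @param train Training mode flag.
#' @return Array `B x L x n_outputs` of log rates.
#' @export
model_forward <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x))
  d <- dim(x)
  if (d[3L] != 4L) stop("input must have 4 channels, got ", d[3L])
  if (d[2L] != model$cfg$subseq_len) {
    stop("input length ", d[2L], " != configured subseq_len ",
         model$cfg$subseq_len)
  }
  for (ly in model$layers) x <- layer_forward(ly, x, train)
  x
}

#' Backward pass (gradient of a scalar loss w.r.t. all parameters)
#'
#' Must follow a forward pass with `train = TRUE`; consumes the caches the
#' forward pass left in the layers and stores each layer's gradients in
#' `layer$grads`.
#'
#' @param model A `seq2cov_model`.
#' @param d_out Gradient of the loss w.r.t. the log-space output,
#'   `B x L x n_outputs`.
#' @return Gradient w.r.t. the input (invisibly).
#' @export
model_backward <- function(model, d_out) {
  for (ly in rev(model$layers)) d_out <- layer_backward(ly, d_out)
  invisible(d_out)
}

#' Extract / restore model weights
#'
#' `model_weights()` deep-copies all parameters (and batch-norm running
#' statistics) into a plain list; `set_model_weights()` writes such a list
#' back. Used for checkpointing the best-validation model.
#'
#' @param model A `seq2cov_model`.
#' @return Nested list of numeric arrays.
#' @export
model_weights <- function(model) {
  lapply(model$layers, function(ly) {
    w <- list(params = ly$params)
    if (ly$type == "batchnorm") {
      w$running_mean <- ly$running_mean
      w$running_var <- ly$running_var
    }
    w
  })
}

#' @rdname model_weights
#' @param weights List produced by `model_weights()`.
#' @export
set_model_weights <- function(model, weights) {
  stopifnot(length(weights) == length(model$layers))
  for (i in seq_along(weights)) {
    ly <- model$layers[[i]]
    ly$params <- weights[[i]]$params
    if (ly$type == "batchnorm") {
      ly$running_mean <- weights[[i]]$running_mean
      ly$running_var <- weights[[i]]$running_var
    }
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the full `model_config`, all weights and a schema
#' version, so a model can be rebuilt exactly.
#'
#' @param model A `seq2cov_model`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(schema = "seq2cov-checkpoint", version = 1L,
               cfg = model$cfg, weights = model_weights(model)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the rebuilt `seq2cov_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, "seq2cov-checkpoint")) {
    stop("not a seq2cov checkpoint: ", path)
  }
  model <- build_model(ck$cfg)
  set_model_weights(model, ck$weights)
  model
}

#' Predict coverage rates for paired-strand chunks
#'
#' Runs the model in evaluation mode over plus/minus chunk pairs, converts
#' log predictions to rates (`exp`), maps minus-strand outputs back to
#' plus-strand coordinates, drops padded positions and stitches chunks into
#' per-sequence tracks. The per-base prediction is the average of the two
#' strand predictions.
#'
#' @param model A `seq2cov_model`.
#' @param chunks List of `encoded_chunk` objects containing, for every
#'   window, one plus- and one minus-strand chunk.
#' @param batch_size Windows per forward pass.
#' @return Named list per sequence; each element is a list with matrices
#'   `plus`, `minus`, `mean` (`seq_length x n_outputs`, plus-strand
#'   coordinates).
#' @export
predict_rates <- function(model, chunks, batch_size = 8L) {
  key <- vapply(chunks, function(ch) {
    paste(ch$seq_id, ch$start, ch$end, sep = ":")
  }, character(1L))
  strands <- vapply(chunks, `[[`, character(1L), "strand")
  plus_i <- which(strands == "+")
  minus_i <- which(strands == "-")
  if (length(plus_i) != length(minus_i) ||
      !setequal(key[plus_i], key[minus_i])) {
    stop("chunks must come in plus/minus pairs per window")
  }
  minus_i <- minus_i[match(key[plus_i], key[minus_i])]

  L <- model$cfg$subseq_len
  no <- model$cfg$n_outputs
  predict_batch <- function(idx) {
    x <- array(0, c(length(idx), L, 4L))
    for (b in seq_along(idx)) x[b, , ] <- chunks[[idx[b]]]$matrix
    exp(model_forward(model, x, train = FALSE))
  }
  run_all <- function(idx) {
    out <- vector("list", length(idx))
    for (s in seq(1L, length(idx), by = batch_size)) {
      e <- min(s + batch_size - 1L, length(idx))
      r <- predict_batch(idx[s:e])
      for (b in seq_len(e - s + 1L)) {
        m <- r[b, , , drop = FALSE]
        dim(m) <- c(L, no)
        out[[s + b - 1L]] <- m
      }
    }
    out
  }
  pred_plus <- run_all(plus_i)
  pred_minus <- run_all(minus_i)

  seq_ids <- vapply(chunks[plus_i], `[[`, character(1L), "seq_id")
  result <- list()
  for (sid in unique(seq_ids)) {
    sel <- which(seq_ids == sid)
    sel <- sel[order(vapply(chunks[plus_i[sel]], `[[`, numeric(1L), "start"))]
    plus_track <- NULL; minus_track <- NULL
    for (j in sel) {
      chp <- chunks[[plus_i[j]]]
      real <- sum(chp$pad_mask)
      p <- pred_plus[[j]][seq_len(real), , drop = FALSE]
      # minus-strand rows run 3'->5'; reverse them back to plus coordinates
      m <- pred_minus[[j]][seq_len(real), , drop = FALSE]
      m <- m[rev(seq_len(real)), , drop = FALSE]
      plus_track <- rbind(plus_track, p)
      minus_track <- rbind(minus_track, m)
    }
    result[[sid]] <- list(plus = plus_track, minus = minus_track,
                          mean = (plus_track + minus_track) / 2)
  }
  result
}
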
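#' Masked Poisson negative log-likelihood loss
#'
#' The loss driving training:
#' \deqn{loss = \frac{1}{n} \sum_{i=1}^{n} e^{x_i} - y_i x_i}
#' where `x` are log-space predictions, `y` the target coverage counts and
#' the sum runs over the `n` unmasked positions only (padded bases are
#' masked and never contribute). Peak-less Poisson coverage makes this the
#' natural likelihood; predicting in log space keeps rates positive.
#'
#' @param x Numeric array of log-space predictions.
#' @param y Target coverage, same shape.
#' @param mask Optional logical array; `TRUE` positions count. A mask of
#'   length `length(x)/k` is recycled over a trailing output axis.
#' @return Scalar loss.
#' @export
poisson_loss <- function(x, y, mask = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(mask)) {
    mask <- rep(TRUE, length(x))
  } else {
    mask <- as.logical(mask)
    if (length(x) %% length(mask) != 0L) {
      stop("mask length is not a divisor of the prediction length")
    }
    mask <- rep(mask, times = length(x) %/% length(mask))
  }
  n <- sum(mask)
  if (n == 0L) stop("all positions are masked; loss undefined")
  if (any(y[mask] < 0)) stop("targets must be non-negative where unmasked")
  sum(exp(x[mask]) - y[mask] * x[mask]) / n
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else array(0, dim = dim(p) %||% length(p))
  }
  list(t = 0L,
       m = lapply(model$layers, function(ly) zero_like(ly$params)),
       v = lapply(model$layers, function(ly) zero_like(ly$params)))
}

adam_step <- function(model, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (length(ly$params) == 0L) next
    r <- upd(ly$params, ly$grads, state$m[[i]], state$v[[i]])
    ly$params <- r$p
    state$m[[i]] <- r$m
    state$v[[i]] <- r$v
  }
  state
}

# ---- training loop --------------------------------------------------------

#' Validation Pearson correlation of a model
#'
#' Predicted rates (`exp` of the log-space output, evaluation mode) are
#' correlated with the targets over all unmasked positions, concatenated
#' across windows; with several outputs, the per-output correlations are
#' averaged.
#'
#' @param model A `seq2cov_model`.
#' @param x Input array `N x L x 4`.
#' @param y Target array `N x L x n_outputs`.
#' @param mask Logical `N x L` (TRUE = position counts).
#' @param batch_size Windows per forward pass.
#' @return Scalar mean Pearson r.
#' @export
evaluate_pearson <- function(model, x, y, mask, batch_size = 16L) {
  N <- dim(x)[1L]
  no <- model$cfg$n_outputs
  preds <- vector("list", ceiling(N / batch_size))
  bi <- 0L
  for (s in seq(1L, N, by = batch_size)) {
    e <- min(s + batch_size - 1L, N)
    bi <- bi + 1L
    preds[[bi]] <- exp(model_forward(model, x[s:e, , , drop = FALSE],
                                     train = FALSE))
  }
  rs <- numeric(no)
  for (k in seq_len(no)) {
    pairs <- lapply(seq_along(preds), function(b) {
      s <- (b - 1L) * batch_size + 1L
      e <- min(s + batch_size - 1L, N)
      mb <- mask[s:e, , drop = FALSE]
      p <- preds[[b]][, , k, drop = FALSE]
      yb <- y[s:e, , k, drop = FALSE]
      list(p = p[mb], y = yb[mb])
    })
    rs[k] <- pearson_r(unlist(lapply(pairs, `[[`, "p")),
                       unlist(lapply(pairs, `[[`, "y")))
  }
  mean(rs)
}

#' Train a model with the masked Poisson loss and Adam
#'
#' Standard epoch loop: windows are shuffled (seeded), minibatches are run
#' forward in training mode, the masked Poisson loss gradient
#' `(exp(x) - y)/n` is backpropagated and Adam updates the weights. After
#' every epoch the validation Pearson correlation is computed; the epoch
#' with the highest value defines the best model, whose weights are
#' restored into `model` at the end (and optionally checkpointed). Training
#' stops early when validation Pearson has not improved for `patience`
#' epochs. A non-finite loss aborts with the offending epoch/batch index.
#'
#' @param model A `seq2cov_model` (modified in place).
#' @param x,y,mask Training arrays (see [evaluate_pearson()] for shapes).
#' @param val_x,val_y,val_mask Validation arrays, disjoint from training.
#' @param epochs Maximum epochs.
#' @param batch_size Windows per minibatch.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience in epochs (default: none).
#' @param seed Seed for shuffling and dropout; `NULL` uses the current RNG.
#' @param checkpoint Optional path; the best model is saved there.
#' @param verbose Print one line per epoch?
#' @return A `train_state` list: `epoch`, `best_epoch`,
#'   `best_val_pearson`, `history` (data frame epoch/train_loss/
#'   val_pearson), `best_checkpoint`, `seed`.
#' @export
train_model <- function(model, x, y, mask, val_x, val_y, val_mask,
                        epochs = 10L, batch_size = 16L, lr = 1e-2,
                        patience = Inf, seed = NULL, checkpoint = NULL,
                        verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  N <- dim(x)[1L]
  no <- model$cfg$n_outputs
  state <- adam_init(model)
  best <- list(pearson = -Inf, epoch = 0L, weights = model_weights(model))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_pearson = numeric())
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; n_batches <- 0L
    for (s in seq(1L, N, by = batch_size)) {
      e <- min(s + batch_size - 1L, N)
      idx <- ord[s:e]
      xb <- x[idx, , , drop = FALSE]
      yb <- y[idx, , , drop = FALSE]
      mb <- mask[idx, , drop = FALSE]
      out <- model_forward(model, xb, train = TRUE)
      mb3 <- array(rep(mb, times = no), dim = dim(out))
      n_unmasked <- sum(mb3)
      if (n_unmasked == 0L) stop("all-masked batch at epoch ", ep)
      loss <- sum((exp(out) - yb * out)[mb3]) / n_unmasked
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", ep, ", batch ", n_batches + 1L,
             " (first window index ", idx[1L], ")")
      }
      d_out <- (exp(out) - yb) * mb3 / n_unmasked
      model_backward(model, d_out)
      state <- adam_step(model, state, lr)
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
    }
    vp <- evaluate_pearson(model, val_x, val_y, val_mask,
                           batch_size = batch_size)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss / n_batches,
                                val_pearson = vp))
    if (verbose) {
      message(sprintf("epoch %d: train loss %.5f, val pearson %.4f",
                      ep, ep_loss / n_batches, vp))
    }
    if (vp > best$pearson) {
      best <- list(pearson = vp, epoch = ep, weights = model_weights(model))
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  set_model_weights(model, best$weights)
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  structure(list(epoch = nrow(history), best_epoch = best$epoch,
                 best_val_pearson = best$pearson, history = history,
                 best_checkpoint = checkpoint, seed = seed),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state> %d epochs, best val pearson %.4f at epoch %d\n",
              x$epoch, x$best_val_pearson, x$best_epoch))
  invisible(x)
}

# ---- splits ---------------------------------------------------------------

#' Whole-sequence intra-species train/validation split
#'
#' Each sequence identifier is fully assigned to either the training or the
#' validation set (never split), so no window leaks across the boundary.
#' IDs are shuffled (seeded) and a prefix goes to validation such that the
#' realised share of validation bases is as close to `fraction` as
#' whole-ID assignment allows.
#'
#' @param seq_lengths Named numeric vector: sequence length in bp per ID.
#' @param fraction Target validation share of bases, in (0, 1).
#' @param seed Optional shuffling seed.
#' @return List with character vectors `train_ids` and `val_ids`.
#' @export
intra_species_split <- function(seq_lengths, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1, !is.null(names(seq_lengths)))
  if (!is.null(seed)) set.seed(seed)
  ids <- names(seq_lengths)
  if (length(ids) == 1L) {
    warning("only one sequence; assigning it to training, validation empty")
    return(list(train_ids = ids, val_ids = character()))
  }
  ord <- sample(ids)
  share <- cumsum(seq_lengths[ord]) / sum(seq_lengths)
  k <- which.min(abs(c(0, share[-length(share)]) - fraction)) - 1L
  # prefix of size k to validation; never the whole genome
  list(train_ids = ord[setdiff(seq_along(ord), seq_len(k))],
       val_ids = if (k > 0L) ord[seq_len(k)] else character())
}

#' Leave-one-out cross-validation plan over species
#'
#' One fold per species: the fold trains on all other species and validates
#' on the held-out one.
#'
#' @param species Character vector of at least two distinct species names.
#' @return List of folds, each `list(train, held_out)`.
#' @export
loocv_plan <- function(species) {
  if (anyDuplicated(species)) {
    stop("duplicate species names: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  if (length(species) < 2L) stop("need at least two species")
  lapply(species, function(sp) {
    list(train = setdiff(species, sp), held_out = sp)
  })
}

# ---- container -> arrays --------------------------------------------------

#' Assemble training arrays from a dataset container
#'
#' Converts the chunks and coverage matrices of a read container into the
#' dense arrays the training loop consumes, dropping gap chunks and
#' blacklisted chunks. The target mask is the padding mask (sentinel
#' positions are masked out).
#'
#' @param container List returned by [read_container()].
#' @param kinds Coverage kinds to stack as outputs (default: all present).
#' @param seq_ids Optional: restrict to chunks of these sequences (used for
#'   train/validation splits).
#' @return List with `x` (N x L x 4), `y` (N x L x n_kinds), `mask`
#'   (N x L logical), `chunks` (the retained chunk objects) and `kinds`.
#' @export
training_arrays <- function(container, kinds = NULL, seq_ids = NULL) {
  if (is.null(kinds)) kinds <- names(container$coverage)
  if (length(kinds) == 0L) stop("container holds no coverage to train on")
  keep <- !vapply(container$chunks, `[[`, logical(1L), "is_gap") &
    !container$blacklist_flag
  if (!is.null(seq_ids)) {
    keep <- keep & vapply(container$chunks, `[[`, character(1L),
                          "seq_id") %in% seq_ids
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("no usable chunks after filtering")
  L <- nrow(container$chunks[[idx[1L]]]$matrix)
  N <- length(idx)
  x <- array(0, c(N, L, 4L))
  y <- array(0, c(N, L, length(kinds)))
  mask <- matrix(FALSE, N, L)
  for (b in seq_len(N)) {
    ch <- container$chunks[[idx[b]]]
    x[b, , ] <- ch$matrix
    mask[b, ] <- ch$pad_mask
    for (k in seq_along(kinds)) {
      v <- container$coverage[[kinds[k]]][idx[b], ]
      v[!ch$pad_mask] <- 0
      y[b, , k] <- v
    }
  }
  list(x = x, y = y, mask = mask, chunks = container$chunks[idx],
       kinds = kinds)
}
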
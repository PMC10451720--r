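#' Configuration of the recurrent aggression classifier
#'
#' An LSTM consumes the packed 600-dimensional vector of each kept frame; a
#' fully connected head fuses the temporal features of the whole clip into a
#' single logit, and a sigmoid converts it to the probability that the clip
#' contains aggression. Training minimises binary cross-entropy with Adam.
#'
#' @param input_dim Per-frame input length (600: 4 quadrant blocks of 150).
#' @param hidden_dim LSTM hidden units (default 128).
#' @param num_layers Stacked LSTM layers (default 1).
#' @param fusion `"concat_all_steps"` (default: the fully connected head
#'   sees the hidden state of every frame, concatenated) or `"last_step"`.
#' @param learning_rate Initial Adam learning rate (default 0.01).
#' @param epochs Training epochs (default 200).
#' @param optimizer_name Only `"adam"` is implemented.
#' @param batch_size Minibatch size (default 32). Independent of the
#'   sequence length: a clip's frame count is set by [skip_config()].
#' @param seed Integer seed; all parameter initialisation and minibatch
#'   shuffling derive from it.
#' @param decision_threshold Probability at or above which a clip is called
#'   aggressive (default 0.5, `>=` rule).
#' @param translate_sd SD (in normalized image units) of the per-clip,
#'   per-epoch random camera-pan translation applied to occupied x/y
#'   entries during training (default 0.1; 0 disables). Aggression is a
#'   motion pattern, not a place: the translation makes absolute position
#'   uninformative so the network must read temporal dynamics.
#' @param scale_sd SD of the log of the per-clip random zoom factor applied
#'   about the image center during training (default 0.1; 0 disables).
#' @param dropout_tuples Probability that an occupied `[x, y, w, h]` tuple
#'   is zeroed during training (extra simulated missed detections;
#'   default 0.05).
#' @param jitter_sd SD of the coordinate jitter added to occupied entries
#'   during training (normalized units, default 0.005).
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(input_dim = 600L, hidden_dim = 128L,
                              num_layers = 1L,
                              fusion = c("concat_all_steps", "last_step"),
                              learning_rate = 0.01, epochs = 200L,
                              optimizer_name = "adam", batch_size = 32L,
                              seed = 42L, decision_threshold = 0.5,
                              translate_sd = 0.1, scale_sd = 0.1,
                              dropout_tuples = 0.05, jitter_sd = 0.005) {
  fusion <- match.arg(fusion)
  if (input_dim <= 0 || hidden_dim <= 0 || num_layers <= 0 || batch_size <= 0) {
    rlang::abort("dimensions and batch size must be positive.")
  }
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    rlang::abort("`decision_threshold` must lie in (0, 1).")
  }
  if (!identical(optimizer_name, "adam")) {
    rlang::abort("only the 'adam' optimizer is implemented.")
  }
  if (epochs < 0) rlang::abort("`epochs` must be >= 0.")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 num_layers = as.integer(num_layers),
                 fusion = fusion, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 optimizer_name = optimizer_name,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold,
                 translate_sd = translate_sd,
                 scale_sd = scale_sd,
                 dropout_tuples = dropout_tuples,
                 jitter_sd = jitter_sd),
            class = "classifier_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with probabilities
#' clipped to `[1e-7, 1 - 1e-7]` for numerical stability. On a balanced set
#' an uninformative constant p = 0.5 predictor scores exactly `log(2)`,
#' about 0.6931 — the plateau a sequence model sits at when its input
#' carries no usable class signal.
#'
#' @param probability Predicted probabilities in \[0, 1\].
#' @param label Reference 0/1 labels.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(probability, label) {
  if (length(probability) != length(label)) {
    rlang::abort("`probability` and `label` must have equal length.")
  }
  p <- pmin(pmax(probability, 1e-7), 1 - 1e-7)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

init_matrix <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

# Which columns of a packed vector hold x and y coordinates. Packed vectors
# are laid out in quadrant blocks of 150 dims (37 [x,y,w,h] tuples + 2
# always-zero trailing dims); inputs that are not a multiple of 150 are
# treated as flat 4-tuple sequences.
channel_columns <- function(input_dim) {
  block <- if (input_dim %% 150L == 0L) 150L else input_dim
  offset <- (seq_len(input_dim) - 1L) %% block
  tuple_cols <- offset < 4L * (block %/% 4L)
  list(x = which(tuple_cols & offset %% 4L == 0L),
       y = which(tuple_cols & offset %% 4L == 1L))
}

#' Build an untrained recurrent classifier
#'
#' Initialises the LSTM gate weights (forget, input, output gates and the
#' cell candidate, each `input -> 4 * hidden`) uniformly in
#' `[-1/sqrt(hidden), 1/sqrt(hidden)]` from `config$seed`. The fully
#' connected fusion head depends on the clip length `T`, which is fixed at
#' the first call that sees data; its weights are likewise derived from the
#' seed, so two builds with the same seed are bit-identical.
#'
#' @param config A [classifier_config()].
#' @return A `flock_lstm` model object.
#' @export
build_classifier <- function(config = classifier_config()) {
  set.seed(config$seed)
  H <- config$hidden_dim
  scale <- 1 / sqrt(H)
  layers <- vector("list", config$num_layers)
  for (l in seq_len(config$num_layers)) {
    D <- if (l == 1) config$input_dim else H
    layers[[l]] <- list(W = init_matrix(D, 4L * H, scale),
                        U = init_matrix(H, 4L * H, scale),
                        b = numeric(4L * H))
  }
  structure(list(config = config, layers = layers, fc = NULL, fc_T = NULL,
                 history = tibble::tibble(epoch = integer(0),
                                          train_loss = double(0),
                                          val_loss = double(0),
                                          precision = double(0),
                                          recall = double(0)),
                 trained = FALSE),
            class = "flock_lstm")
}

ensure_fc <- function(model, T_steps) {
  if (!is.null(model$fc)) {
    if (model$fc_T != T_steps && model$config$fusion == "concat_all_steps") {
      rlang::abort(sprintf(
        "model was built for clips of %d frames; got %d (clips must share T).",
        model$fc_T, T_steps))
    }
    return(model)
  }
  H <- model$config$hidden_dim
  fan_in <- if (model$config$fusion == "concat_all_steps") T_steps * H else H
  set.seed(model$config$seed + 1L)
  model$fc <- list(w = init_matrix(fan_in, 1L, 1 / sqrt(fan_in)),
                   b = 0)
  model$fc_T <- as.integer(T_steps)
  model
}

# clips (list of T x D matrices) -> list over t of N x D matrices
stack_time_major <- function(clips, input_dim) {
  T_steps <- unique(vapply(clips, nrow, 0L))
  if (length(T_steps) != 1) {
    rlang::abort("all clips in a batch must share the same number of frames T.")
  }
  dims <- unique(vapply(clips, ncol, 0L))
  if (length(dims) != 1 || dims != input_dim) {
    rlang::abort(sprintf("clips must be T x %d matrices.", input_dim))
  }
  lapply(seq_len(T_steps), function(t) {
    do.call(rbind, lapply(clips, function(m) m[t, ]))
  })
}

# Gate layout in the 4H columns: [input | forget | cell candidate | output].
# Forward pass for one layer over all time steps; X is a list of N x D
# matrices. Returns hidden states and (optionally) the caches BPTT needs.
lstm_layer_forward <- function(params, X, keep_cache = FALSE) {
  H <- ncol(params$U)
  Hn <- H / 4L
  N <- nrow(X[[1]])
  T_steps <- length(X)
  h <- matrix(0, N, Hn)
  cc <- matrix(0, N, Hn)
  hs <- vector("list", T_steps)
  cache <- if (keep_cache) vector("list", T_steps) else NULL
  idx_i <- seq_len(Hn)
  idx_f <- Hn + idx_i
  idx_g <- 2L * Hn + idx_i
  idx_o <- 3L * Hn + idx_i
  for (t in seq_len(T_steps)) {
    z <- X[[t]] %*% params$W + h %*% params$U +
      matrix(params$b, N, H, byrow = TRUE)
    gi <- sigmoid(z[, idx_i, drop = FALSE])
    gf <- sigmoid(z[, idx_f, drop = FALSE])
    gg <- tanh(z[, idx_g, drop = FALSE])
    go <- sigmoid(z[, idx_o, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev_cache <- h
    h <- go * tc
    hs[[t]] <- h
    if (keep_cache) {
      cache[[t]] <- list(x = X[[t]], h_prev = h_prev_cache, c_prev = c_prev,
                         gi = gi, gf = gf, gg = gg, go = go, cc = cc, tc = tc)
    }
  }
  list(hs = hs, cache = cache)
}

# Backprop through time for one layer. dh_ext: list over t of external
# gradients on h_t (NULL entries allowed). Returns parameter gradients and,
# if need_dx, gradients on the layer inputs.
lstm_layer_backward <- function(params, cache, dh_ext, need_dx = FALSE) {
  T_steps <- length(cache)
  N <- nrow(cache[[1]]$x)
  Hn <- ncol(cache[[1]]$gi)
  dW <- matrix(0, nrow(params$W), ncol(params$W))
  dU <- matrix(0, nrow(params$U), ncol(params$U))
  db <- numeric(length(params$b))
  dx <- if (need_dx) vector("list", T_steps) else NULL
  dh_carry <- matrix(0, N, Hn)
  dc_carry <- matrix(0, N, Hn)
  for (t in rev(seq_len(T_steps))) {
    cc <- cache[[t]]
    dh <- dh_carry
    if (!is.null(dh_ext[[t]])) dh <- dh + dh_ext[[t]]
    dgo <- dh * cc$tc
    dc <- dc_carry + dh * cc$go * (1 - cc$tc^2)
    dgi <- dc * cc$gg
    dgg <- dc * cc$gi
    dgf <- dc * cc$c_prev
    dz <- cbind(dgi * cc$gi * (1 - cc$gi),
                dgf * cc$gf * (1 - cc$gf),
                dgg * (1 - cc$gg^2),
                dgo * cc$go * (1 - cc$go))
    dW <- dW + crossprod(cc$x, dz)
    dU <- dU + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dh_carry <- dz %*% t(params$U)
    dc_carry <- dc * cc$gf
    if (need_dx) dx[[t]] <- dz %*% t(params$W)
  }
  list(W = dW, U = dU, b = db, dx = dx)
}

model_forward <- function(model, X, keep_cache = FALSE) {
  acts <- vector("list", length(model$layers))
  input <- X
  for (l in seq_along(model$layers)) {
    acts[[l]] <- lstm_layer_forward(model$layers[[l]], input, keep_cache)
    input <- acts[[l]]$hs
  }
  hs <- acts[[length(acts)]]$hs
  fused <- if (model$config$fusion == "concat_all_steps") {
    do.call(cbind, hs)
  } else {
    hs[[length(hs)]]
  }
  logit <- fused %*% model$fc$w + model$fc$b
  list(p = as.vector(sigmoid(logit)), fused = fused, acts = acts)
}

model_backward <- function(model, fwd, y) {
  N <- length(y)
  T_steps <- length(fwd$acts[[1]]$hs)
  Hn <- model$config$hidden_dim
  # BCE + sigmoid: dL/dlogit = (p - y) / N
  dlogit <- matrix((fwd$p - y) / N, ncol = 1)
  grads <- list(fc = list(w = crossprod(fwd$fused, dlogit),
                          b = sum(dlogit)))
  dfused <- dlogit %*% t(model$fc$w)
  dh_ext <- vector("list", T_steps)
  if (model$config$fusion == "concat_all_steps") {
    for (t in seq_len(T_steps)) {
      dh_ext[[t]] <- dfused[, (t - 1L) * Hn + seq_len(Hn), drop = FALSE]
    }
  } else {
    dh_ext[[T_steps]] <- dfused
  }
  layer_grads <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    bw <- lstm_layer_backward(model$layers[[l]], fwd$acts[[l]]$cache, dh_ext,
                              need_dx = l > 1)
    layer_grads[[l]] <- bw[c("W", "U", "b")]
    if (l > 1) dh_ext <- bw$dx
  }
  grads$layers <- layer_grads
  grads
}

adam_state_like <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train the recurrent aggression classifier
#'
#' Minimises binary cross-entropy over labeled clip tensors with minibatch
#' Adam. Fully deterministic given `config$seed`: parameter initialisation
#' and epoch shuffling are both derived from it, so two runs with identical
#' inputs produce identical histories. The recorded training loss is the
#' epoch mean of minibatch losses; precision and recall are computed each
#' epoch on the validation set when one is given, otherwise on the training
#' set.
#'
#' @param clips A clip-set tibble with `tensor` (list of `T x input_dim`
#'   matrices) and `label` (0/1) columns, e.g. from [build_clip_set()].
#' @param config A [classifier_config()].
#' @param val_clips Optional clip-set tibble for per-epoch validation.
#' @param model Optional pre-built [build_classifier()] model to continue
#'   from; defaults to a fresh build from `config`.
#' @param reshuffle_each_epoch For heuristic-disabled (order-shuffled) clip
#'   sets built with `order = "shuffled"`: re-draw every frame's random
#'   packing order at each epoch, so the network cannot key on one
#'   arbitrary static arrangement. Requires tensors that carry their raw
#'   tuples (as [build_clip_tensor()] stores for shuffled packing).
#' @return A trained `flock_lstm` with a `history` tibble (one row per
#'   epoch: `epoch`, `train_loss`, `val_loss`, `precision`, `recall`).
#' @export
train_classifier <- function(clips, config = classifier_config(),
                             val_clips = NULL, model = NULL,
                             reshuffle_each_epoch = FALSE) {
  model <- model %||% build_classifier(config)
  config <- model$config
  y <- as.numeric(clips$label)
  if (anyNA(y)) rlang::abort("all training clips must be labeled.")
  if (length(unique(y)) < 2) {
    rlang::warn("single-class training set: the loss floor is not log(2).")
  }
  tensors <- clips$tensor
  T_steps <- nrow(tensors[[1]])
  model <- ensure_fc(model, T_steps)
  X <- stack_time_major(tensors, config$input_dim)
  n <- length(y)

  val_X <- NULL
  val_y <- NULL
  if (!is.null(val_clips)) {
    val_X <- stack_time_major(val_clips$tensor, config$input_dim)
    val_y <- as.numeric(val_clips$label)
  }

  shift_sd <- config$translate_sd
  ch <- channel_columns(config$input_dim)
  xcols <- ch$x
  ycols <- ch$y

  tuples_list <- NULL
  pack_cfg <- NULL
  if (reshuffle_each_epoch) {
    tuples_list <- lapply(tensors, attr, "tuples")
    if (any(vapply(tuples_list, is.null, TRUE))) {
      rlang::abort(paste0("`reshuffle_each_epoch = TRUE` needs clip tensors ",
                          "built with order = \"shuffled\" (they carry the raw tuples)."))
    }
    pack_cfg <- attr(tensors[[1]], "pack_config") %||% heuristic_config()
  }

  state <- list(layers = lapply(model$layers, adam_state_like),
                fc = adam_state_like(model$fc))
  step <- 0L
  history <- vector("list", config$epochs)
  set.seed(config$seed + 2L)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    if (!is.null(tuples_list)) {
      for (i in seq_len(n)) {
        for (t in seq_len(T_steps)) {
          X[[t]][i, ] <- suppressWarnings(
            pack_tuples_shuffled(tuples_list[[i]][[t]], pack_cfg))
        }
      }
    }
    if (shift_sd > 0 || config$scale_sd > 0 || config$dropout_tuples > 0 ||
        config$jitter_sd > 0) {
      # label-preserving detector/camera augmentations, re-drawn each epoch:
      # a per-clip pan translation and zoom of occupied tuples, random tuple
      # dropout (extra missed detections), and small coordinate jitter
      dx <- stats::rnorm(n, 0, shift_sd)
      dy <- stats::rnorm(n, 0, shift_sd)
      sc <- exp(stats::rnorm(n, 0, config$scale_sd))
      drop_mask <- NULL
      if (config$dropout_tuples > 0) {
        drop_mask <- lapply(seq_along(X), function(t) {
          matrix(stats::runif(n * length(xcols)) < config$dropout_tuples,
                 n, length(xcols))
        })
      }
      Xa <- lapply(seq_along(X), function(t) {
        m <- X[[t]]
        occ <- m[, xcols, drop = FALSE] != 0
        if (config$scale_sd > 0) {
          # zoom about the image center; sizes scale with coordinates
          mx <- m[, xcols, drop = FALSE]
          my <- m[, ycols, drop = FALSE]
          m[, xcols] <- pmin(pmax((0.5 + (mx - 0.5) * sc) * occ, 0), 1)
          m[, ycols] <- pmin(pmax((0.5 + (my - 0.5) * sc) * occ, 0), 1)
          m[, xcols + 2L] <- pmin(m[, xcols + 2L, drop = FALSE] * sc, 1)
          m[, ycols + 2L] <- pmin(m[, ycols + 2L, drop = FALSE] * sc, 1)
        }
        if (shift_sd > 0) {
          m[, xcols] <- pmin(pmax(m[, xcols, drop = FALSE] + dx * occ, 0), 1)
          m[, ycols] <- pmin(pmax(m[, ycols, drop = FALSE] + dy * occ, 0), 1)
        }
        if (config$jitter_sd > 0) {
          nz <- m != 0
          m <- pmin(pmax(m + matrix(stats::rnorm(length(m), 0, config$jitter_sd),
                                    nrow(m)) * nz, 0), 1)
        }
        if (!is.null(drop_mask)) {
          dm <- drop_mask[[t]] & occ
          for (k in 0:3) m[, xcols + k][dm] <- 0
        }
        m
      })
    } else {
      Xa <- X
    }
    batch_starts <- seq.int(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (bs in batch_starts) {
      rows <- ord[bs:min(bs + config$batch_size - 1L, n)]
      Xb <- lapply(Xa, function(m) m[rows, , drop = FALSE])
      yb <- y[rows]
      fwd <- model_forward(model, Xb, keep_cache = TRUE)
      epoch_loss <- epoch_loss + bce_loss(fwd$p, yb) * length(rows)
      grads <- model_backward(model, fwd, yb)
      step <- step + 1L
      for (l in seq_along(model$layers)) {
        for (nm in c("W", "U", "b")) {
          upd <- adam_step(model$layers[[l]][[nm]], grads$layers[[l]][[nm]],
                           state$layers[[l]][[nm]], config$learning_rate, step)
          model$layers[[l]][[nm]] <- upd$p
          state$layers[[l]][[nm]] <- upd$st
        }
      }
      for (nm in c("w", "b")) {
        upd <- adam_step(model$fc[[nm]], grads$fc[[nm]], state$fc[[nm]],
                         config$learning_rate, step)
        model$fc[[nm]] <- upd$p
        state$fc[[nm]] <- upd$st
      }
    }
    train_loss <- epoch_loss / n
    if (!is.null(val_X)) {
      val_p <- model_forward(model, val_X)$p
      val_loss <- bce_loss(val_p, val_y)
      eval_p <- val_p
      eval_y <- val_y
    } else {
      val_loss <- NA_real_
      eval_p <- model_forward(model, X)$p
      eval_y <- y
    }
    pred <- as.integer(eval_p >= config$decision_threshold)
    prf <- suppressWarnings(precision_recall_f1(confusion_counts(eval_y, pred)))
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss,
                                       precision = prf$precision,
                                       recall = prf$recall)
  }
  model$history <- dplyr::bind_rows(history)
  model$trained <- config$epochs > 0
  model
}

#' Predict aggression probabilities for clips
#'
#' One probability and 0/1 label per clip; `predicted = 1` iff the
#' probability is at or above the decision threshold. The output is
#' invariant to how clips are partitioned into batches.
#'
#' @param model A `flock_lstm` (trained or not).
#' @param clips A clip-set tibble with a `tensor` list-column (and
#'   optionally `clip_id`, `label`, carried through).
#' @param decision_threshold Overrides the model's threshold if given.
#' @return A tibble: `clip_id`, `label` (if present), `probability`,
#'   `predicted`.
#' @export
predict_clips <- function(model, clips, decision_threshold = NULL) {
  thr <- decision_threshold %||% model$config$decision_threshold
  tensors <- clips$tensor
  model <- ensure_fc(model, nrow(tensors[[1]]))
  X <- stack_time_major(tensors, model$config$input_dim)
  p <- model_forward(model, X)$p
  out <- tibble::tibble(
    clip_id = clips$clip_id %||% seq_along(tensors),
    probability = p,
    predicted = as.integer(p >= thr))
  if (!is.null(clips$label)) out$label <- clips$label
  out[ , c("clip_id", intersect("label", names(out)), "probability", "predicted")]
}

#' @export
print.flock_lstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<flock_lstm> %s | input %d, hidden %d, layers %d, fusion %s\n",
              if (x$trained) "trained" else "untrained",
              cfg$input_dim, cfg$hidden_dim, cfg$num_layers, cfg$fusion))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs | final train loss %.4f | P %.3f R %.3f\n",
                nrow(x$history), last$train_loss, last$precision, last$recall))
  }
  invisible(x)
}

#' Per-epoch training history of a fitted classifier
#'
#' @param x A `flock_lstm`.
#' @param ... Unused.
#' @return The history tibble (one row per epoch).
#' @method tidy flock_lstm
#' @export
tidy.flock_lstm <- function(x, ...) x$history

#' One-row summary of a fitted classifier
#'
#' @param x A `flock_lstm`.
#' @param ... Unused.
#' @return A one-row tibble with the architecture and final-epoch metrics.
#' @method glance flock_lstm
#' @export
glance.flock_lstm <- function(x, ...) {
  last <- if (nrow(x$history) > 0) x$history[nrow(x$history), ] else
    tibble::tibble(train_loss = NA_real_, val_loss = NA_real_,
                   precision = NA_real_, recall = NA_real_)
  tibble::tibble(hidden_dim = x$config$hidden_dim,
                 num_layers = x$config$num_layers,
                 fusion = x$config$fusion,
                 epochs = nrow(x$history),
                 train_loss = last$train_loss, val_loss = last$val_loss,
                 precision = last$precision, recall = last$recall)
}

#' Plot the training history of a fitted classifier
#'
#' Loss (training, and validation when available) and precision/recall
#' curves over epochs, with the log(2) uninformative-baseline level marked.
#'
#' @param object A trained `flock_lstm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flock_lstm
#' @export
autoplot.flock_lstm <- function(object, ...) {
  h <- object$history
  if (nrow(h) == 0) rlang::abort("the model has no training history yet.")
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric",
                              values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_hline(yintercept = log(2), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Save / load a classifier checkpoint
#'
#' A checkpoint is a single self-describing RDS archive holding the config,
#' all parameters and the training history; loading validates the expected
#' input dimension and clip length.
#'
#' @param model A `flock_lstm`.
#' @param path File path.
#' @return `write_classifier()` returns `path` invisibly;
#'   `read_classifier()` returns the model.
#' @export
write_classifier <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$config) || is.null(obj$layers)) {
    rlang::abort("not a classifier checkpoint.")
  }
  obj$config <- do.call(classifier_config, obj$config[names(formals(classifier_config))[
    names(formals(classifier_config)) %in% names(obj$config)]])
  structure(obj, class = "flock_lstm")
}
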
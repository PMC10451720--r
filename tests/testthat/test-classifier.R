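zeroed_model <- function(config, T_steps) {
  model <- build_classifier(config)
  model <- flockwatch:::ensure_fc(model, T_steps)
  model$layers <- lapply(model$layers, function(l) {
    list(W = l$W * 0, U = l$U * 0, b = l$b * 0)
  })
  model$fc$w <- model$fc$w * 0
  model$fc$b <- 0
  model
}

random_clip_set <- function(n, T_steps, input_dim, labels = NULL) {
  tibble::tibble(
    clip_id = seq_len(n),
    label = labels %||% rbinom(n, 1, 0.5),
    tensor = lapply(seq_len(n), function(i) {
      matrix(runif(T_steps * input_dim), T_steps, input_dim)
    }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a zero-weight model outputs probability 0.5 and label 1 at the >= threshold", {
  cfg <- classifier_config(input_dim = 20, hidden_dim = 8, seed = 1)
  model <- zeroed_model(cfg, T_steps = 4)
  set.seed(61)
  clips <- random_clip_set(5, 4, 20)
  out <- predict_clips(model, clips)
  expect_equal(out$probability, rep(0.5, 5))
  expect_equal(out$predicted, rep(1L, 5))
})

test_that("builds are bit-identical given the seed", {
  cfg <- classifier_config(input_dim = 30, hidden_dim = 16, seed = 99)
  m1 <- build_classifier(cfg)
  m2 <- build_classifier(cfg)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_classifier(classifier_config(input_dim = 30, hidden_dim = 16,
                                           seed = 100))
  expect_false(identical(m1$layers, m3$layers))
})

test_that("a hand-set one-unit LSTM matches the pencil-and-paper gate recurrences", {
  cfg <- classifier_config(input_dim = 1, hidden_dim = 1, seed = 1,
                           fusion = "last_step")
  model <- zeroed_model(cfg, T_steps = 2)
  wi <- 0.5; ui <- -0.3; bi <- 0.1
  wf <- -0.2; uf <- 0.4; bf <- 0.2
  wg <- 0.7; ug <- 0.1; bg <- -0.1
  wo <- 0.3; uo <- -0.5; bo <- 0.05
  # package gate layout: [input | forget | candidate | output]
  model$layers[[1]]$W <- matrix(c(wi, wf, wg, wo), 1, 4)
  model$layers[[1]]$U <- matrix(c(ui, uf, ug, uo), 1, 4)
  model$layers[[1]]$b <- c(bi, bf, bg, bo)
  model$fc$w <- matrix(2, 1, 1)
  model$fc$b <- -0.25

  x <- c(0.8, -0.4)
  s1 <- scalar_lstm_step(x[1], 0, 0, wi, ui, bi, wf, uf, bf, wg, ug, bg, wo, uo, bo)
  s2 <- scalar_lstm_step(x[2], s1$h, s1$c, wi, ui, bi, wf, uf, bf, wg, ug, bg,
                         wo, uo, bo)
  expected_p <- 1 / (1 + exp(-(2 * s2$h - 0.25)))

  clips <- tibble::tibble(clip_id = 1, label = 1L,
                          tensor = list(matrix(x, 2, 1)))
  out <- predict_clips(model, clips)
  expect_equal(out$probability, expected_p, tolerance = 1e-12)
})

test_that("concat fusion uses every step's hidden state in the head", {
  cfg <- classifier_config(input_dim = 2, hidden_dim = 1, seed = 3,
                           fusion = "concat_all_steps")
  model <- zeroed_model(cfg, T_steps = 3)
  # input + candidate gates react to x1 only; forget and output gates flat
  model$layers[[1]]$W <- cbind(c(1, 0), c(0, 0), c(1, 0), c(0, 0))
  model$layers[[1]]$b <- c(0, 0, 0, 2)                # output gate mostly open
  model$fc$w <- matrix(c(1, 1, 1), 3, 1)
  # manual forward
  sig <- function(z) 1 / (1 + exp(-z))
  h <- 0; cc <- 0; hs <- numeric(3)
  xs <- c(0.5, -0.2, 0.9)
  for (t in 1:3) {
    i <- sig(xs[t]); f <- sig(0); g <- tanh(xs[t]); o <- sig(2)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    hs[t] <- h
  }
  clips <- tibble::tibble(clip_id = 1, label = 0L,
                          tensor = list(cbind(xs, 0)))
  out <- predict_clips(model, clips)
  expect_equal(out$probability, sig(sum(hs)), tolerance = 1e-12)
})

test_that("bce_loss matches its closed form and an independent recomputation", {
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  set.seed(62)
  p <- runif(100)
  y <- rbinom(100, 1, 0.5)
  manual <- -mean(ifelse(y == 1, log(p), log(1 - p)))
  expect_equal(bce_loss(p, y), manual, tolerance = 1e-9)
  expect_error(bce_loss(c(0.5, 0.5), 1), "equal length")
})

test_that("training is deterministic given the seed and epochs = 0 is a no-op", {
  set.seed(63)
  clips <- random_clip_set(12, 3, 10, labels = rep(c(0L, 1L), 6))
  cfg <- classifier_config(input_dim = 10, hidden_dim = 4, epochs = 5,
                           batch_size = 4, seed = 7)
  m1 <- train_classifier(clips, cfg)
  m2 <- train_classifier(clips, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
  expect_equal(nrow(m1$history), 5)

  cfg0 <- classifier_config(input_dim = 10, hidden_dim = 4, epochs = 0, seed = 7)
  m0 <- train_classifier(clips, cfg0)
  expect_identical(m0$layers, build_classifier(cfg0)$layers)
  expect_equal(nrow(m0$history), 0)
  expect_false(m0$trained)
})

test_that("gradients match numerical finite differences on a tiny model", {
  cfg <- classifier_config(input_dim = 3, hidden_dim = 2, seed = 5,
                           fusion = "concat_all_steps")
  model <- build_classifier(cfg)
  model <- flockwatch:::ensure_fc(model, 4)
  set.seed(64)
  clips <- lapply(1:3, function(i) matrix(runif(12), 4, 3))
  y <- c(1, 0, 1)
  X <- flockwatch:::stack_time_major(clips, 3)
  fwd <- flockwatch:::model_forward(model, X, keep_cache = TRUE)
  grads <- flockwatch:::model_backward(model, fwd, y)
  loss_at <- function(m) {
    bce_loss(flockwatch:::model_forward(m, X)$p, y)
  }
  eps <- 1e-6
  check_entries <- list(
    list(path = c("layers", 1L, "W"), idx = c(2L, 3L)),
    list(path = c("layers", 1L, "U"), idx = c(1L, 5L)),
    list(path = c("layers", 1L, "b"), idx = 4L),
    list(path = c("fc", "w"), idx = c(3L, 1L)))
  for (ce in check_entries) {
    m_plus <- model; m_minus <- model
    if (ce$path[1] == "layers") {
      g <- grads$layers[[1L]][[ce$path[3]]]
      if (length(ce$idx) == 2) {
        m_plus$layers[[1]][[ce$path[3]]][ce$idx[1], ce$idx[2]] <-
          m_plus$layers[[1]][[ce$path[3]]][ce$idx[1], ce$idx[2]] + eps
        m_minus$layers[[1]][[ce$path[3]]][ce$idx[1], ce$idx[2]] <-
          m_minus$layers[[1]][[ce$path[3]]][ce$idx[1], ce$idx[2]] - eps
        analytic <- g[ce$idx[1], ce$idx[2]]
      } else {
        m_plus$layers[[1]][[ce$path[3]]][ce$idx] <-
          m_plus$layers[[1]][[ce$path[3]]][ce$idx] + eps
        m_minus$layers[[1]][[ce$path[3]]][ce$idx] <-
          m_minus$layers[[1]][[ce$path[3]]][ce$idx] - eps
        analytic <- g[ce$idx]
      }
    } else {
      m_plus$fc$w[ce$idx[1], ce$idx[2]] <- m_plus$fc$w[ce$idx[1], ce$idx[2]] + eps
      m_minus$fc$w[ce$idx[1], ce$idx[2]] <- m_minus$fc$w[ce$idx[1], ce$idx[2]] - eps
      analytic <- grads$fc$w[ce$idx[1], ce$idx[2]]
    }
    numeric_grad <- (loss_at(m_plus) - loss_at(m_minus)) / (2 * eps)
    expect_equal(analytic, numeric_grad, tolerance = 1e-5)
  }
})

test_that("prediction is deterministic and invariant to batch partitioning", {
  cfg <- classifier_config(input_dim = 8, hidden_dim = 4, epochs = 3,
                           batch_size = 4, seed = 11)
  set.seed(65)
  clips <- random_clip_set(10, 3, 8, labels = rep(c(0L, 1L), 5))
  model <- train_classifier(clips, cfg)
  all_at_once <- predict_clips(model, clips)
  expect_identical(predict_clips(model, clips), all_at_once)
  halves <- dplyr::bind_rows(predict_clips(model, clips[1:3, ]),
                             predict_clips(model, clips[4:10, ]))
  expect_equal(halves$probability, all_at_once$probability)
  # identical clip presented twice gets an identical probability
  dup <- clips[c(1, 1), ]
  pd <- predict_clips(model, dup)
  expect_equal(pd$probability[1], pd$probability[2])
})

test_that("clip length mismatches and wrong input dims are shape errors", {
  cfg <- classifier_config(input_dim = 8, hidden_dim = 4, epochs = 1, seed = 2)
  set.seed(66)
  clips <- random_clip_set(4, 3, 8, labels = c(0L, 1L, 0L, 1L))
  model <- train_classifier(clips, cfg)
  bad_t <- random_clip_set(2, 5, 8)
  expect_error(predict_clips(model, bad_t), "clips of 3 frames|share")
  bad_d <- random_clip_set(2, 3, 9)
  expect_error(predict_clips(model, bad_d), "8")
})

test_that("a single-class training set warns and multi-layer models still learn shapes", {
  set.seed(67)
  clips <- random_clip_set(6, 3, 10, labels = rep(1L, 6))
  cfg <- classifier_config(input_dim = 10, hidden_dim = 4, epochs = 1, seed = 3)
  expect_warning(train_classifier(clips, cfg), "single-class")

  cfg2 <- classifier_config(input_dim = 10, hidden_dim = 4, num_layers = 2,
                            epochs = 2, batch_size = 4, seed = 4)
  mixed <- random_clip_set(8, 3, 10, labels = rep(c(0L, 1L), 4))
  m <- train_classifier(mixed, cfg2)
  expect_equal(nrow(m$history), 2)
  expect_length(m$layers, 2)
  out <- predict_clips(m, mixed)
  expect_true(all(out$probability > 0 & out$probability < 1))
})

test_that("checkpoints round-trip through disk", {
  cfg <- classifier_config(input_dim = 8, hidden_dim = 4, epochs = 2,
                           batch_size = 4, seed = 13)
  set.seed(68)
  clips <- random_clip_set(6, 3, 8, labels = rep(c(0L, 1L), 3))
  model <- train_classifier(clips, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  write_classifier(model, path)
  back <- read_classifier(path)
  expect_equal(back$layers, model$layers)
  expect_equal(predict_clips(back, clips)$probability,
               predict_clips(model, clips)$probability)
})

test_that("training separates a small linearly separable synthetic set", {
  clips <- build_clip_set(toy_clip_set(15, seed = 70))
  cfg <- classifier_config(hidden_dim = 32, epochs = 50, batch_size = 10,
                           seed = 71)
  model <- train_classifier(clips, cfg)
  preds <- predict_clips(model, clips)
  acc <- mean(preds$predicted == clips$label)
  expect_gte(acc, 0.95)
})
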
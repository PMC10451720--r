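test_that("a noiseless frozen flock repeats the same frame 25 times", {
  cfg <- scenario_config(n_animals = 10, behavior = "calm", calm_step_sd = 0,
                         miss_rate = 0, false_positive_rate = 0,
                         center_jitter_sd = 0, box_jitter_frac = 0, seed = 5)
  clip <- simulate_clip(cfg)
  expect_equal(frames_of(clip), 0:24)
  det <- tibble::as_tibble(clip)
  first <- det[det$frame == 0, c("cx", "cy", "w", "h", "conf")]
  for (f in 1:24) {
    expect_equal(det[det$frame == f, c("cx", "cy", "w", "h", "conf")], first)
  }
})

test_that("the same config and seed reproduce the identical stream", {
  cfg <- scenario_config(n_animals = 25, behavior = "aggressive", seed = 17)
  c1 <- simulate_clip(cfg)
  c2 <- simulate_clip(cfg)
  expect_identical(tibble::as_tibble(c1), tibble::as_tibble(c2))
  c3 <- simulate_clip(scenario_config(n_animals = 25, behavior = "aggressive",
                                      seed = 18))
  expect_false(identical(tibble::as_tibble(c1), tibble::as_tibble(c3)))
})

test_that("the bout pair moves far more than the 99th percentile of calm animals", {
  # true displacements, noise off so detection artifacts cannot mask motion
  cfg <- scenario_config(n_animals = 40, behavior = "aggressive",
                         miss_rate = 0, false_positive_rate = 0,
                         center_jitter_sd = 0, seed = 23)
  clip <- simulate_clip(cfg)
  det <- tibble::as_tibble(clip)
  det$animal <- rep(seq_len(40), 25)  # stable emission order when nothing is dropped
  steps <- det |>
    dplyr::arrange(animal, frame) |>
    dplyr::group_by(animal) |>
    dplyr::summarise(max_step = max(sqrt(diff(cx)^2 + diff(cy)^2)),
                     .groups = "drop")
  top2 <- sort(steps$max_step, decreasing = TRUE)[1:2]
  calm_steps <- sort(steps$max_step, decreasing = TRUE)[-(1:2)]
  expect_gt(min(top2), quantile(calm_steps, 0.99))
  expect_gt(min(top2), 15)  # charge speed 40 px/frame split over the pair
})

test_that("labels follow behavior: aggressive = 1, calm and courtship = 0", {
  expect_equal(label_of(simulate_clip(scenario_config(behavior = "aggressive",
                                                      seed = 1))), 1L)
  expect_equal(label_of(simulate_clip(scenario_config(behavior = "calm",
                                                      seed = 1))), 0L)
  expect_equal(label_of(simulate_clip(scenario_config(behavior = "courtship",
                                                      seed = 1))), 0L)
})

test_that("emitted confidence is nonincreasing across distance-to-center bins", {
  cfg <- scenario_config(n_animals = 60, behavior = "calm", seed = 29,
                         false_positive_rate = 0)
  det <- tibble::as_tibble(simulate_clip(cfg))
  g <- frame_geometry()
  det$dist <- sqrt((det$cx - g$width / 2)^2 + (det$cy - g$height / 2)^2)
  det$bin <- cut(det$dist, breaks = seq(0, 1500, by = 300))
  mean_conf <- tapply(det$conf, det$bin, mean)
  mean_conf <- mean_conf[!is.na(mean_conf)]
  expect_true(all(diff(mean_conf) <= 0))
})

test_that("make_dataset returns balanced, reproducible, seed-disjoint splits", {
  ds <- make_dataset(10, 5, seed = 31)
  expect_equal(nrow(ds$train), 20)
  expect_equal(nrow(ds$test), 10)
  expect_equal(sum(ds$train$label), 10)
  expect_equal(sum(ds$test$label), 5)
  expect_false(any(ds$train$seed %in% ds$test$seed))

  ds2 <- make_dataset(10, 5, seed = 31)
  expect_identical(ds$train$seed, ds2$train$seed)
  expect_identical(tibble::as_tibble(ds$train$detections[[3]]),
                   tibble::as_tibble(ds2$train$detections[[3]]))

  # every clip reproducible from its recorded seed and parameters
  row <- ds$test[4, ]
  redo <- simulate_clip(scenario_config(behavior = row$behavior,
                                        n_animals = row$n_animals,
                                        seed = row$seed))
  expect_identical(tibble::as_tibble(redo),
                   tibble::as_tibble(row$detections[[1]]))
  expect_true(all(ds$train$n_animals >= 10 & ds$train$n_animals <= 70))
})

test_that("courtship confounders appear only on request and stay labeled 0", {
  ds <- make_dataset(6, 3, seed = 37, include_courtship = TRUE)
  expect_true("courtship" %in% ds$train$behavior)
  expect_true(all(ds$train$label[ds$train$behavior == "courtship"] == 0L))
  ds_plain <- make_dataset(6, 3, seed = 37)
  expect_false("courtship" %in% ds_plain$behavior)
})

test_that("class separation in the packed tensors shrinks as the charge speed approaches calm motion", {
  # Separability is scored by a classifier-free slot statistic: the best
  # per-slot rate of moderate-band temporal deltas (a sustained oscillation
  # at charge amplitude), summarised as the AUC over a labeled clip set.
  slot_stat <- function(m) {
    dm <- abs(diff(unclass(m)))
    max(colMeans(dm > 0.008 & dm < 0.045))
  }
  aucs <- vapply(c(40, 15, 3.01), function(speed) {
    clips <- build_clip_set(toy_clip_set(40, seed = 41, n_animals = 30,
                                         aggressive_pair_speed = speed))
    roc_auc(clips$label, vapply(clips$tensor, slot_stat, 0))$auc
  }, 0)
  expect_true(all(diff(aucs) < 0))   # monotone decay toward chance
  expect_gte(aucs[1], 0.85)          # full charge speed: clearly separable
  expect_lte(aucs[3], 0.70)          # speed ~ calm sd: approaching 0.5
})

test_that("the default dataset's packed tensors separate classes out of sample", {
  ds <- make_dataset(60, 30, seed = 43)
  slot_stat <- function(m) {
    dm <- abs(diff(unclass(m)))
    max(colMeans(dm > 0.008 & dm < 0.045))
  }
  test_clips <- build_clip_set(ds$test)
  auc <- roc_auc(test_clips$label,
                 vapply(test_clips$tensor, slot_stat, 0))$auc
  expect_gte(auc, 0.8)
})
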
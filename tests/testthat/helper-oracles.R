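# Fixture builders and independent brute-force oracles. The oracles share no
# code with the package internals: plain loops and first-principles formulas.

random_detections <- function(n, geometry = frame_geometry(), frame = 0L,
                              conf_range = c(0, 1)) {
  tibble::tibble(
    frame = as.integer(frame),
    cls = "sheep",
    cx = runif(n, 0, geometry$width),
    cy = runif(n, 0, geometry$height),
    w = runif(n, 10, 300),
    h = runif(n, 10, 300),
    conf = runif(n, conf_range[1], conf_range[2]))
}

# Brute-force packing: explicit loops, selection sort over all pairwise
# distance comparisons, no shared helpers with pack_frame().
brute_pack <- function(det, geometry, config) {
  dims <- config$dims_per_quadrant
  out <- numeric(4 * dims)
  keep <- det[det$conf >= config$conf_threshold, , drop = FALSE]
  if (nrow(keep) == 0) return(out)
  u <- keep$cx - geometry$width / 2
  v <- keep$cy - geometry$height / 2
  quad <- integer(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    quad[i] <- if (u[i] >= 0 && v[i] < 0) 1L else if (u[i] < 0 && v[i] < 0) 2L
      else if (u[i] < 0 && v[i] >= 0) 3L else 4L
  }
  d <- sqrt(u^2 + v^2)
  capacity <- dims %/% 4
  for (q in 1:4) {
    members <- which(quad == q)
    # selection sort by (distance, cx, cy)
    sorted <- integer(0)
    pool <- members
    while (length(pool) > 0) {
      best <- pool[1]
      for (j in pool[-1]) {
        if (d[j] < d[best] ||
            (d[j] == d[best] && keep$cx[j] < keep$cx[best]) ||
            (d[j] == d[best] && keep$cx[j] == keep$cx[best] &&
             keep$cy[j] < keep$cy[best])) {
          best <- j
        }
      }
      sorted <- c(sorted, best)
      pool <- setdiff(pool, best)
    }
    if (length(sorted) > capacity) sorted <- sorted[1:capacity]
    pos <- (q - 1) * dims
    for (j in sorted) {
      out[pos + 1] <- keep$cx[j] / geometry$width
      out[pos + 2] <- keep$cy[j] / geometry$height
      out[pos + 3] <- keep$w[j] / geometry$width
      out[pos + 4] <- keep$h[j] / geometry$height
      pos <- pos + 4
    }
  }
  out
}

# Mann-Whitney AUC: mean over all (positive, negative) pairs with half
# credit for ties.
brute_auc <- function(truth, prob) {
  pos <- prob[truth == 1]
  neg <- prob[truth == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Pencil-and-paper LSTM cell (scalar, one unit): standard gate recurrences.
scalar_lstm_step <- function(x, h_prev, c_prev, wi, ui, bi, wf, uf, bf,
                             wg, ug, bg, wo, uo, bo) {
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(wi * x + ui * h_prev + bi)
  f <- sig(wf * x + uf * h_prev + bf)
  g <- tanh(wg * x + ug * h_prev + bg)
  o <- sig(wo * x + uo * h_prev + bo)
  c_new <- f * c_prev + i * g
  list(h = o * tanh(c_new), c = c_new)
}

# A tiny, cleanly separable two-class clip set for fast training tests:
# class 1 has an oscillating pair, class 0 is nearly static.
toy_clip_set <- function(n_per_class, seed, n_animals = 12,
                         aggressive_pair_speed = 40, calm_step_sd = 3) {
  set.seed(seed)
  seeds <- sample.int(1e6, 2 * n_per_class)
  behavior <- rep(c("aggressive", "calm"), n_per_class)
  clips <- tibble::tibble(
    clip_id = seq_along(behavior),
    behavior = behavior,
    seed = seeds)
  clips$detections <- purrr::map2(clips$behavior, clips$seed, function(b, s) {
    simulate_clip(scenario_config(behavior = b, n_animals = n_animals,
                                  aggressive_pair_speed = aggressive_pair_speed,
                                  calm_step_sd = calm_step_sd, seed = s))
  })
  clips$label <- purrr::map_int(clips$detections, label_of)
  clips
}
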
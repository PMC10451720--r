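#' Scenario configuration for the synthetic flock simulator
#'
#' The simulator emulates the statistical signature of pen surveillance
#' video as seen by an object detector: a fixed pen viewed by one camera,
#' 10-70 sheep, calm milling motion with small per-frame displacements
#' versus an aggressive pair with strong locomotor bursts, detector
#' confidence that decays with distance from the image center, missed
#' detections (more frequent far from the center) and spurious boxes. It
#' produces detection streams, not images.
#'
#' Behaviors: `calm` — every animal performs an independent bounded random
#' walk (reflecting at the pen borders). `aggressive` — one randomly chosen
#' pair additionally approaches and then executes repeated charge-recoil
#' cycles (large alternating displacements along the line joining the two),
#' while the rest stay calm. `courtship` — a confounder in which one animal
#' chases another at sustained speed without recoil; it is labeled
#' non-aggressive and is off by default in datasets.
#'
#' @param geometry A [frame_geometry()] (default 2560 x 1440 @ 25 fps).
#' @param n_animals Number of sheep in the pen (2-150).
#' @param behavior `"calm"`, `"aggressive"` or `"courtship"`.
#' @param calm_step_sd Per-axis, per-frame displacement SD of calm motion,
#'   in pixels (default 3).
#' @param aggressive_pair_speed Relative speed of the bout pair during a
#'   charge, pixels per frame (default 40).
#' @param charge_recoil_period Frames per full charge-recoil cycle
#'   (default 8).
#' @param bout_seconds Clip duration in seconds (default 1, the minimum
#'   observed bout length).
#' @param box_size_mean,box_size_sd Mean and SD of the per-animal box width
#'   in pixels (height is drawn around 0.7 of the width).
#' @param conf_base Detector confidence for a box at the image center.
#' @param conf_distance_decay Confidence lost per pixel of distance from the
#'   image center (default 2e-4: about 0.3 at the far corner).
#' @param center_jitter_sd Detection box-center jitter SD in pixels.
#' @param box_jitter_frac Per-frame multiplicative jitter SD on detected box
#'   width/height (detector boxes breathe frame to frame; default 0.04).
#' @param miss_rate Base missed-detection probability at the image center;
#'   it doubles linearly towards the far corner.
#' @param false_positive_rate Expected number of spurious boxes per frame.
#' @param seed Integer seed; the simulation is deterministic given the
#'   config.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(geometry = frame_geometry(), n_animals = 30L,
                            behavior = c("calm", "aggressive", "courtship"),
                            calm_step_sd = 3, aggressive_pair_speed = 40,
                            charge_recoil_period = 8L, bout_seconds = 1,
                            box_size_mean = 140, box_size_sd = 15,
                            conf_base = 0.92, conf_distance_decay = 2e-4,
                            center_jitter_sd = 2, box_jitter_frac = 0.04,
                            miss_rate = 0.03,
                            false_positive_rate = 0.05, seed = 1L) {
  assert_geometry(geometry)
  behavior <- match.arg(behavior)
  n_animals <- as.integer(n_animals)
  if (n_animals < 1L || n_animals > 150L) {
    rlang::abort("`n_animals` must be in [1, 150].")
  }
  if (behavior %in% c("aggressive", "courtship") && n_animals < 2L) {
    rlang::abort(sprintf("behavior '%s' needs at least 2 animals.", behavior))
  }
  rates <- c(miss_rate = miss_rate, false_positive_rate = false_positive_rate,
             conf_base = conf_base)
  if (any(rates < 0 | rates > 1)) {
    rlang::abort("`miss_rate`, `false_positive_rate` and `conf_base` must lie in [0, 1].")
  }
  if (calm_step_sd < 0 || center_jitter_sd < 0 || box_size_sd < 0 ||
      box_jitter_frac < 0) {
    rlang::abort("standard deviations must be >= 0.")
  }
  if (aggressive_pair_speed <= 0 || charge_recoil_period <= 0 ||
      bout_seconds <= 0 || box_size_mean <= 0 || conf_distance_decay < 0) {
    rlang::abort("speeds, periods, durations and sizes must be positive.")
  }
  structure(list(geometry = geometry, n_animals = n_animals,
                 behavior = behavior, calm_step_sd = calm_step_sd,
                 aggressive_pair_speed = aggressive_pair_speed,
                 charge_recoil_period = as.integer(charge_recoil_period),
                 bout_seconds = bout_seconds,
                 box_size_mean = box_size_mean, box_size_sd = box_size_sd,
                 conf_base = conf_base,
                 conf_distance_decay = conf_distance_decay,
                 center_jitter_sd = center_jitter_sd,
                 box_jitter_frac = box_jitter_frac,
                 miss_rate = miss_rate,
                 false_positive_rate = false_positive_rate,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

reflect_into <- function(x, lo, hi) {
  # reflect a coordinate back into [lo, hi] (pen borders are walls)
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

#' Simulate one labeled detection clip
#'
#' Generates true animal trajectories for `bout_seconds` of video according
#' to the scenario's behavior, then derives detections from them: box
#' centers with Gaussian jitter, confidence decaying with distance from the
#' image center, distance-dependent missed detections, and spurious boxes.
#' Deterministic given the config (including its seed). The returned stream
#' carries label 1 for `aggressive`, else 0.
#'
#' @param config A [scenario_config()].
#' @return A [video_detections()] stream with a 0/1 `label` attribute.
#' @export
simulate_clip <- function(config) {
  if (!inherits(config, "scenario_config")) {
    rlang::abort("`config` must be created with `scenario_config()`.")
  }
  g <- config$geometry
  set.seed(config$seed)
  n_frames <- as.integer(round(g$fps * config$bout_seconds))
  n <- config$n_animals
  margin <- config$box_size_mean / 2
  px <- stats::runif(n, margin, g$width - margin)
  py <- stats::runif(n, margin, g$height - margin)
  bw <- pmax(20, stats::rnorm(n, config$box_size_mean, config$box_size_sd))
  bh <- pmax(14, 0.7 * bw + stats::rnorm(n, 0, config$box_size_sd / 2))

  pair <- if (config$behavior %in% c("aggressive", "courtship")) {
    sample.int(n, 2L)
  } else integer(0)
  contact_dist <- 1.2 * config$box_size_mean
  if (config$behavior == "aggressive" && length(pair) == 2) {
    # an aggression clip starts at the violent behavior: the bout pair is
    # already engaged, so charge-recoil cycles fill the whole second
    angle <- stats::runif(1, 0, 2 * pi)
    d0 <- stats::runif(1, 0.8, 1.2) * contact_dist
    px[pair[2]] <- reflect_into(px[pair[1]] + d0 * cos(angle), margin,
                                g$width - margin)
    py[pair[2]] <- reflect_into(py[pair[1]] + d0 * sin(angle), margin,
                                g$height - margin)
  }
  if (config$behavior == "courtship" && length(pair) == 2) {
    # start the chase from a distance so it does not collapse immediately
    px[pair[2]] <- reflect_into(px[pair[1]] + g$width / 3, margin, g$width - margin)
  }
  half_period <- max(1L, config$charge_recoil_period %/% 2L)

  # Detection failures are temporally persistent: an occluded or distant
  # sheep stays missed for a run of frames, and a spurious (ghost) box
  # lingers where the detector keeps hallucinating it. Misses follow a
  # sticky two-state process with the distance-dependent rate as its
  # stationary distribution; ghosts are short tracks at fixed positions.
  miss_persist <- 0.8
  miss_state <- rep(FALSE, n)
  ghost_runs <- 8
  n_ghosts <- stats::rpois(1, config$false_positive_rate * n_frames / ghost_runs)
  ghosts <- if (n_ghosts > 0) {
    tibble::tibble(
      gx = stats::runif(n_ghosts, 0, g$width),
      gy = stats::runif(n_ghosts, 0, g$height),
      gw = stats::runif(n_ghosts, 30, config$box_size_mean),
      gh = stats::runif(n_ghosts, 20, 0.7 * config$box_size_mean),
      gconf = stats::runif(n_ghosts, 0.3, 0.9),
      start = sample.int(n_frames, n_ghosts, replace = TRUE),
      dur = 1L + stats::rgeom(n_ghosts, 1 / ghost_runs))
  } else NULL

  frames_list <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    # calm random-walk step for everyone
    px <- px + stats::rnorm(n, 0, config$calm_step_sd)
    py <- py + stats::rnorm(n, 0, config$calm_step_sd)
    if (length(pair) == 2) {
      a <- pair[1]; b <- pair[2]
      dx <- px[b] - px[a]; dy <- py[b] - py[a]
      d <- sqrt(dx^2 + dy^2)
      ux <- if (d > 0) dx / d else 1
      uy <- if (d > 0) dy / d else 0
      v <- config$aggressive_pair_speed / 2
      if (config$behavior == "aggressive") {
        if (d > contact_dist) {
          dir <- 1  # approach
        } else {
          # alternate charge (towards) and recoil (away) every half period
          dir <- if (((t - 1L) %/% half_period) %% 2L == 0L) 1 else -1
        }
        px[a] <- px[a] + dir * v * ux; py[a] <- py[a] + dir * v * uy
        px[b] <- px[b] - dir * v * ux; py[b] <- py[b] - dir * v * uy
      } else {
        # courtship: b flees, a chases at sustained speed, no recoil
        px[a] <- px[a] + 2 * v * ux; py[a] <- py[a] + 2 * v * uy
        px[b] <- px[b] + 2 * v * ux; py[b] <- py[b] + 2 * v * uy
      }
    }
    px <- reflect_into(px, margin, g$width - margin)
    py <- reflect_into(py, margin, g$height - margin)

    cx <- px + stats::rnorm(n, 0, config$center_jitter_sd)
    cy <- py + stats::rnorm(n, 0, config$center_jitter_sd)
    wd <- pmax(10, bw * (1 + stats::rnorm(n, 0, config$box_jitter_frac)))
    hd <- pmax(8, bh * (1 + stats::rnorm(n, 0, config$box_jitter_frac)))
    cx <- pmin(pmax(cx, 0), g$width)
    cy <- pmin(pmax(cy, 0), g$height)
    dist_c <- sqrt((cx - g$width / 2)^2 + (cy - g$height / 2)^2)
    max_dist <- sqrt((g$width / 2)^2 + (g$height / 2)^2)
    conf <- pmin(pmax(config$conf_base - config$conf_distance_decay * dist_c,
                      0.01), 0.99)
    p_miss <- pmin(config$miss_rate * (1 + dist_c / max_dist), 1)
    fresh <- stats::runif(n) < p_miss
    sticky <- stats::runif(n) < miss_persist
    miss_state <- ifelse(sticky & t > 1L, miss_state, fresh)
    kept <- !miss_state
    det <- tibble::tibble(frame = t - 1L, cls = "sheep",
                          cx = cx[kept], cy = cy[kept],
                          w = wd[kept], h = hd[kept], conf = conf[kept])
    if (!is.null(ghosts)) {
      live <- ghosts$start <= t & t < ghosts$start + ghosts$dur
      if (any(live)) {
        det <- dplyr::bind_rows(det, tibble::tibble(
          frame = t - 1L, cls = "sheep",
          cx = ghosts$gx[live], cy = ghosts$gy[live],
          w = ghosts$gw[live], h = ghosts$gh[live],
          conf = ghosts$gconf[live]))
      }
    }
    frames_list[[t]] <- det
  }
  det <- dplyr::bind_rows(frames_list)
  video_detections(det, g, frames = 0:(n_frames - 1L),
                   label = as.integer(config$behavior == "aggressive"))
}

#' Default per-clip parameter ranges for dataset generation
#'
#' Each clip of a dataset draws its flock size uniformly from
#' `n_animals` (10-70 sheep, the range observed in pen surveillance).
#' Other scenario parameters are held at their [scenario_config()] defaults
#' unless overridden here.
#'
#' @param n_animals Integer range `c(min, max)` for the flock size.
#' @param ... Named scalar overrides passed to every clip's
#'   [scenario_config()].
#' @return A list of ranges/overrides for [make_dataset()].
#' @export
scenario_ranges <- function(n_animals = c(10L, 70L), ...) {
  list(n_animals = as.integer(n_animals), overrides = list(...))
}

#' Generate balanced labeled train/test clip sets
#'
#' Draws per-clip scenarios (flock size uniform over the configured range,
#' behavior alternating between aggressive and calm) with per-clip seeds
#' taken from disjoint streams derived from the master seed, simulates each
#' clip, and returns train and test manifests with the detection streams as
#' a list-column. Every clip is reproducible from its recorded seed and
#' parameters.
#'
#' @param n_per_class_train Clips per class in the training set.
#' @param n_per_class_test Clips per class in the test set.
#' @param config_ranges A [scenario_ranges()] list.
#' @param seed Master seed.
#' @param include_courtship If `TRUE`, one third of the non-aggressive clips
#'   are courtship confounders (labeled 0). Off by default.
#' @return A list with `train` and `test` tibbles: `clip_id`, `label`,
#'   `behavior`, `n_animals`, `seed`, `detections` (list-column of
#'   [video_detections()]).
#' @export
make_dataset <- function(n_per_class_train, n_per_class_test,
                         config_ranges = scenario_ranges(), seed = 1L,
                         include_courtship = FALSE) {
  if (n_per_class_train <= 0 || n_per_class_test <= 0) {
    rlang::abort("clip counts must be positive.")
  }
  set.seed(seed)
  make_split <- function(n_per_class, prefix) {
    n_clips <- 2L * n_per_class
    clip_seeds <- sample.int(.Machine$integer.max - 1L, n_clips)
    n_animals <- sample(seq(config_ranges$n_animals[1],
                            config_ranges$n_animals[2]),
                        n_clips, replace = TRUE)
    behavior <- rep(c("aggressive", "calm"), n_per_class)
    if (include_courtship) {
      calm_idx <- which(behavior == "calm")
      n_court <- length(calm_idx) %/% 3L
      if (n_court > 0) behavior[calm_idx[seq_len(n_court)]] <- "courtship"
    }
    manifest <- tibble::tibble(
      clip_id = sprintf("%s_%04d", prefix, seq_len(n_clips)),
      behavior = behavior, n_animals = n_animals, seed = clip_seeds)
    manifest$detections <- purrr::pmap(
      manifest[c("behavior", "n_animals", "seed")],
      function(behavior, n_animals, seed) {
        cfg <- do.call(scenario_config,
                       c(list(behavior = behavior, n_animals = n_animals,
                              seed = seed),
                         config_ranges$overrides))
        simulate_clip(cfg)
      })
    manifest$label <- purrr::map_int(manifest$detections, label_of)
    manifest[c("clip_id", "label", "behavior", "n_animals", "seed", "detections")]
  }
  train <- make_split(n_per_class_train, "train")
  test <- make_split(n_per_class_test, "test")
  list(train = train, test = test)
}

#' Plot a detection stream
#'
#' Box centers over time, colored by frame, sized by confidence — a quick
#' visual check of a simulated or parsed clip.
#'
#' @param object A [video_detections()] stream.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot video_detections
#' @export
autoplot.video_detections <- function(object, ...) {
  g <- geometry_of(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$cx, y = .data$cy,
                               colour = .data$frame, size = .data$conf)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_reverse(limits = c(g$height, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, g$width)) +
    ggplot2::scale_size_continuous(range = c(0.5, 2)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "frame",
                  size = "conf") +
    ggplot2::theme_minimal()
}
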
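#' The 79-feature registry
#'
#' Ordered registry of every feature extracted from an assessment session,
#' across five categories: mouse movement, mouse click, keyboard, memory
#' and demographic. The mouse/keyboard block is a systematic grid (the
#' same statistics across the three tracing paths and the three key
#' tasks); names quoted in published feature-importance tables are kept
#' verbatim in lower-snake-case, which is why the article usage varies
#' between paths (`time_to_trace_a_spiral` vs
#' `time_to_trace_the_spiral_normalized`).
#'
#' @return A `data.frame` with columns `name`, `category`, `unit`,
#'   79 rows in extraction order.
#' @export
feature_registry <- function() {
  paths <- c(straight = "straight_line", sine = "sine_wave", spiral = "spiral")
  time_raw <- c(straight = "time_to_trace_a_straight_line",
                sine = "time_to_trace_the_sine_wave",
                spiral = "time_to_trace_a_spiral")
  time_norm <- c(straight = "time_to_trace_a_straight_line_normalized",
                 sine = "time_to_trace_the_sine_wave_normalized",
                 spiral = "time_to_trace_the_spiral_normalized")
  rows <- list()
  add <- function(name, category, unit)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, category = category,
                                             unit = unit)
  for (k in names(paths)) {
    p <- paths[[k]]
    add(paste0("total_deviation_", p), "mouse_movement", "percent_screen_height")
    add(paste0("net_deviation_", p), "mouse_movement", "percent_screen_height")
    add(paste0("maximum_deviation_", p), "mouse_movement", "percent_screen_height")
    add(paste0("average_absolute_deviation_", p), "mouse_movement",
        "percent_screen_height")
    add(paste0("mean_deviation_", p), "mouse_movement", "fraction_screen_height")
    add(paste0("maximum_pixel_deviation_", p), "mouse_movement", "pixels")
    add(paste0("deviation_sd_", p), "mouse_movement", "pixels")
    add(time_raw[[k]], "mouse_movement", "seconds")
    add(time_norm[[k]], "mouse_movement", "seconds_per_pixel")
    add(paste0("points_inside_", p), "mouse_movement", "count")
    add(paste0("mean_speed_", p), "mouse_movement", "pixels_per_second")
    add(paste0("max_speed_", p), "mouse_movement", "pixels_per_second")
    add(paste0("speed_sd_", p), "mouse_movement", "pixels_per_second")
    add(paste0("path_length_", p), "mouse_movement", "pixels")
    add(paste0("mean_abs_acceleration_", p), "mouse_movement",
        "pixels_per_second_squared")
    add(paste0("direction_changes_", p), "mouse_movement", "count")
  }
  add("average_tracing_time_for_all_tasks", "mouse_movement", "seconds")
  add("average_points_inside_all_lines", "mouse_movement", "count")

  add("total_click_time_for_all_tests", "mouse_click", "seconds")
  add("total_click_reaction_time", "mouse_click", "seconds")
  add("click_hit_rate", "mouse_click", "ratio")
  add("average_click_time", "mouse_click", "seconds")
  add("click_distance_error_mean", "mouse_click", "pixels")
  add("click_time_sd", "mouse_click", "seconds")

  rate_names <- c(constant_key = "correct_the_press_rate_constant_key",
                  two_letter_key = "correct_press_rate_two_letter_key",
                  random_key = "correct_press_rate_random_key")
  for (k in c("constant_key", "two_letter_key", "random_key")) {
    add(paste0("average_response_time_", k), "keyboard", "seconds")
    add(paste0("response_time_sd_", k), "keyboard", "seconds")
    add(paste0("correct_press_count_", k), "keyboard", "count")
    add(paste0("false_press_ratio_", k), "keyboard", "ratio")
    add(rate_names[[k]], "keyboard", "presses_per_second")
  }
  add("average_false_presses_all_tests", "keyboard", "count")
  add("average_response_time_all_tests", "keyboard", "seconds")

  add("memory_max_sequence_length", "memory", "count")
  add("memory_incorrect_trials", "memory", "count")

  add("sex", "demographic", "categorical")
  add("race_binary", "demographic", "categorical")
  add("device", "demographic", "categorical")
  add("hand", "demographic", "categorical")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the feature registry as a versioned CSV
#'
#' @param path Output path; defaults to the package's shipped copy name.
#' @return `path`, invisibly.
#' @export
write_feature_registry <- function(path = "feature_registry_v1.csv") {
  utils::write.csv(feature_registry(), path, row.names = FALSE)
  invisible(path)
}

#' Signed deviations of a trace from its centerline
#'
#' For straight and sine paths the deviation of sample i is
#' `y_i - centerline_y(x_i)` (positive = below the line in screen
#' coordinates); for the spiral it is the radial distance of the sample
#' minus the centerline radius at the matched angle. Samples outside the
#' path's x-domain are excluded and counted, not failed.
#'
#' @param trace A `motorfair_trace`.
#' @return A list with `d` (signed offsets, px), `screen_height`,
#'   `window_width` and `n_excluded`.
#' @export
signed_deviations <- function(trace) {
  p <- trace$centerline_params
  s <- trace$samples
  if (p$path_kind == "spiral") {
    r <- sqrt((s$x - p$cx)^2 + (s$y - p$cy)^2)
    theta <- if (!is.null(s$theta)) s$theta else {
      raw <- atan2(s$y - p$cy, s$x - p$cx)
      # unwrap so the angle increases monotonically along the spiral
      cumsum(c(raw[1], (diff(raw) + pi) %% (2 * pi) - pi))
    }
    d <- r - centerline_eval(p, theta)
    excl <- 0L
  } else {
    inside <- s$x >= min(p$x0, p$x1) & s$x <= max(p$x0, p$x1)
    d <- s$y[inside] - centerline_eval(p, s$x[inside])
    excl <- sum(!inside)
  }
  list(d = as.numeric(d), screen_height = p$window_height,
       window_width = p$window_width, n_excluded = excl)
}

#' Deviation summary features for one deviation series
#'
#' All percentage features are relative to the screen height H:
#' total = sum(|d|)/H x 100; net = |sum(d)|/H x 100; max = max(|d|)/H x
#' 100; average absolute = mean(|d|)/H x 100; mean is the signed fraction
#' mean(d)/H (not a percentage); maximum pixel deviation is max(|d|) in
#' raw pixels.
#'
#' @param dev A deviation series from [signed_deviations()].
#' @return Named list of `total`, `net`, `max`, `avg_abs`, `mean`,
#'   `max_pixel`; all `NA` for an empty series.
#' @export
deviation_features <- function(dev) {
  d <- dev$d
  if (length(d) == 0)
    return(list(total = NA_real_, net = NA_real_, max = NA_real_,
                avg_abs = NA_real_, mean = NA_real_, max_pixel = NA_real_))
  H <- dev$screen_height
  list(total = sum(abs(d)) / H * 100,
       net = abs(sum(d)) / H * 100,
       max = max(abs(d)) / H * 100,
       avg_abs = mean(abs(d)) / H * 100,
       mean = mean(d) / H,
       max_pixel = max(abs(d)))
}

trace_time_s <- function(trace) {
  t <- trace$samples$t
  if (length(t) < 2) return(NA_real_)
  (t[length(t)] - t[1]) / 1000
}

#' Tracing time features
#'
#' Per path kind: the raw tracing time summed over the three levels
#' (seconds) and that time normalized by the window width (s/px); plus
#' the average per-trace time over all nine tracing tasks.
#'
#' @param session A `motorfair_session`.
#' @return Named list of timing features.
#' @export
timing_features <- function(session) {
  per_trace <- vapply(session$trace_tasks, trace_time_s, numeric(1))
  kinds <- vapply(session$trace_tasks, function(tr) tr$path_kind, character(1))
  W <- vapply(session$trace_tasks,
              function(tr) tr$centerline_params$window_width, numeric(1))
  out <- list()
  for (k in trace_kinds()) {
    sel <- kinds == k
    tt <- if (any(sel) && !anyNA(per_trace[sel])) sum(per_trace[sel]) else NA_real_
    out[[paste0("time_", k)]] <- tt
    out[[paste0("time_norm_", k)]] <- if (is.na(tt)) NA_real_ else tt / W[sel][1]
  }
  out$average_tracing_time <- if (length(per_trace) && !anyNA(per_trace))
    mean(per_trace) else NA_real_
  out
}

#' Points-inside-band features
#'
#' Counts, per trace, the samples whose absolute centerline deviation is
#' at most `band_halfwidth` pixels; reports the average count per path
#' kind and over all nine traces.
#'
#' @param session A `motorfair_session`.
#' @param band_halfwidth Half-width of the acceptance band, px (> 0).
#' @return Named list of per-kind and overall average counts.
#' @export
points_inside_features <- function(session, band_halfwidth = 15) {
  if (!is.numeric(band_halfwidth) || band_halfwidth <= 0)
    stop("band_halfwidth must be > 0", call. = FALSE)
  counts <- vapply(session$trace_tasks, function(tr) {
    dv <- signed_deviations(tr)
    sum(abs(dv$d) <= band_halfwidth)
  }, numeric(1))
  kinds <- vapply(session$trace_tasks, function(tr) tr$path_kind, character(1))
  out <- list()
  for (k in trace_kinds())
    out[[paste0("points_inside_", k)]] <-
      if (any(kinds == k)) mean(counts[kinds == k]) else NA_real_
  out$average_points_inside <- if (length(counts)) mean(counts) else NA_real_
  out
}

## speed/acceleration/turn statistics pooled over the levels of one path kind
kinematic_features <- function(traces, devs = NULL) {
  sp <- c(); acc <- c(); plen <- 0; dirch <- 0
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    s <- tr$samples
    if (nrow(s) < 3) next
    dt <- diff(s$t) / 1000
    step <- sqrt(diff(s$x)^2 + diff(s$y)^2)
    v <- step / dt
    sp <- c(sp, v)
    acc <- c(acc, abs(diff(v) / dt[-1]))
    plen <- plen + sum(step)
    d <- if (is.null(devs)) signed_deviations(tr)$d else devs[[i]]$d
    dd <- diff(d)
    dirch <- dirch + sum(diff(sign(dd[dd != 0])) != 0)
  }
  if (!length(sp))
    return(list(mean_speed = NA_real_, max_speed = NA_real_,
                speed_sd = NA_real_, path_length = NA_real_,
                mean_abs_acceleration = NA_real_, direction_changes = NA_real_))
  list(mean_speed = mean(sp), max_speed = max(sp), speed_sd = stats::sd(sp),
       path_length = plen, mean_abs_acceleration = mean(acc),
       direction_changes = dirch)
}

#' Keyboard features
#'
#' Response time is press time minus prompt time for the matched prompt
#' (prompts and presses are paired in order). Per key-task kind, pooled
#' over its three levels: average and s.d. of response time (s), count of
#' correct presses, ratio of false presses to total presses, and the
#' correct-press rate defined as correct presses divided by the average
#' response time. Ratios are flagged missing (`NA`) when there are no
#' presses, never coerced to zero.
#'
#' @param session A `motorfair_session`.
#' @return Named list of keyboard features.
#' @export
keyboard_features <- function(session) {
  kinds <- vapply(session$key_tasks, function(k) k$task_kind, character(1))
  per_task_false <- vapply(session$key_tasks, function(k) {
    sum(k$presses$key != k$prompts$expected_key)
  }, numeric(1))
  out <- list()
  all_rt <- c()
  for (k in key_kinds()) {
    tasks <- session$key_tasks[kinds == k]
    rt <- c(); correct <- c()
    for (task in tasks) {
      n <- min(nrow(task$prompts), nrow(task$presses))
      if (n == 0) next
      rt <- c(rt, (task$presses$t_press[1:n] - task$prompts$t_prompt[1:n]) / 1000)
      correct <- c(correct, task$presses$key[1:n] == task$prompts$expected_key[1:n])
    }
    all_rt <- c(all_rt, rt)
    if (!length(rt)) {
      out[[paste0("avg_rt_", k)]] <- NA_real_
      out[[paste0("rt_sd_", k)]] <- NA_real_
      out[[paste0("correct_count_", k)]] <- NA_real_
      out[[paste0("false_ratio_", k)]] <- NA_real_
      out[[paste0("press_rate_", k)]] <- NA_real_
    } else {
      avg <- mean(rt)
      out[[paste0("avg_rt_", k)]] <- avg
      out[[paste0("rt_sd_", k)]] <- stats::sd(rt)
      out[[paste0("correct_count_", k)]] <- sum(correct)
      out[[paste0("false_ratio_", k)]] <- sum(!correct) / length(correct)
      out[[paste0("press_rate_", k)]] <- sum(correct) / avg
    }
  }
  out$average_false_presses <- if (length(per_task_false))
    mean(per_task_false) else NA_real_
  out$average_response_time_all <- if (length(all_rt)) mean(all_rt) else NA_real_
  out
}

#' Click-task features
#'
#' Total click time is the sum over targets of click latency (s); the
#' reaction-time variant subtracts a fixed 200 ms stimulus-perception
#' allowance from each latency (floored at zero), approximating the
#' movement-onset-to-click interval when no pointer stream is recorded
#' for the click game.
#'
#' @param session A `motorfair_session`.
#' @return Named list of click features (`NA` when no clicks recorded).
#' @export
click_features <- function(session) {
  ct <- session$click_task
  if (is.null(ct) || is.null(ct$clicks) || nrow(ct$clicks) == 0)
    return(list(total_click_time = NA_real_, total_click_reaction = NA_real_,
                hit_rate = NA_real_, average_click_time = NA_real_,
                distance_error = NA_real_, click_time_sd = NA_real_))
  lat <- (ct$clicks$t_click - ct$targets$t_shown) / 1000
  dist <- sqrt((ct$clicks$x - ct$targets$x)^2 + (ct$clicks$y - ct$targets$y)^2)
  list(total_click_time = sum(lat),
       total_click_reaction = sum(pmax(lat - 0.2, 0)),
       hit_rate = mean(ct$clicks$hit),
       average_click_time = mean(lat),
       distance_error = mean(dist),
       click_time_sd = stats::sd(lat))
}

#' Memory-task features
#'
#' @param session A `motorfair_session`.
#' @return Named list with the maximum sequence length reached (the last
#'   correctly recalled length; one less than the first length if the
#'   first trial fails) and the number of incorrect trials.
#' @export
memory_features <- function(session) {
  mt <- session$memory_task
  if (is.null(mt) || is.null(mt$trials) || nrow(mt$trials) == 0)
    return(list(max_length = NA_real_, incorrect = NA_real_))
  list(max_length = as.numeric(mt$max_length_reached),
       incorrect = sum(!mt$trials$correct))
}

#' Extract the full feature vector for one participant
#'
#' Emits exactly the registry's features in registry order. Demographic
#' features are included only when `include_demographics` is `TRUE` (runs
#' excluding demographics from the model inputs drop them here). Memory
#' features can be excluded from the analysis via `include_memory`
#' (flagged missing, schema unchanged).
#'
#' @param session A `motorfair_session`.
#' @param participant The matching cohort row.
#' @param registry Feature registry, defaults to [feature_registry()].
#' @param include_demographics Include the 4 demographic features?
#' @param include_memory Populate the 2 memory features?
#' @param band_halfwidth Band half-width for points-inside features, px.
#' @return A one-row `data.frame`: `participant_id` followed by the
#'   registry features in order (demographics omitted when excluded).
#' @export
extract_features <- function(session, participant,
                             registry = feature_registry(),
                             include_demographics = TRUE,
                             include_memory = TRUE,
                             band_halfwidth = 15) {
  stopifnot(nrow(registry) == 79L)
  participant <- as.list(participant)
  kinds <- vapply(session$trace_tasks, function(tr) tr$path_kind, character(1))
  vals <- list()

  paths <- c(straight = "straight_line", sine = "sine_wave", spiral = "spiral")
  timing <- timing_features(session)
  devs <- lapply(session$trace_tasks, signed_deviations)
  if (!is.numeric(band_halfwidth) || band_halfwidth <= 0)
    stop("band_halfwidth must be > 0", call. = FALSE)
  inside_counts <- vapply(devs, function(dv)
    sum(abs(dv$d) <= band_halfwidth), numeric(1))
  pts <- list()
  for (k in trace_kinds())
    pts[[paste0("points_inside_", k)]] <-
      if (any(kinds == k)) mean(inside_counts[kinds == k]) else NA_real_
  pts$average_points_inside <-
    if (length(inside_counts)) mean(inside_counts) else NA_real_
  time_raw <- c(straight = "time_to_trace_a_straight_line",
                sine = "time_to_trace_the_sine_wave",
                spiral = "time_to_trace_a_spiral")
  time_norm <- c(straight = "time_to_trace_a_straight_line_normalized",
                 sine = "time_to_trace_the_sine_wave_normalized",
                 spiral = "time_to_trace_the_spiral_normalized")
  for (k in names(paths)) {
    p <- paths[[k]]
    traces <- session$trace_tasks[kinds == k]
    kdevs <- devs[kinds == k]
    pooled <- list(d = numeric(0), screen_height = NA_real_,
                   window_width = NA_real_)
    for (dv in kdevs) {
      pooled$d <- c(pooled$d, dv$d)
      pooled$screen_height <- dv$screen_height
      pooled$window_width <- dv$window_width
    }
    devf <- deviation_features(pooled)
    vals[[paste0("total_deviation_", p)]] <- devf$total
    vals[[paste0("net_deviation_", p)]] <- devf$net
    vals[[paste0("maximum_deviation_", p)]] <- devf$max
    vals[[paste0("average_absolute_deviation_", p)]] <- devf$avg_abs
    vals[[paste0("mean_deviation_", p)]] <- devf$mean
    vals[[paste0("maximum_pixel_deviation_", p)]] <- devf$max_pixel
    vals[[paste0("deviation_sd_", p)]] <-
      if (length(pooled$d) > 1) stats::sd(pooled$d) else NA_real_
    vals[[time_raw[[k]]]] <- timing[[paste0("time_", k)]]
    vals[[time_norm[[k]]]] <- timing[[paste0("time_norm_", k)]]
    vals[[paste0("points_inside_", p)]] <- pts[[paste0("points_inside_", k)]]
    kin <- kinematic_features(traces, kdevs)
    vals[[paste0("mean_speed_", p)]] <- kin$mean_speed
    vals[[paste0("max_speed_", p)]] <- kin$max_speed
    vals[[paste0("speed_sd_", p)]] <- kin$speed_sd
    vals[[paste0("path_length_", p)]] <- kin$path_length
    vals[[paste0("mean_abs_acceleration_", p)]] <- kin$mean_abs_acceleration
    vals[[paste0("direction_changes_", p)]] <- kin$direction_changes
  }
  vals$average_tracing_time_for_all_tasks <- timing$average_tracing_time
  vals$average_points_inside_all_lines <- pts$average_points_inside

  cf <- click_features(session)
  vals$total_click_time_for_all_tests <- cf$total_click_time
  vals$total_click_reaction_time <- cf$total_click_reaction
  vals$click_hit_rate <- cf$hit_rate
  vals$average_click_time <- cf$average_click_time
  vals$click_distance_error_mean <- cf$distance_error
  vals$click_time_sd <- cf$click_time_sd

  kf <- keyboard_features(session)
  key_map <- c(constant = "constant_key", two_letter = "two_letter_key",
               random = "random_key")
  rate_names <- c(constant_key = "correct_the_press_rate_constant_key",
                  two_letter_key = "correct_press_rate_two_letter_key",
                  random_key = "correct_press_rate_random_key")
  for (k in key_kinds()) {
    kk <- key_map[[k]]
    vals[[paste0("average_response_time_", kk)]] <- kf[[paste0("avg_rt_", k)]]
    vals[[paste0("response_time_sd_", kk)]] <- kf[[paste0("rt_sd_", k)]]
    vals[[paste0("correct_press_count_", kk)]] <- kf[[paste0("correct_count_", k)]]
    vals[[paste0("false_press_ratio_", kk)]] <- kf[[paste0("false_ratio_", k)]]
    vals[[rate_names[[kk]]]] <- kf[[paste0("press_rate_", k)]]
  }
  vals$average_false_presses_all_tests <- kf$average_false_presses
  vals$average_response_time_all_tests <- kf$average_response_time_all

  if (include_memory) {
    mf <- memory_features(session)
    vals$memory_max_sequence_length <- mf$max_length
    vals$memory_incorrect_trials <- mf$incorrect
  } else {
    vals$memory_max_sequence_length <- NA_real_
    vals$memory_incorrect_trials <- NA_real_
  }

  if (include_demographics) {
    vals$sex <- participant$sex %||% NA_character_
    vals$race_binary <- participant$race_binary %||% NA_character_
    vals$device <- participant$device %||% NA_character_
    vals$hand <- participant$hand %||% NA_character_
  }

  want <- registry$name
  if (!include_demographics)
    want <- want[registry$category != "demographic"]
  missing_names <- setdiff(want, names(vals))
  if (length(missing_names))
    stop("extractor did not produce: ", paste(missing_names, collapse = ", "),
         call. = FALSE)
  out <- c(list(participant_id = participant$id %||% session$participant_id),
           vals[want])
  quick_df(lapply(out, function(v) if (is.null(v)) NA else unname(v)))
}

#' Extract the feature matrix for a cohort of sessions
#'
#' @param sessions Named list of sessions (names = participant ids).
#' @param cohort Cohort `data.frame`.
#' @inheritParams extract_features
#' @return A `data.frame`: `participant_id` column then the registry
#'   features in registry order, one row per participant.
#' @export
extract_feature_matrix <- function(sessions, cohort,
                                   registry = feature_registry(),
                                   include_demographics = TRUE,
                                   include_memory = TRUE,
                                   band_halfwidth = 15) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    p <- as.list(cohort[i, ])
    extract_features(sessions[[p$id]], p, registry, include_demographics,
                     include_memory, band_halfwidth)
  })
  do.call(rbind, rows)
}

#' Write or read a feature matrix CSV
#'
#' First column `participant_id`, then the registry columns in registry
#' order.
#'
#' @param features Feature `data.frame`.
#' @param path File path.
#' @return `read_feature_matrix()` returns the `data.frame`.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
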
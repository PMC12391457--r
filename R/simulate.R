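#' @title Simulate raw interaction streams for the assessment battery
#' @description The battery mirrors a browser-based remote assessment:
#' three mouse-tracing tasks (straight line, sine wave, spiral), three
#' timed key-press tasks (constant key, two-letter, random sequence), a
#' target-clicking task, and a digit-span working-memory task, each tracing
#' and key task at three levels of increasing difficulty. Coordinates use
#' the browser convention: origin top-left, y increasing downward, CSS
#' pixels. Pointer offsets follow an AR(1) Gaussian process around the task
#' centerline, with an optional sinusoidal tremor for PD participants.
#' @name simulate
NULL

default_screen <- function() c(width = 1280, height = 800)

trace_kinds <- function() c("straight", "sine", "spiral")
key_kinds <- function() c("constant", "two_letter", "random")

## centerline geometry for one tracing task
centerline_params <- function(path_kind, level, screen) {
  W <- unname(screen[["width"]]); H <- unname(screen[["height"]])
  margin <- 80
  base <- list(path_kind = path_kind, level = level,
               window_width = W, window_height = H)
  switch(path_kind,
    straight = c(base, list(x0 = margin, x1 = W - margin, y_mid = H / 2)),
    sine = c(base, list(x0 = margin, x1 = W - margin, y_mid = H / 2,
                        amp = 40 + 25 * level,
                        wavelength = (W - 2 * margin) / (level + 1))),
    spiral = c(base, list(cx = W / 2, cy = H / 2,
                          theta_max = 2 * pi * (1 + 0.5 * level),
                          b = (min(W, H) / 2 - margin) /
                              (2 * pi * (1 + 0.5 * level)))),
    stop("unknown path_kind: ", path_kind, call. = FALSE)
  )
}

## evaluates the centerline y (straight/sine) or radius (spiral) at the
## sample's progress coordinate
centerline_eval <- function(params, x_or_theta) {
  switch(params$path_kind,
    straight = rep(params$y_mid, length(x_or_theta)),
    sine = params$y_mid +
      params$amp * sin(2 * pi * (x_or_theta - params$x0) / params$wavelength),
    spiral = params$b * x_or_theta
  )
}

## stationary AR(1) noise pinned to 0 at the first sample (the participant
## starts on the path)
ar1_offsets <- function(n, sd, rho) {
  if (n <= 1L || sd == 0) return(numeric(n))
  innov <- stats::rnorm(n - 1L, 0, sd * sqrt(1 - rho^2))
  c(0, stats::filter(innov, rho, method = "recursive"))
}

trace_duration_ms <- function(path_kind, level) {
  base <- c(straight = 2500, sine = 3500, spiral = 4500)[[path_kind]]
  base * (1 + 0.25 * (level - 1))
}

#' Simulate one mouse-tracing task
#'
#' Samples the pointer at the configured rate along the task centerline,
#' adding an AR(1) Gaussian offset whose standard deviation is
#' `base_noise_sd` scaled by the PD deviation multiplier (PD participants),
#' the device noise multiplier, and the non-dominant-hand penalty, plus a
#' sinusoidal tremor of amplitude `pd_tremor_amp` for PD participants.
#' Sample timestamps are dilated by `pd_time_scale` for PD participants.
#' The offset is applied vertically for straight/sine paths and radially
#' for the spiral.
#'
#' @param participant One cohort row (list or single-row data.frame).
#' @param path_kind `"straight"`, `"sine"` or `"spiral"`.
#' @param level Difficulty level, 1--3.
#' @param effects An [effect_config()].
#' @param screen Named vector `c(width =, height =)` in pixels.
#' @param seed Integer seed.
#' @param traits Optional per-participant traits from
#'   [participant_traits()]; drawn from `seed` when `NULL`.
#' @return A `motorfair_trace`: list with `path_kind`, `level`, `samples`
#'   (`data.frame` of `t` ms, `x` px, `y` px) and `centerline_params`.
#' @export
simulate_trace <- function(participant, path_kind, level, effects,
                           screen = default_screen(), seed = 1L,
                           traits = NULL) {
  if (!path_kind %in% trace_kinds())
    stop("unknown path_kind: ", path_kind, call. = FALSE)
  stopifnot(screen[["width"]] > 0, screen[["height"]] > 0)
  validate_effects(effects)
  participant <- as.list(participant)
  pe <- participant_effects(participant, effects)
  traits <- traits %||% participant_traits(effects, derive_seed(seed, "traits"))
  params <- centerline_params(path_kind, level, screen)
  dur <- trace_duration_ms(path_kind, level) * pe$time_scale * traits$time_mult
  n <- max(2L, as.integer(round(dur / 1000 * effects$sample_rate_hz)) + 1L)
  t <- seq(0, dur, length.out = n)
  with_seed(seed, {
    off <- ar1_offsets(n, pe$noise_sd * traits$noise_mult, effects$noise_ar)
    if (pe$tremor_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      trem <- pe$tremor_amp * sin(2 * pi * pe$tremor_freq * t / 1000 + phase)
      trem[1] <- 0  # start pinned to the path
      off <- off + trem
    }
  })
  if (path_kind == "spiral") {
    theta <- seq(0, params$theta_max, length.out = n)
    r <- pmax(0, centerline_eval(params, theta) + off)
    x <- params$cx + r * cos(theta)
    y <- params$cy + r * sin(theta)
    samples <- quick_df(list(t = t, x = x, y = y, theta = theta))
  } else {
    x <- seq(params$x0, params$x1, length.out = n)
    y <- centerline_eval(params, x) + off
    samples <- quick_df(list(t = t, x = x, y = y))
  }
  structure(list(path_kind = path_kind, level = level, samples = samples,
                 centerline_params = params),
            class = "motorfair_trace")
}

#' Simulate one timed key-press task
#'
#' Each of `n_prompts` visual prompts asks for one key; the simulated
#' response time is `base_rt_ms` dilated by `pd_time_scale` for PD
#' participants, plus the device latency and Gaussian noise
#' (`rt_noise_sd_ms`), floored at 50 ms. With probability
#' `base_false_press_p` (scaled by `pd_false_press_scale` for PD) the
#' pressed key differs from the prompted key.
#'
#' @inheritParams simulate_trace
#' @param task_kind `"constant"`, `"two_letter"` or `"random"`.
#' @param n_prompts Prompts per level.
#' @return A list with `task_kind`, `level`, `alphabet`, `prompts`
#'   (`data.frame` of `t_prompt`, `expected_key`) and `presses`
#'   (`data.frame` of `t_press`, `key`).
#' @export
simulate_key_task <- function(participant, task_kind, level, effects,
                              seed = 1L, n_prompts = 10L, traits = NULL) {
  if (!task_kind %in% key_kinds())
    stop("unknown task_kind: ", task_kind, call. = FALSE)
  validate_effects(effects)
  participant <- as.list(participant)
  pe <- participant_effects(participant, effects)
  traits <- traits %||% participant_traits(effects, derive_seed(seed, "traits"))
  alphabet <- switch(task_kind,
    constant = "f",
    two_letter = c("f", "j"),
    random = letters[1:10])
  with_seed(seed, {
    gaps <- 1500 + stats::runif(n_prompts, 0, 300)
    t_prompt <- cumsum(gaps)
    expected <- if (task_kind == "constant") rep("f", n_prompts) else
      sample(alphabet, n_prompts, replace = TRUE)
    rt <- pmax(50, effects$base_rt_ms * pe$time_scale * traits$time_mult +
                 pe$latency_ms + traits$rt_shift_ms +
                 stats::rnorm(n_prompts, 0, effects$rt_noise_sd_ms))
    wrong <- stats::runif(n_prompts) < pe$false_press_p
    full <- c(letters[1:10], "f", "j")
    key <- expected
    if (any(wrong))
      key[wrong] <- vapply(expected[wrong], function(e)
        sample(setdiff(full, e), 1L), character(1))
  })
  list(task_kind = task_kind, level = level, alphabet = alphabet,
       prompts = quick_df(list(t_prompt = t_prompt, expected_key = expected)),
       presses = quick_df(list(t_press = t_prompt + rt, key = key)))
}

#' Simulate the target-clicking task
#'
#' Targets appear at random screen locations; one click attempt is recorded
#' per target with latency `base_click_rt_ms` (PD-dilated, device-delayed,
#' noisy) and a placement error with standard deviation `click_noise_sd_px`
#' scaled by the same group noise multipliers as the tracing offset. A
#' click within 25 px of the target counts as a hit.
#'
#' @inheritParams simulate_trace
#' @param n_targets Number of targets shown.
#' @return A list with `targets` (`t_shown`, `x`, `y`) and `clicks`
#'   (`t_click`, `x`, `y`, `hit`).
#' @export
simulate_click_task <- function(participant, effects,
                                screen = default_screen(), seed = 1L,
                                n_targets = 10L, traits = NULL) {
  validate_effects(effects)
  participant <- as.list(participant)
  pe <- participant_effects(participant, effects)
  traits <- traits %||% participant_traits(effects, derive_seed(seed, "traits"))
  W <- unname(screen[["width"]]); H <- unname(screen[["height"]])
  margin <- 60
  with_seed(seed, {
    tx <- stats::runif(n_targets, margin, W - margin)
    ty <- stats::runif(n_targets, margin, H - margin)
    t_shown <- 2000 * seq_len(n_targets)
    lat <- pmax(100, effects$base_click_rt_ms * pe$time_scale *
                  traits$time_mult + pe$latency_ms + traits$rt_shift_ms +
                  stats::rnorm(n_targets, 0, effects$rt_noise_sd_ms))
    err_sd <- effects$click_noise_sd_px * pe$noise_mult * traits$noise_mult
    cx <- tx + stats::rnorm(n_targets, 0, err_sd)
    cy <- ty + stats::rnorm(n_targets, 0, err_sd)
  })
  hit <- sqrt((cx - tx)^2 + (cy - ty)^2) <= 25
  list(targets = data.frame(t_shown = t_shown, x = tx, y = ty),
       clicks = data.frame(t_click = t_shown + lat, x = cx, y = cy, hit = hit))
}

#' Simulate the digit-span working-memory task
#'
#' Sequence lengths increase from `start_length` until the first failure or
#' the configured cap. Recall success is Bernoulli with probability
#' `plogis((capacity - length) / 0.8)` where the baseline capacity of 7
#' items is reduced by `pd_memory_penalty` for PD participants.
#'
#' @inheritParams simulate_trace
#' @param cap Maximum sequence length attempted.
#' @param start_length First sequence length.
#' @return A list with `trials` (`data.frame` of `sequence_length`,
#'   `correct`) and `max_length_reached` (last correct length, or
#'   `start_length - 1` if the first trial fails).
#' @export
simulate_memory_task <- function(participant, effects, seed = 1L,
                                 cap = 10L, start_length = 3L) {
  validate_effects(effects)
  participant <- as.list(participant)
  pe <- participant_effects(participant, effects)
  capacity <- 7 - pe$memory_penalty
  lens <- integer(0); correct <- logical(0)
  with_seed(seed, {
    for (len in seq.int(start_length, cap)) {
      ok <- stats::runif(1) < stats::plogis((capacity - len) / 0.8)
      lens <- c(lens, len); correct <- c(correct, ok)
      if (!ok) break
    }
  })
  max_len <- if (any(correct)) max(lens[correct]) else start_length - 1L
  list(trials = data.frame(sequence_length = lens, correct = correct),
       max_length_reached = as.integer(max_len))
}

#' Simulate one full assessment session
#'
#' Assembles the 3 tracing kinds and 3 key-task kinds at 3 levels each
#' (9 + 9 records), one clicking task and one memory run. Sub-task seeds
#' are derived from the session seed and the task name, so inserting a
#' task never shifts the randomness of the others.
#'
#' @inheritParams simulate_trace
#' @return A `motorfair_session`: list with `participant_id`, `screen`,
#'   `trace_tasks` (9), `key_tasks` (9), `click_task`, `memory_task`.
#' @export
simulate_session <- function(participant, effects = effect_config(),
                             screen = default_screen(), seed = 1L) {
  participant <- as.list(participant)
  traits <- participant_traits(effects, derive_seed(seed, "traits"))
  traces <- list(); keys <- list()
  for (kind in trace_kinds()) for (lvl in 1:3) {
    s <- derive_seed(seed, paste("trace", kind, lvl))
    traces[[length(traces) + 1L]] <-
      simulate_trace(participant, kind, lvl, effects, screen, s, traits)
  }
  for (kind in key_kinds()) for (lvl in 1:3) {
    s <- derive_seed(seed, paste("key", kind, lvl))
    keys[[length(keys) + 1L]] <-
      simulate_key_task(participant, kind, lvl, effects, s, traits = traits)
  }
  structure(list(
    participant_id = participant$id %||% "unknown",
    screen = screen,
    trace_tasks = traces,
    key_tasks = keys,
    click_task = simulate_click_task(participant, effects, screen,
                                     derive_seed(seed, "click"),
                                     traits = traits),
    memory_task = simulate_memory_task(participant, effects,
                                       derive_seed(seed, "memory"))
  ), class = "motorfair_session")
}

#' Simulate sessions for a whole cohort
#'
#' @param cohort Cohort `data.frame` from [generate_cohort()].
#' @inheritParams simulate_trace
#' @return A named list of `motorfair_session`, one per participant.
#' @export
simulate_cohort_sessions <- function(cohort, effects = effect_config(),
                                     screen = default_screen(), seed = 1L) {
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    p <- as.list(cohort[i, ])
    out[[i]] <- simulate_session(p, effects, screen,
                                 derive_seed(seed, paste0("session/", p$id)))
  }
  names(out) <- cohort$id
  out
}

#' Write or read sessions as JSON-lines
#'
#' One session object per line, schema-tagged `motorfair.session.v1`.
#'
#' @param sessions List of sessions from [simulate_cohort_sessions()].
#' @param path Output file.
#' @return `write_sessions()` returns `path` invisibly; `read_sessions()`
#'   returns a list of sessions.
#' @export
write_sessions <- function(sessions, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (s in sessions) {
    obj <- unclass(s)
    obj$trace_tasks <- lapply(obj$trace_tasks, unclass)
    obj$screen <- as.list(obj$screen)
    obj$schema <- "motorfair.session.v1"
    writeLines(jsonlite::toJSON(obj, dataframe = "columns", digits = I(8),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    s <- jsonlite::fromJSON(l, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    if (!identical(s$schema, "motorfair.session.v1"))
      stop("unrecognized session schema", call. = FALSE)
    s$schema <- NULL
    s$screen <- unlist(s$screen)
    s$trace_tasks <- lapply(s$trace_tasks, function(tr) {
      tr$samples <- as.data.frame(tr$samples)
      structure(tr, class = "motorfair_trace")
    })
    s$key_tasks <- lapply(s$key_tasks, function(k) {
      k$prompts <- as.data.frame(k$prompts)
      k$presses <- as.data.frame(k$presses)
      k
    })
    s$click_task$targets <- as.data.frame(s$click_task$targets)
    s$click_task$clicks <- as.data.frame(s$click_task$clicks)
    s$memory_task$trials <- as.data.frame(s$memory_task$trials)
    structure(s, class = "motorfair_session")
  })
  names(out) <- vapply(out, function(s) s$participant_id, character(1))
  out
}
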
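# Hand-built session fragments with known geometry, for checking the
# feature extractors against values computed by hand.

make_straight_trace <- function(t, x, y, W = 1280, H = 800, y_mid = H / 2,
                                level = 1) {
  structure(list(
    path_kind = "straight", level = level,
    samples = data.frame(t = t, x = x, y = y),
    centerline_params = list(path_kind = "straight", level = level,
                             window_width = W, window_height = H,
                             x0 = min(x), x1 = max(x), y_mid = y_mid)
  ), class = "motorfair_trace")
}

make_key_task <- function(task_kind, expected, pressed, rt_ms, level = 1) {
  t_prompt <- 1000 * seq_along(expected)
  list(task_kind = task_kind, level = level,
       alphabet = unique(c(expected, pressed)),
       prompts = data.frame(t_prompt = t_prompt, expected_key = expected,
                            stringsAsFactors = FALSE),
       presses = data.frame(t_press = t_prompt + rt_ms, key = pressed,
                            stringsAsFactors = FALSE))
}

make_click_task <- function(latency_ms, err_px = 0) {
  n <- length(latency_ms)
  t_shown <- 2000 * seq_len(n)
  x <- rep(500, n); y <- rep(300, n)
  list(targets = data.frame(t_shown = t_shown, x = x, y = y),
       clicks = data.frame(t_click = t_shown + latency_ms,
                           x = x + err_px, y = y,
                           hit = rep(err_px <= 25, n)))
}

fixture_participant <- function() {
  list(id = "F1", sex = "female", race = "Black", race_binary = "Non-White",
       device = "Windows", hand = "left", label = "PD")
}

# a complete simulator session for registry-level checks
fixture_session <- function(seed = 42) {
  simulate_session(fixture_participant(), effect_config(), seed = seed)
}
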
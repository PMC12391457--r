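test_that("registry holds exactly 79 uniquely named features with the published names", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 79)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(unclass(table(reg$category)),
               c(demographic = 4, keyboard = 17, memory = 2, mouse_click = 6,
                 mouse_movement = 50), ignore_attr = TRUE)
  published <- c(
    "total_deviation_straight_line", "time_to_trace_a_spiral",
    "net_deviation_straight_line", "maximum_deviation_straight_line",
    "average_absolute_deviation_straight_line",
    "time_to_trace_a_straight_line_normalized",
    "time_to_trace_the_spiral_normalized",
    "maximum_pixel_deviation_straight_line",
    "average_tracing_time_for_all_tasks",
    "time_to_trace_the_sine_wave_normalized",
    "correct_the_press_rate_constant_key",
    "average_response_time_constant_key", "mean_deviation_straight_line",
    "total_click_time_for_all_tests", "false_press_ratio_random_key",
    "average_false_presses_all_tests", "total_click_reaction_time",
    "time_to_trace_a_straight_line", "average_points_inside_all_lines")
  expect_true(all(published %in% reg$name))
})

test_that("signed deviations follow the definitions for straight and spiral paths", {
  tr <- make_straight_trace(t = c(0, 100, 200), x = c(100, 200, 300),
                            y = c(410, 390, 420), y_mid = 400)
  expect_equal(signed_deviations(tr)$d, c(10, -10, 20))
  # spiral: radial sample minus centerline radius at the matched angle
  sp <- simulate_trace(fixture_participant(), "spiral", 1,
                       null_effects(base_noise_sd = 0,
                                    between_subject_sd_noise = 0,
                                    between_subject_sd_time = 0,
                                    between_subject_rt_sd_ms = 0,
                                    rt_noise_sd_ms = 0), seed = 1)
  i <- 57
  sp$samples$x[i] <- sp$centerline_params$cx +
    (sp$centerline_params$b * sp$samples$theta[i] + 5) * cos(sp$samples$theta[i])
  sp$samples$y[i] <- sp$centerline_params$cy +
    (sp$centerline_params$b * sp$samples$theta[i] + 5) * sin(sp$samples$theta[i])
  expect_equal(signed_deviations(sp)$d[i], 5, tolerance = 1e-9)
  # out-of-domain samples are excluded and counted
  tr2 <- make_straight_trace(t = c(0, 100, 200), x = c(100, 200, 300),
                             y = c(410, 390, 420), y_mid = 400)
  tr2$centerline_params$x0 <- 150
  dv <- signed_deviations(tr2)
  expect_equal(dv$n_excluded, 1L)
  expect_equal(dv$d, c(-10, 20))
})

test_that("deviation summary features match hand-computed values", {
  dev <- list(d = c(10, -10, 20), screen_height = 1000, window_width = 1280)
  f <- deviation_features(dev)
  expect_equal(f$total, 4.0)
  expect_equal(f$net, 2.0)
  expect_equal(f$max, 2.0)
  expect_equal(f$avg_abs, 4 / 3, tolerance = 1e-6)
  expect_equal(f$mean, 20 / 3 / 1000, tolerance = 1e-6)
  expect_equal(f$max_pixel, 20)
  # zero series
  z <- deviation_features(list(d = rep(0, 5), screen_height = 800))
  expect_true(all(unlist(z) == 0))
  # empty series: all six flagged missing
  e <- deviation_features(list(d = numeric(0), screen_height = 800))
  expect_true(all(is.na(unlist(e))))
})

test_that("percentage features are scale-invariant, pixel features linear", {
  d <- c(3, -7, 11)
  f1 <- deviation_features(list(d = d, screen_height = 500))
  f2 <- deviation_features(list(d = 2 * d, screen_height = 1000))
  for (nm in c("total", "net", "max", "avg_abs", "mean"))
    expect_equal(f1[[nm]], f2[[nm]])
  expect_equal(f2$max_pixel, 2 * f1$max_pixel)
})

test_that("deviation magnitude orderings hold on random series", {
  set.seed(99)
  for (i in 1:50) {
    d <- rnorm(sample(2:200, 1), sd = runif(1, 0.1, 30))
    f <- deviation_features(list(d = d, screen_height = 800))
    expect_gte(f$total, f$net)
    expect_gte(f$total, f$max)
    expect_gte(f$max, f$avg_abs)
  }
})

test_that("timing features use last-minus-first time and window-width normalization", {
  tr <- make_straight_trace(t = c(0, 2500, 5000), x = c(0, 500, 1000),
                            y = rep(400, 3), W = 1000)
  session <- list(trace_tasks = list(tr))
  f <- timing_features(session)
  expect_equal(f$time_straight, 5.0)
  expect_equal(f$time_norm_straight, 0.005)
  # nine traces with times 1..9 s average to 5 s
  traces <- lapply(1:9, function(i)
    make_straight_trace(t = c(0, i * 1000), x = c(0, 100), y = c(400, 400)))
  f9 <- timing_features(list(trace_tasks = traces))
  expect_equal(f9$average_tracing_time, 5.0)
  # a single-sample trace leaves the time features missing
  one <- make_straight_trace(t = 0, x = 100, y = 400)
  expect_true(is.na(timing_features(list(trace_tasks = list(one)))$time_straight))
})

test_that("points-inside counts respect the band and reject a zero band", {
  tr <- make_straight_trace(t = c(0, 100, 200), x = c(100, 200, 300),
                            y = c(410, 390, 420), y_mid = 400)
  session <- list(trace_tasks = list(tr))
  f <- points_inside_features(session, band_halfwidth = 10)
  expect_equal(f$points_inside_straight, 2)
  on_line <- make_straight_trace(t = c(0, 100), x = c(0, 50), y = c(400, 400))
  f2 <- points_inside_features(list(trace_tasks = list(on_line)), 15)
  expect_equal(f2$points_inside_straight, 2)
  expect_error(points_inside_features(session, 0), "band_halfwidth")
})

test_that("keyboard features follow the press-rate and false-press definitions", {
  const <- make_key_task("constant", rep("f", 3), rep("f", 3), rep(500, 3))
  rand <- make_key_task("random", c("a", "b", "c", "d"),
                        c("a", "x", "c", "d"), rep(400, 4))
  two <- make_key_task("two_letter", c("f", "j"), c("f", "j"), rep(300, 2))
  session <- list(key_tasks = list(const, rand, two))
  f <- keyboard_features(session)
  expect_equal(f$avg_rt_constant, 0.5)
  expect_equal(f$press_rate_constant, 3 / 0.5)  # correct presses / mean RT
  expect_equal(f$false_ratio_random, 0.25)
  expect_equal(f$correct_count_random, 3)
  expect_equal(f$average_false_presses, mean(c(0, 1, 0)))
  # no false presses anywhere
  f2 <- keyboard_features(list(key_tasks = list(const, two)))
  expect_equal(f2$average_false_presses, 0)
  # a kind with no presses is flagged missing, not zero
  empty <- make_key_task("random", character(0), character(0), numeric(0))
  f3 <- keyboard_features(list(key_tasks = list(const, empty)))
  expect_true(is.na(f3$false_ratio_random))
})

test_that("click features sum latencies and flag empty tasks missing", {
  session <- list(click_task = make_click_task(c(400, 600)))
  f <- click_features(session)
  expect_equal(f$total_click_time, 1.0)
  expect_equal(f$total_click_reaction, sum(pmax(c(0.4, 0.6) - 0.2, 0)))
  expect_equal(f$hit_rate, 1.0)
  empty <- list(click_task = make_click_task(numeric(0)))
  expect_true(all(is.na(unlist(click_features(empty)))))
  miss <- list(click_task = make_click_task(c(500, 500), err_px = 50))
  expect_equal(click_features(miss)$hit_rate, 0)
  expect_equal(click_features(miss)$distance_error, 50)
})

test_that("memory features follow the stated failure convention", {
  ok <- list(memory_task = list(
    trials = data.frame(sequence_length = 3:5, correct = TRUE),
    max_length_reached = 5L))
  f <- memory_features(ok)
  expect_equal(f$max_length, 5)
  expect_equal(f$incorrect, 0)
  fail_first <- list(memory_task = list(
    trials = data.frame(sequence_length = 3L, correct = FALSE),
    max_length_reached = 2L))
  f2 <- memory_features(fail_first)
  expect_equal(f2$max_length, 2)
  expect_equal(f2$incorrect, 1)
  none <- list(memory_task = list(trials = data.frame(), max_length_reached = NA))
  expect_true(all(is.na(unlist(memory_features(none)))))
})

test_that("extract_features emits the registry schema deterministically", {
  p <- fixture_participant()
  s <- fixture_session()
  fv <- extract_features(s, p)
  expect_equal(ncol(fv), 80)  # participant_id + 79 registry features
  expect_equal(names(fv)[-1], feature_registry()$name)
  expect_identical(extract_features(s, p), fv)
  # demographics excluded drops exactly the 4 demographic columns
  fv2 <- extract_features(s, p, include_demographics = FALSE)
  expect_equal(ncol(fv2), 76)
  expect_false(any(c("sex", "device") %in% names(fv2)))
  # memory excluded flags the memory features missing, schema unchanged
  fv3 <- extract_features(s, p, include_memory = FALSE)
  expect_equal(ncol(fv3), 80)
  expect_true(is.na(fv3$memory_max_sequence_length))
  # zero-noise sessions produce zero deviation features
  quiet <- simulate_session(p, null_effects(
    base_noise_sd = 0, rt_noise_sd_ms = 0, click_noise_sd_px = 0,
    between_subject_sd_time = 0, between_subject_sd_noise = 0,
    between_subject_rt_sd_ms = 0), seed = 3)
  fq <- extract_features(quiet, p)
  expect_equal(fq$total_deviation_straight_line, 0)
  expect_equal(fq$net_deviation_sine_wave, 0)
  expect_equal(fq$maximum_deviation_spiral, 0, tolerance = 1e-9)
})

test_that("feature matrix CSV round-trips with registry column order", {
  co <- generate_cohort(cohort_config(seed = 8))[1:3, ]
  sess <- simulate_cohort_sessions(co, effect_config(), seed = 4)
  fm <- extract_feature_matrix(sess, co)
  expect_equal(nrow(fm), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(names(back), names(fm))
  expect_equal(back$total_deviation_spiral, fm$total_deviation_spiral,
               tolerance = 1e-9)
  # shipped registry file matches the in-code registry
  shipped <- system.file("extdata", "feature_registry_v1.csv",
                         package = "motorfair")
  expect_true(nzchar(shipped))
  expect_equal(utils::read.csv(shipped, stringsAsFactors = FALSE),
               feature_registry())
})
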
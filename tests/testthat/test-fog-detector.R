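test_that("decide applies the <= threshold rule", {
  cfg <- detector_config()
  # constant window: statistic 0, flagged FOG (extreme of a limb at rest)
  d <- decide(rep(9.81, 256), cfg)
  expect_equal(d$statistic_pct, 0)
  expect_true(d$fog)

  # walking window: statistic > 4, not FOG
  w <- synth_series(noise = 0, seed = 1)
  d <- decide(w$values, cfg)
  expect_gt(d$statistic_pct, 4)
  expect_false(d$fog)

  # boundary: statistic exactly at the threshold flags FOG.
  # Construct a window whose DC1 share is exactly 2% by scaling a
  # detail-only component against an approximation-only component.
  base <- rep(c(1, -1), 128) # pure DC1 content, unit energy per sample
  dc <- rep(1, 256) # pure approximation content
  # energy split: a^2 * 256 in DC1, b^2 * 256 in AC5 -> share a^2/(a^2+b^2)
  a <- sqrt(0.02)
  b <- sqrt(0.98)
  win <- a * base + b * dc
  d <- decide(win, cfg)
  expect_equal(d$statistic_pct, 2, tolerance = 1e-9)
  expect_true(d$fog)

  expect_error(decide(rep(1, 100), cfg), "expects 256")
})

test_that("batch run produces the documented timelines", {
  cfg <- detector_config()
  # constant record: every decision positive, one episode spanning the
  # decided region (backdated one decision interval)
  t <- (0:511) / 8
  const <- structure(
    list(times = t, values = rep(9.81, 512), sampling_rate_hz = 8),
    class = "magnitude_series"
  )
  tl <- detect_fog(const, cfg)
  expect_equal(length(tl$fog_flags), 33)
  expect_true(all(tl$fog_flags))
  expect_equal(nrow(tl$episodes), 1)
  expect_equal(tl$episodes$start_s, 255 / 8 - 1)
  expect_equal(tl$episodes$end_s, 511 / 8)

  # stimulation mirrors the decision flags one-for-one
  expect_identical(tl$stimulation_flags, tl$fog_flags)

  # pure walking: no positive decisions, no episodes
  w <- synth_series(duration_s = 64, noise = 0, seed = 1)
  tlw <- detect_fog(w, cfg)
  expect_equal(sum(tlw$fog_flags), 0)
  expect_equal(nrow(tlw$episodes), 0)

  # short series: warning + empty timeline
  short <- structure(
    list(times = (0:254) / 8, values = rep(9.81, 255), sampling_rate_hz = 8),
    class = "magnitude_series"
  )
  expect_warning(tls <- detect_fog(short, cfg), "shorter")
  expect_length(tls$fog_flags, 0)
  expect_equal(nrow(tls$episodes), 0)
})

test_that("an injected long FOG episode is recovered with bounded latency", {
  cfg <- detector_config()
  truth <- c(24, 48)
  s <- synth_series(duration_s = 64, episodes = list(truth), noise = 0, seed = 3)
  tl <- detect_fog(s, cfg)
  expect_equal(nrow(tl$episodes), 1)
  m <- match_episodes(data.frame(start_s = truth[1], end_s = truth[2]), tl$episodes)
  expect_equal(m$tp, 1)
  expect_equal(m$fn, 0)

  # onset is flagged no earlier than the true onset, and at latest by
  # the time the window is entirely FOG (window_size/fs seconds later)
  first_pos <- min(tl$decision_times[tl$fog_flags])
  expect_gte(first_pos, truth[1])
  expect_lte(first_pos, truth[1] + cfg$window_size / cfg$sampling_rate_hz)
})

test_that("episodes shorter than the detectability floor yield no decisions", {
  # a 10-s episode can cover at most 10/32 of a window; with walking at
  # ~5.1% first-band share the mixed-window statistic stays above 2%
  s <- synth_series(duration_s = 64, episodes = list(c(40, 50)), noise = 0, seed = 3)
  tl <- detect_fog(s)
  expect_equal(sum(tl$fog_flags), 0)
  expect_gt(min(tl$statistic_values), 2)
})

test_that("raising the threshold never decreases positive decisions", {
  s <- synth_series(duration_s = 64, episodes = list(c(20, 44)), noise = 0.5, seed = 8)
  counts <- vapply(c(0.5, 1, 2, 4, 6, 10), function(th) {
    sum(detect_fog(s, detector_config(threshold_pct = th))$fog_flags)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("every positive decision belongs to exactly one episode", {
  cfg <- detector_config()
  s <- synth_series(
    duration_s = 128, noise = 0.5, seed = 13,
    episodes = list(c(10, 34), c(60, 84), c(100, 124))
  )
  tl <- detect_fog(s, cfg)
  interval <- cfg$stride / cfg$sampling_rate_hz
  pos_times <- tl$decision_times[tl$fog_flags]
  covering <- vapply(pos_times, function(tt) {
    sum(tt > tl$episodes$start_s & tt <= tl$episodes$end_s + 1e-9)
  }, numeric(1))
  expect_true(all(covering == 1))
  # and episode boundaries come from positive decisions (start backdated)
  start_decisions <- tl$episodes$start_s + interval
  expect_true(all(vapply(start_decisions, function(sd) {
    any(abs(pos_times - sd) < 1e-9)
  }, logical(1))))
})

test_that("stream decisions equal batch decisions under arbitrary chunking", {
  cfg <- detector_config()
  s <- synth_series(
    duration_s = 66, noise = 0.5, seed = 21,
    episodes = list(c(20, 44))
  )
  batch <- detect_fog(s, cfg)

  feed_in_chunks <- function(sizes) {
    st <- stream_new(cfg)
    i <- 1L
    for (k in sizes) {
      st <- stream_feed(st, s$values[i:(i + k - 1L)])
      i <- i + k
    }
    stopifnot(i == length(s$values) + 1L)
    stream_timeline(st)
  }

  n <- length(s$values)
  chunkings <- list(
    rep(8L, n / 8), # the on-device cadence
    rep(1L, n), # one sample at a time
    c(n), # all at once
    c(300L, rep(1L, 28), 200L, n - 300L - 28L - 200L)
  )
  # plus a random partition
  set.seed(99)
  sizes <- c()
  left <- n
  while (left > 0L) {
    k <- sample.int(min(37L, left), 1L)
    sizes <- c(sizes, k)
    left <- left - k
  }
  chunkings[[length(chunkings) + 1L]] <- sizes

  for (sz in chunkings) {
    st_tl <- feed_in_chunks(sz)
    expect_equal(st_tl$decision_times, batch$decision_times)
    expect_equal(st_tl$statistic_values, batch$statistic_values)
    expect_identical(st_tl$fog_flags, batch$fog_flags)
    expect_equal(st_tl$episodes, batch$episodes)
  }

  # fewer than window_size samples: no decisions yet
  st <- stream_feed(stream_new(cfg), s$values[1:255])
  expect_length(stream_timeline(st)$fog_flags, 0)
  expect_equal(nrow(attr(st, "new_decisions")), 0)
})

test_that("min-duration filter drops short episodes when enabled", {
  s <- synth_series(duration_s = 64, episodes = list(c(24, 48)), noise = 0, seed = 3)
  full <- detect_fog(s, detector_config())
  dur <- full$episodes$end_s - full$episodes$start_s
  kept <- detect_fog(s, detector_config(min_episode_s = dur + 1))
  expect_equal(nrow(kept$episodes), 0)
  # flags are untouched by the episode filter
  expect_identical(kept$fog_flags, full$fog_flags)
})
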
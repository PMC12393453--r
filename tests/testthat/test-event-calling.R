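trace_tbl <- function(mfi, cell = 1L) {
  tibble::tibble(cell_id = cell, frame = seq_along(mfi), mfi = mfi)
}

test_that("window minima partition frames into non-overlapping windows", {
  expect_equal(window_minima(rep(100, 250)), rep(100, 250))
  x <- c(rep(c(120, 80), 50), rep(c(150, 120), 50))  # min 80 then 120
  expect_equal(window_minima(x, 100), c(rep(80, 100), rep(120, 100)))
  set.seed(1)
  y <- runif(73, 10, 50)
  expect_equal(window_minima(y, 100), rep(min(y), 73))   # window > n: global min
})

test_that("events are strict 50%-above-minimum runs with correct durations", {
  x <- rep(100, 300)
  x[51:56] <- 160
  ev <- call_events(trace_tbl(x), 3.44)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 51)   # spec's frames 50-55, 1-based here
  expect_equal(ev$end_frame, 56)
  expect_equal(ev$duration_s, 6 * 3.44)
  expect_false(ev$censored)
  # excursion to exactly 1.5x the minimum is NOT an event (strict rule)
  y <- rep(100, 300)
  y[51:56] <- 150
  expect_equal(nrow(call_events(trace_tbl(y), 3.44)), 0)
})

test_that("runs crossing the 100-frame window boundary merge into one event", {
  x <- rep(100, 300)
  x[99:103] <- 180
  ev <- call_events(trace_tbl(x), 3.44)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start_frame, ev$end_frame), c(99, 103))
  expect_equal(ev$end_frame - ev$start_frame + 1, 5)
})

test_that("boundary-touching events are kept and flagged censored", {
  x <- rep(100, 200)
  x[1:4] <- 180
  x[198:200] <- 180
  ev <- call_events(trace_tbl(x), 3.44)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$censored))
})

test_that("gap tolerance merges short sub-threshold gaps only when asked", {
  x <- rep(100, 120)
  x[30:34] <- 180
  x[36:40] <- 180
  expect_equal(nrow(call_events(trace_tbl(x), 3.44)), 2)
  ev <- call_events(trace_tbl(x), 3.44, gap_tolerance = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start_frame, ev$end_frame), c(30, 40))
})

test_that("detector agrees exactly with the brute-force oracle on random traces", {
  set.seed(99)
  for (k in 1:60) {
    n <- sample(80:350, 1)
    x <- runif(n, 80, 120)
    # plant a few excursions so supra-threshold frames actually occur
    for (j in seq_len(sample(0:4, 1))) {
      s <- sample(n, 1)
      e <- min(n, s + sample(0:10, 1))
      x[s:e] <- x[s:e] * runif(1, 1.4, 2.5)
    }
    ev <- call_events(trace_tbl(x), 1, window = 100)
    orc <- oracle_events(x, window = 100)
    expect_equal(as.data.frame(ev[, c("start_frame", "end_frame")]), orc)
  }
})

test_that("raising the threshold never increases supra-threshold frames", {
  set.seed(5)
  for (k in 1:20) {
    x <- runif(200, 80, 200)
    frames_at <- vapply(c(0.3, 0.5, 0.8, 1.2), function(r) {
      ev <- call_events(trace_tbl(x), 1, threshold_ratio = r)
      sum(ev$end_frame - ev$start_frame + 1)
    }, numeric(1))
    expect_true(all(diff(frames_at) <= 0))
  }
})

test_that("dynamics arithmetic: frequency floor, averages, inactive cells", {
  fi <- 3.44
  ev1 <- call_events(trace_tbl(c(rep(100, 50), rep(180, 3), rep(100, 247))), fi)
  dyn <- compute_dynamics(ev1, 300, fi)
  expect_equal(dyn$frequency, 1 / 17.2)   # single event over 17 min 12 s
  expect_equal(dyn$status, "active")
  # 3 events of 2, 4, 6 frames
  ev3 <- tibble::tibble(
    cell_id = 1L, start_frame = c(10L, 50L, 90L), end_frame = c(11L, 53L, 95L),
    duration_s = c(2, 4, 6) * fi, censored = FALSE
  )
  dyn3 <- compute_dynamics(ev3, 300, fi)
  expect_equal(dyn3$avg_duration, 12 * fi / 3)
  expect_equal(dyn3$frequency, 3 / 17.2)
  # no events: inactive, frequency 0, avg duration absent
  dyn0 <- compute_dynamics(ev3[0, ], 300, fi, cell_ids = 1:2)
  expect_equal(dyn0$status, c("inactive", "inactive"))
  expect_equal(dyn0$frequency, c(0, 0))
  expect_true(all(is.na(dyn0$avg_duration)))
  # any active cell is at or above the single-event floor
  set.seed(2)
  rec <- generate_recording(recording_spec(n_cells = 40, noise_sd = 0, rng_seed = 2))
  tr <- extract_traces(rec$movie, rec$labels)
  d <- compute_dynamics(call_events(tr, fi), 300, fi)
  expect_true(all(d$frequency[d$status == "active"] >= 1 / 17.2))
})

test_that("persistence uses a strict 170 threshold and a minimum duration", {
  fi <- 3.44
  p <- detect_persistent(trace_tbl(rep(180, 300)), fi)
  expect_true(p$persistent)
  expect_equal(p$persistent_duration_s, 1032)      # 300 x 3.44 s
  expect_false(detect_persistent(trace_tbl(rep(170, 300)), fi)$persistent)
  # 30 frames above threshold = 103.2 s, below the 120 s floor
  x <- rep(100, 300); x[1:30] <- 200
  p2 <- detect_persistent(trace_tbl(x), fi)
  expect_false(p2$persistent)
  expect_equal(p2$persistent_duration_s, 103.2)
  expect_error(detect_persistent(trace_tbl(c(300, 100)), fi), "scale_max")
})

test_that("1-SD dynamics classification uses sample SD and a fixed reference", {
  d <- tibble::tibble(
    cell_id = 1:5, status = "active", n_events = 1L,
    frequency = c(0.1, 0.2, 0.3, 0.4, 1.0),
    total_duration_s = 10, avg_duration = c(5, 5, 5, 5, 5)
  )
  cls <- classify_dynamics(d)
  thr <- attr(cls, "thresholds")
  expect_equal(unname(thr["frequency"]), 0.4 + sd(c(0.1, 0.2, 0.3, 0.4, 1.0)))
  expect_equal(round(unname(thr["frequency"]), 4), 0.7536)
  expect_equal(cls$cell_id[cls$high_frequency], 5L)
  # identical cells: nobody is strictly above mean + 0 SD
  d2 <- d |> dplyr::mutate(frequency = 0.3)
  expect_false(any(classify_dynamics(d2)$high_frequency))
  # reference thresholds are invariant to the population being classified
  shifted <- d |> dplyr::mutate(frequency = frequency + 10)
  cls_ref <- classify_dynamics(shifted, reference = d)
  expect_equal(attr(cls_ref, "thresholds"), thr)
  expect_true(all(cls_ref$high_frequency))
  expect_error(classify_dynamics(d[1, ]), "refused")
})

test_that("raster round-trips events and rejects overlaps", {
  expect_equal(sum(build_raster(tibble::tibble(
    cell_id = integer(), start_frame = integer(), end_frame = integer()
  ), 50, 1, cell_ids = 1:3)), 0)
  ev <- tibble::tibble(cell_id = 2L, start_frame = 11L, end_frame = 20L)
  ras <- build_raster(ev, 50, 3.44, cell_ids = 1:3)
  expect_equal(unname(rowSums(ras)), c(0, 10, 0))
  set.seed(10)
  rec <- generate_recording(recording_spec(n_cells = 30, noise_sd = 0, rng_seed = 10))
  tr <- extract_traces(rec$movie, rec$labels)
  ev <- call_events(tr, 3.44)
  ras <- build_raster(ev, 300, 3.44)
  back <- raster_to_events(ras)
  expect_equal(back$start_frame, ev$start_frame)
  expect_equal(back$end_frame, ev$end_frame)
  expect_equal(back$duration_s, ev$duration_s)
  # per-cell signalling seconds from raster row sums
  secs <- tibble::tibble(cell_id = as.integer(rownames(ras)),
                         s = rowSums(ras) * 3.44)
  tot <- dplyr::summarise(dplyr::group_by(ev, cell_id), s = sum(duration_s))
  expect_equal(unname(secs$s[match(tot$cell_id, secs$cell_id)]), tot$s)
  bad <- tibble::tibble(cell_id = c(1L, 1L), start_frame = c(5L, 8L),
                        end_frame = c(10L, 12L))
  expect_error(build_raster(bad, 50, 1), "overlapping")
})

test_that("high-frequency tail is near the Gaussian 1-SD band on synthetic populations", {
  set.seed(31)
  flagged <- vapply(1:30, function(k) {
    d <- tibble::tibble(
      cell_id = 1:200, status = "active", n_events = 1L,
      frequency = pmax(0.01, rnorm(200, 0.45, 0.2)),
      total_duration_s = 10, avg_duration = pmax(1, rnorm(200, 8, 3))
    )
    mean(classify_dynamics(d)$high_frequency)
  }, numeric(1))
  expect_gt(mean(flagged), 0.10)
  expect_lt(mean(flagged), 0.25)
})
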
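test_that("sleep annotation follows the 5-contiguous-minute definition", {
  expect_equal(annotate_sleep(c(0, 0, 0, 0, 0))$duration_min, 5)
  expect_equal(nrow(annotate_sleep(c(0, 0, 0, 0))), 0)
  b <- annotate_sleep(c(1, 0, 0, 0, 0, 0, 0, 2, 0, 0, 0, 0, 0, 1))
  expect_equal(b$duration_min, c(6, 5))
  expect_equal(b$start, c(1, 8))
  expect_equal(b$end, c(7, 13))
  expect_error(annotate_sleep(c(1, -2, 0)), "negative")
})

test_that("zero-runs touching missing minutes are discarded", {
  x <- c(1, 0, 0, 0, 0, 0, NA, 1, 0, 0, 0, 0, 0, 1)
  b <- annotate_sleep(x)
  expect_equal(nrow(b), 1)       # first run touches the NA
  expect_equal(b$start, 8)
  # run starting right after an NA is also dropped
  expect_equal(nrow(annotate_sleep(c(NA, 0, 0, 0, 0, 0, 1))), 0)
})

test_that("annotation matches an independent zero-run scanner on random series", {
  set.seed(42)
  for (r in 1:400) {
    n <- sample(10:120, 1)
    x <- rpois(n, 0.5)
    x[runif(n) < 0.05] <- NA
    expect_identical(annotate_sleep(x), oracle_bouts(x))
  }
})

test_that("bout clipping splits durations across windows and conserves totals", {
  # a bout ZT3:30-4:30 against 4-h bins: 30 min in each neighbouring bin
  seg <- clip_bouts_to_windows(data.frame(start = 210, end = 270),
                               seq(0, 1440, by = 240))
  expect_equal(seg$window, c(1, 2))
  expect_equal(seg$duration_min, c(30, 30))
  # fully interior bout: one segment, full duration
  seg <- clip_bouts_to_windows(data.frame(start = 250, end = 300),
                               seq(0, 1440, by = 240))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$duration_min, 50)
  expect_error(clip_bouts_to_windows(data.frame(start = 1, end = 2), c(0, 10, 5)),
               "increasing")
  # conservation against the naive double-loop on random bouts/partitions
  set.seed(7)
  for (r in 1:50) {
    b <- random_bouts(sample(1:30, 1))
    edges <- sort(sample(0:1440, sample(3:12, 1)))
    edges <- c(0, edges[edges > 0 & edges < 1440], 1440)
    seg <- clip_bouts_to_windows(b, edges)
    ora <- oracle_clip(b, edges)
    expect_equal(sum(seg$duration_min), sum(b$end - b$start))
    expect_equal(sum(seg$duration_min), sum(ora$duration_min))
    expect_equal(tapply(seg$duration_min, seg$window, sum)[order(unique(seg$window))],
                 tapply(ora$duration_min, ora$window, sum)[order(unique(ora$window))])
  }
})

test_that("window statistics give MSBL, counts and totals per window", {
  b <- data.frame(start = c(10, 40), end = c(20, 60))  # clipped: 10 and 20 min
  ws <- window_stats(b, c(0, 240))
  expect_equal(ws$msbl_min, 15)
  expect_equal(ws$bout_count, 2L)
  expect_equal(ws$sleep_min, 30)
  ws <- window_stats(data.frame(start = numeric(), end = numeric()), c(0, 240))
  expect_true(is.na(ws$msbl_min))
  expect_equal(ws$bout_count, 0L)
  expect_equal(ws$sleep_min, 0)
  # random bouts: agrees with a brute-force recomputation from clipped segments
  set.seed(99)
  b <- random_bouts(100, span = 2880)
  edges <- seq(0, 2880, by = 240)
  ws <- window_stats(b, edges)
  ora <- oracle_clip(b, edges)
  for (w in ws$window) {
    d <- ora$duration_min[ora$window == w]
    expect_equal(ws$sleep_min[w], sum(d))
    expect_equal(ws$bout_count[w], length(d))
    expect_equal(ws$msbl_min[w], if (length(d)) median(d) else NA_real_)
  }
})

test_that("day/night totals split at ZT12 with boundary clipping", {
  # a fly asleep exactly ZT10-ZT14 every day: 120 day + 120 night minutes
  counts <- matrix(1L, 5 * 1440, 1)
  for (d in 0:4) counts[d * 1440 + (601:840), 1] <- 0L
  tab <- monitor_table(counts, light_schedule(regime = rep("LD", 5)))
  dn <- day_night_totals(tab)
  expect_equal(dn$day_sleep_min, 120)
  expect_equal(dn$night_sleep_min, 120)
  # a fly that is never inactive sleeps zero
  tab0 <- monitor_table(matrix(1L, 5 * 1440, 1), light_schedule(regime = rep("LD", 5)))
  dn0 <- day_night_totals(tab0)
  expect_equal(dn0$day_sleep_min + dn0$night_sleep_min, 0)
  # fewer than 3 LD cycles is an error naming the shortfall
  tab2 <- monitor_table(matrix(1L, 2 * 1440, 1), light_schedule(regime = rep("LD", 2)))
  expect_error(day_night_totals(tab2), "found 2")
})

test_that("daily sleep profile matches the minute-grid average of pooled flies", {
  # single fly asleep ZT0:00-0:15 on each of 3 days: first bin 50%, rest 0
  counts <- matrix(1L, 3 * 1440, 1)
  for (d in 0:2) counts[d * 1440 + (1:15), 1] <- 0L
  tab <- monitor_table(counts, light_schedule(regime = rep("LD", 3)))
  prof <- daily_sleep_profile(tab)
  expect_equal(prof$value[1], 50)
  expect_equal(sum(prof$value[-1]), 0)
  # an always-asleep fly is at 100% everywhere
  tab1 <- monitor_table(matrix(0L, 3 * 1440, 1), light_schedule(regime = rep("LD", 3)))
  expect_true(all(daily_sleep_profile(tab1)$value == 100))
  # pooled simulated flies: bin-wise equal to the minute-grid oracle
  sim <- simulate_activity(sim_params("tropical"), n_flies = 16, days_ld = 5,
                           seed = 21, min_wake_count = 1)
  prof <- daily_sleep_profile(sim$table, mode = "minutes")
  bouts_by_fly <- lapply(seq_len(16), function(j) {
    b <- annotate_sleep(sim$table$counts[, j])
    b  # table starts at lights-on, so series minutes == tau minutes
  })
  ora <- oracle_profile(bouts_by_fly, cycles = 2:4)
  expect_equal(prof$value, ora, tolerance = 1e-12)
})

test_that("wake periods carry all beam counts", {
  # no sleep at all: a single wake period holding the series total
  x <- c(rep(1L, 100), 200L, rep(1L, 99))
  b <- annotate_sleep(x)
  w <- waking_activity(x, b)
  expect_equal(nrow(w), 1)
  expect_equal(w$counts_total, sum(x))
  # random series: wake totals always equal the series total (bouts are zeros)
  set.seed(13)
  for (r in 1:30) {
    x <- rpois(500, 0.4)
    w <- waking_activity(x, annotate_sleep(x))
    expect_equal(sum(w$counts_total), sum(x))
  }
})

test_that("sleep + wake + missing minutes partition the recording span", {
  set.seed(31)
  x <- rpois(2000, 0.4)
  x[sample(2000, 30)] <- NA
  b <- annotate_sleep(x, threshold_min = 1)  # every maximal clean zero-run
  w <- waking_activity(x, b)
  slept <- sum(b$duration_min)
  awake <- sum(w$end - w$start)  # includes NA-adjacent zero-runs (not sleep)
  expect_equal(slept + awake + sum(is.na(x)), length(x))
})
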
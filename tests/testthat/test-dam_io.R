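test_that("a toy DAM file reads back its count matrix", {
  f <- withr::local_tempfile(fileext = ".txt")
  cnt <- matrix(c(1L, 0L, 2L, 0L, 0L, 5L), nrow = 3)
  write_toy_dam(cnt, f)
  tab <- read_dam(f, light_schedule(regime = "LD"))
  expect_equal(unname(tab$counts), cnt)
  expect_equal(tab$start_clock, 480)
  expect_equal(tab$channel_ids, c("ch01", "ch02"))
})

test_that("duplicated or backward timestamps are hard errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  lines <- c("1\t02 Jan 17\t08:00:00\t1\t3",
             "2\t02 Jan 17\t08:00:00\t1\t4")
  writeLines(lines, f)
  expect_error(read_dam(f, light_schedule()), "duplicated")
  writeLines(rev(lines), f)  # same duplicate; now also non-increasing
  expect_error(read_dam(f, light_schedule()))
  writeLines(c("1\t02 Jan 17\t08:01:00\t1\t3",
               "2\t02 Jan 17\t08:00:00\t1\t4"), f)
  expect_error(read_dam(f, light_schedule()), "increasing")
})

test_that("malformed rows are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1\t02 Jan 17\t08:00:00\t1\t3",
               "2\t02 Jan 17\t08:01:00\t1"), f)
  expect_error(read_dam(f, light_schedule()), "row 2")
  writeLines(c("1\t02 Jan 17\tnot-a-time\t1\t3"), f)
  expect_error(read_dam(f, light_schedule()), "row 1")
})

test_that("write_dam / read_dam round-trip a synthetic day losslessly", {
  sim <- simulate_activity(sim_params("tropical"), n_flies = 3, days_ld = 1,
                           seed = 11)
  f <- withr::local_tempfile(fileext = ".txt")
  write_dam(sim$table, f)
  back <- read_dam(f, sim$table$schedule, channel_ids = sim$table$channel_ids)
  expect_identical(unname(back$counts), unname(sim$table$counts))
  expect_equal(back$start_clock, sim$table$start_clock)
  # an empty table writes an empty but valid file
  emp <- monitor_table(matrix(integer(), 0, 2,
                              dimnames = list(NULL, c("a", "b"))),
                       light_schedule())
  write_dam(emp, f)
  expect_equal(n_minutes(read_dam(f, light_schedule())), 0)
})

test_that("32-channel tables write 32 count columns", {
  tab <- monitor_table(matrix(0L, 5, 32), light_schedule())
  f <- withr::local_tempfile(fileext = ".txt")
  write_dam(tab, f)
  expect_length(strsplit(readLines(f)[1], "\t")[[1]], 4 + 32)
})

test_that("recording gaps and error-status rows become explicit missing minutes", {
  f <- withr::local_tempfile(fileext = ".txt")
  tm <- as.POSIXct("2017-01-02 08:00:00", tz = "UTC") + c(0, 60, 180) # minute 2 absent
  writeLines(paste(1:3, format(tm, "%d %b %y"), format(tm, "%H:%M:%S"),
                   c(1L, 51L, 1L), c(5L, 7L, 2L), sep = "\t"), f)
  tab <- read_dam(f, light_schedule())
  expect_equal(n_minutes(tab), 4)
  expect_equal(unname(tab$counts[, 1]), c(5L, NA, NA, 2L))  # row 2 flagged, row 3 gap
  expect_equal(tab$status[2], 51L)
})

test_that("ZT mapping follows the lights-on anchor and modular arithmetic", {
  sched <- light_schedule(lights_on = "08:00", regime = rep("LD", 3))
  mk <- function(start_clock, n) monitor_table(matrix(1L, n, 1), sched,
                                               start_clock = start_clock)
  zt <- to_zt(mk("08:00", 1))
  expect_equal(zt$zt_min, 0); expect_equal(zt$cycle, 0L)
  zt <- to_zt(mk("20:00", 1))
  expect_equal(zt$zt_min, 720)
  zt <- to_zt(mk("07:59", 2))
  expect_equal(zt$zt_min, c(1439, 0))
  expect_equal(zt$cycle, c(-1L, 0L))
  # independent modular-arithmetic oracle over a random start
  start <- 313
  tab <- mk(start, 3000)
  zt <- to_zt(tab)
  clock <- start + seq_len(3000) - 1
  expect_equal(zt$zt_min, (clock - 480) %% 1440)
  expect_equal(zt$cycle, as.integer(floor((clock - 480) / 1440)))
  # bijection per cycle and count conservation
  expect_false(anyDuplicated(zt[, c("zt_min", "cycle")]) > 0)
  expect_equal(sum(zt$count), sum(tab$counts))
})

test_that("to_zt requires a schedule", {
  tab <- monitor_table(matrix(1L, 3, 1), light_schedule())
  tab$schedule <- NULL
  expect_error(to_zt(tab), "schedule")
})

test_that("manifests validate region labels and referenced files", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- line_id: HB22", "  region: tropical",
               "  channels: [ch01, ch02]",
               "- line_id: S3", "  region: temperate",
               "  channels: [ch01]"), f)
  man <- read_manifest(f)
  expect_equal(nrow(man), 3)
  expect_setequal(unique(man$region), c("tropical", "temperate"))
  writeLines(c("- line_id: X", "  region: nowhere", "  channels: [c1]"), f)
  expect_error(read_manifest(f), "region")
})
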
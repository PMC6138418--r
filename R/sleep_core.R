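# Sleep annotation and fragmentation metrics.
#
# A sleep bout is a maximal run of >= threshold contiguous zero-count minutes
# (5 min by default, the standard Drosophila inactivity criterion). Bouts are
# half-open [start, end) in 0-based minute offsets. Runs that touch a missing
# minute are discarded (their true extent is unknowable); runs truncated by the
# series boundary are kept if the observed length reaches the threshold.

#' Annotate sleep bouts in one fly's minute series
#'
#' @param counts integer vector of per-minute beam crossings; `NA` marks
#'   missing minutes.
#' @param threshold_min minimum bout length in minutes (default 5).
#' @return a `data.frame` with columns `start`, `end` (half-open, 0-based
#'   minute offsets) and `duration_min`.
#' @export
annotate_sleep <- function(counts, threshold_min = 5L) {
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts are not allowed")
  n <- length(counts)
  if (n == 0)
    return(data.frame(start = integer(), end = integer(), duration_min = integer()))
  state <- ifelse(is.na(counts), 2L, as.integer(counts == 0))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L & r$lengths >= threshold_min
  if (any(keep)) {
    i <- which(keep)
    # drop zero-runs adjacent to a missing minute
    prev_missing <- i > 1 & r$values[pmax(i - 1L, 1L)] == 2L
    next_missing <- i < length(r$values) & r$values[pmin(i + 1L, length(r$values))] == 2L
    i <- i[!(prev_missing | next_missing)]
  } else i <- integer()
  data.frame(start = starts[i] - 1L, end = ends[i],
             duration_min = r$lengths[i])
}

#' Clip sleep bouts to a window partition
#'
#' Implements the bin-boundary rule used for all windowed sleep metrics: a bout
#' spanning neighbouring windows contributes to each window only the duration
#' that falls inside it. Clipping conserves total duration exactly whenever the
#' partition covers the bouts.
#'
#' @param bouts data.frame with `start`, `end` (half-open minutes).
#' @param edges strictly increasing numeric vector of window edges; window `i`
#'   is `[edges[i], edges[i+1])`. Edges define non-overlapping windows by
#'   construction; a non-increasing vector is an error.
#' @return a `data.frame` with columns `window` (1-based index), `win_start`,
#'   `start`, `end`, `duration_min` — one row per (bout, overlapped window).
#' @export
clip_bouts_to_windows <- function(bouts, edges) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("window edges must be strictly increasing (overlapping windows are not allowed)")
  nw <- length(edges) - 1L
  if (nw < 1) stop("need at least one window")
  empty <- data.frame(window = integer(), win_start = numeric(),
                      start = numeric(), end = numeric(), duration_min = numeric())
  if (nrow(bouts) == 0) return(empty)
  # first and last window each bout touches (clamped to the partition)
  lo <- pmax(findInterval(bouts$start, edges), 1L)
  hi <- pmin(findInterval(bouts$end, edges, left.open = TRUE), nw)
  reps <- pmax(hi - lo + 1L, 0L)
  if (sum(reps) == 0) return(empty)
  w <- sequence(reps) - 1L + rep(lo, reps)
  bs <- rep(bouts$start, reps)
  be <- rep(bouts$end, reps)
  s <- pmax(bs, edges[w])
  e <- pmin(be, edges[w + 1L])
  keep <- e > s
  data.frame(window = w[keep], win_start = edges[w[keep]],
             start = s[keep], end = e[keep], duration_min = (e - s)[keep])
}

#' Windowed sleep statistics (MSBL, bout count, sleep minutes)
#'
#' Computes, per window of the partition, the median sleep bout length (MSBL,
#' median of the *clipped* segment durations; `NA` when the window holds no
#' segment), the number of segments, and total sleep minutes. A bout spanning a
#' boundary is counted once in each overlapped window.
#'
#' @inheritParams clip_bouts_to_windows
#' @return a `data.frame` with one row per window: `window`, `win_start`,
#'   `msbl_min`, `bout_count`, `sleep_min`.
#' @export
window_stats <- function(bouts, edges) {
  seg <- clip_bouts_to_windows(bouts, edges)
  nw <- length(edges) - 1L
  res <- data.frame(window = seq_len(nw), win_start = edges[-length(edges)],
                    msbl_min = NA_real_, bout_count = 0L, sleep_min = 0)
  if (nrow(seg)) {
    agg <- stats::aggregate(duration_min ~ window, seg,
                            function(d) c(med = stats::median(d), n = length(d),
                                          tot = sum(d)))
    res$msbl_min[agg$window] <- agg$duration_min[, "med"]
    res$bout_count[agg$window] <- as.integer(agg$duration_min[, "n"])
    res$sleep_min[agg$window] <- agg$duration_min[, "tot"]
  }
  res
}

# Sleep bouts for every channel of a monitor table, on the "tau" axis:
# minutes since the ZT0 of cycle 0 (so cycle c spans [c*1440, (c+1)*1440)).
sleep_bouts_table <- function(table, threshold_min = 5L) {
  shift <- table$start_clock - table$schedule$lights_on
  res <- lapply(seq_along(table$channel_ids), function(j) {
    b <- annotate_sleep(table$counts[, j], threshold_min)
    if (nrow(b)) {
      b$start <- b$start + shift
      b$end <- b$end + shift
      b$channel <- table$channel_ids[j]
    }
    b
  })
  data.table::rbindlist(res[vapply(res, nrow, 0L) > 0], fill = TRUE)
}

#' Per-fly day and night sleep totals
#'
#' Total sleep minutes during the 12-h light phase (ZT0--12) and dark phase
#' (ZT12--24), averaged over the last `last_n` complete LD cycles (the standard
#' last-three-LD-days convention). Bouts spanning ZT0 or ZT12 are clipped at
#' the boundary so each phase receives only the minutes falling inside it.
#'
#' @param table a [monitor_table()] with at least `last_n` complete LD cycles.
#' @param last_n number of trailing LD cycles to average (default 3).
#' @param threshold_min sleep bout threshold.
#' @return a `data.table` with columns `channel`, `day_sleep_min`,
#'   `night_sleep_min`.
#' @export
day_night_totals <- function(table, last_n = 3L, threshold_min = 5L) {
  ld <- complete_cycles(table, regime = "LD")
  if (length(ld) < last_n)
    stop("need at least ", last_n, " complete LD cycles, found ", length(ld))
  use <- utils::tail(ld, last_n)
  shift <- table$start_clock - table$schedule$lights_on
  res <- lapply(seq_along(table$channel_ids), function(j) {
    b <- annotate_sleep(table$counts[, j], threshold_min)
    b$start <- b$start + shift
    b$end <- b$end + shift
    day <- night <- 0
    for (cc in use) {
      seg <- clip_bouts_to_windows(b, cc * MIN_PER_DAY + c(0, 720, MIN_PER_DAY))
      day <- day + sum(seg$duration_min[seg$window == 1L])
      night <- night + sum(seg$duration_min[seg$window == 2L])
    }
    data.table::data.table(channel = table$channel_ids[j],
                           day_sleep_min = day / last_n,
                           night_sleep_min = night / last_n)
  })
  data.table::rbindlist(res)
}

#' Daily sleep profile in 30-min bins
#'
#' Per-bin sleep, averaged over flies and cycles: the standard daily sleep
#' profile (48 bins per 24-h cycle at the default width). In percent mode each
#' bin is `100 * sleep_min / bin_min`, the percentage of the bin spent asleep.
#'
#' @param table a [monitor_table()].
#' @param bin_min bin width in minutes (must divide 1440; default 30).
#' @param mode `"percent"` or `"minutes"`.
#' @param cycles cycles to average; default the last 3 complete LD cycles.
#' @param threshold_min sleep bout threshold.
#' @return a `data.frame` with `zt_min` (bin start), `value`, `n_flies`; the
#'   per-fly bin matrix is attached as attribute `per_fly`.
#' @export
daily_sleep_profile <- function(table, bin_min = 30L, mode = c("percent", "minutes"),
                                cycles = NULL, threshold_min = 5L) {
  mode <- match.arg(mode)
  stopifnot(MIN_PER_DAY %% bin_min == 0)
  if (is.null(cycles)) {
    ld <- complete_cycles(table, regime = "LD")
    if (length(ld) < 3) stop("need at least 3 complete LD cycles, found ", length(ld))
    cycles <- utils::tail(ld, 3L)
  }
  nb <- MIN_PER_DAY %/% bin_min
  shift <- table$start_clock - table$schedule$lights_on
  per_fly <- sapply(seq_along(table$channel_ids), function(j) {
    b <- annotate_sleep(table$counts[, j], threshold_min)
    b$start <- b$start + shift
    b$end <- b$end + shift
    acc <- numeric(nb)
    for (cc in cycles) {
      edges <- cc * MIN_PER_DAY + seq(0, MIN_PER_DAY, by = bin_min)
      seg <- clip_bouts_to_windows(b, edges)
      if (nrow(seg)) {
        tot <- tapply(seg$duration_min, factor(seg$window, levels = seq_len(nb)), sum)
        tot[is.na(tot)] <- 0
        acc <- acc + as.numeric(tot)
      }
    }
    acc / length(cycles)
  })
  per_fly <- matrix(per_fly, nrow = nb,
                    dimnames = list(NULL, table$channel_ids))
  val <- rowMeans(per_fly)
  if (mode == "percent") {
    val <- 100 * val / bin_min
    per_fly <- 100 * per_fly / bin_min
  }
  out <- data.frame(zt_min = seq(0, MIN_PER_DAY - bin_min, by = bin_min),
                    value = val, n_flies = ncol(per_fly))
  attr(out, "per_fly") <- per_fly
  out
}

#' Beam-crossing totals per wake period
#'
#' Wake periods are the complement of the sleep bouts within the analysed span
#' (maximal runs of non-missing minutes outside any bout). Because sleep bouts
#' contain only zero-count minutes, the wake-period totals conserve the series
#' total exactly.
#'
#' @param counts one fly's minute series (`NA` = missing).
#' @param bouts sleep bouts from [annotate_sleep()] on the same series.
#' @return `data.frame` with `start`, `end`, `counts_total` per wake period.
#' @export
waking_activity <- function(counts, bouts) {
  n <- length(counts)
  occupied <- rep(FALSE, n)
  for (b in seq_len(nrow(bouts)))
    occupied[(bouts$start[b] + 1L):bouts$end[b]] <- TRUE
  wake <- !occupied & !is.na(counts)
  r <- rle(wake)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  data.frame(start = starts[i] - 1L, end = ends[i],
             counts_total = vapply(i, function(k)
               sum(counts[starts[k]:ends[k]]), 0))
}

#' Mean waking activity per fly, day/night split
#'
#' Mean beam crossings per wake period over the last `last_n` complete LD
#' cycles, split into day (ZT0--12) and night (ZT12--24) by the midpoint of
#' each wake period.
#'
#' @inheritParams day_night_totals
#' @return `data.table` with `channel`, `day_mean_counts`, `night_mean_counts`.
#' @export
waking_activity_summary <- function(table, last_n = 3L, threshold_min = 5L) {
  ld <- complete_cycles(table, regime = "LD")
  if (length(ld) < last_n)
    stop("need at least ", last_n, " complete LD cycles, found ", length(ld))
  use <- utils::tail(ld, last_n)
  shift <- table$start_clock - table$schedule$lights_on
  res <- lapply(seq_along(table$channel_ids), function(j) {
    x <- table$counts[, j]
    b <- annotate_sleep(x, threshold_min)
    w <- waking_activity(x, b)
    mid <- shift + (w$start + w$end) / 2
    cyc <- floor(mid / MIN_PER_DAY)
    keep <- cyc %in% use
    is_day <- (mid %% MIN_PER_DAY) < 720
    data.table::data.table(
      channel = table$channel_ids[j],
      day_mean_counts = mean(w$counts_total[keep & is_day]),
      night_mean_counts = mean(w$counts_total[keep & !is_day]))
  })
  data.table::rbindlist(res)
}
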
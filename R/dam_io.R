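# Time conventions shared by the whole pipeline:
#  * canonical sampling bin = 1 minute; coarser input is rejected, not resampled
#  * intervals are half-open [start, end) in minutes
#  * ZT0 = lights-on; zt_min = (clock - lights_on) mod 1440
#  * cycle c covers [lights_on + c*1440, lights_on + (c+1)*1440) on the clock axis

MIN_PER_DAY <- 1440L

#' Parse a clock time string to minutes of day
#'
#' @param x character like `"08:00"` or `"08:00:00"`, or a numeric already in
#'   minutes of day (returned unchanged).
#' @return minutes since midnight, in `[0, 1440)`.
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) {
    stopifnot(x >= 0, x < MIN_PER_DAY)
    return(as.numeric(x))
  }
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(parts) < 2 || anyNA(parts)) stop("cannot parse clock time: ", x)
  parts[1] * 60 + parts[2] + if (length(parts) >= 3) parts[3] / 60 else 0
}

#' Light/temperature schedule of a monitor experiment
#'
#' Describes the environmental regime the flies experienced: the clock time of
#' lights-on (which anchors zeitgeber time, ZT0), one regime label per
#' experimental day, and the holding temperature. In an LD day the light phase
#' is ZT0--ZT12 and the dark phase ZT12--ZT24; DD is constant darkness and LL
#' constant light.
#'
#' @param lights_on clock time of lights-on, `"HH:MM"` or minutes of day.
#' @param regime character vector, one of `"LD"`, `"DD"`, `"LL"` per day,
#'   indexed by cycle number (cycle 0 = first day).
#' @param temperature_C holding temperature in degrees Celsius (scalar).
#' @return an object of class `light_schedule`.
#' @export
light_schedule <- function(lights_on = "08:00", regime = rep("LD", 5),
                           temperature_C = 25) {
  regime <- toupper(regime)
  if (!all(regime %in% c("LD", "DD", "LL")))
    stop("regime entries must be LD, DD or LL")
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1)
  structure(
    list(lights_on = parse_clock(lights_on), regime = regime,
         temperature_C = temperature_C),
    class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> lights-on %02d:%02d, %d day(s) [%s], %g degC\n",
              x$lights_on %/% 60, round(x$lights_on %% 60), length(x$regime),
              paste(rle(x$regime)$values, collapse = "/"), x$temperature_C))
  invisible(x)
}

#' Per-minute activity monitor table
#'
#' The central container for beam-crossing data: one column of non-negative
#' integer counts per fly channel, one row per minute, at strictly contiguous
#' 1-minute spacing. Missing minutes (recording gaps, error-status rows) are
#' explicit `NA`s, never silently dropped; downstream sleep annotation discards
#' any putative sleep bout that touches a missing minute.
#'
#' @param counts integer matrix, minutes x channels; `NA` marks missing.
#' @param schedule a [light_schedule()].
#' @param channel_ids character vector of fly/channel identifiers.
#' @param start_clock clock time of the first sample (minutes of day or
#'   `"HH:MM"`); defaults to lights-on.
#' @param start_date `Date` of the first sample (used only when writing DAM
#'   files).
#' @param status optional integer vector of per-row monitor status codes
#'   (1 = OK).
#' @return an object of class `monitor_table`.
#' @export
monitor_table <- function(counts, schedule, channel_ids = NULL,
                          start_clock = NULL, start_date = as.Date("2017-01-02"),
                          status = NULL) {
  counts <- as.matrix(counts)
  if (is.null(channel_ids)) channel_ids <- colnames(counts)
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(ncol(counts)))
  stopifnot(length(channel_ids) == ncol(counts))
  ok <- counts[!is.na(counts)]
  if (length(ok) && (any(ok < 0) || any(ok != round(ok))))
    stop("counts must be non-negative integers")
  stopifnot(inherits(schedule, "light_schedule"))
  if (is.null(start_clock)) start_clock <- schedule$lights_on
  start_clock <- parse_clock(start_clock)
  if (is.null(status)) status <- rep(1L, nrow(counts))
  stopifnot(length(status) == nrow(counts))
  colnames(counts) <- channel_ids
  structure(
    list(counts = counts, channel_ids = channel_ids, schedule = schedule,
         start_clock = start_clock, start_date = as.Date(start_date),
         status = as.integer(status)),
    class = "monitor_table")
}

#' @export
print.monitor_table <- function(x, ...) {
  cat(sprintf("<monitor_table> %d min x %d channels, %d missing row(s)\n",
              nrow(x$counts), ncol(x$counts), sum(rowSums(is.na(x$counts)) > 0)))
  print(x$schedule)
  invisible(x)
}

#' Number of minutes in a monitor table
#' @param table a [monitor_table()].
#' @export
n_minutes <- function(table) nrow(table$counts)

# Minutes of each sample since midnight of table$start_date (0-based rows).
.abs_minutes <- function(table) table$start_clock + seq_len(n_minutes(table)) - 1

#' Read a Trikinetics DAM-style monitor file
#'
#' Expects tab-delimited rows: record index, date (`"1 Jan 17"`), time
#' (`"HH:MM:SS"`), status code, then one count column per channel (the column
#' offset of the first count column is configurable for other dialects).
#' Timestamps must be strictly increasing at 1-minute spacing; gaps are filled
#' with explicit missing rows, duplicated or backward timestamps are a hard
#' error, and rows whose status is not in `ok_status` are flagged by masking
#' their counts to `NA` (the raw status codes are kept).
#'
#' @param path file path.
#' @param schedule a [light_schedule()] describing the experiment.
#' @param count_col_offset number of leading non-count columns (default 4).
#' @param ok_status integer status codes considered valid (default 1).
#' @param channel_ids optional channel names (default `ch01`, `ch02`, ...).
#' @return a [monitor_table()].
#' @export
read_dam <- function(path, schedule, count_col_offset = 4L, ok_status = 1L,
                     channel_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(monitor_table(matrix(integer(), 0, 0,
                                dimnames = list(NULL, character())),
                         schedule, channel_ids = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1)
    stop("malformed DAM file: row ", which(nf != nf[1])[1],
         " has ", nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
  if (nf[1] <= count_col_offset)
    stop("malformed DAM file: no count columns after offset ", count_col_offset)
  m <- do.call(rbind, fields)
  tm <- as.POSIXct(paste(m[, 2], m[, 3]), format = "%d %b %y %H:%M:%S", tz = "UTC")
  bad <- which(is.na(tm))
  if (length(bad)) stop("malformed DAM file: cannot parse timestamp on row ", bad[1])
  mins <- as.numeric(difftime(tm, tm[1], units = "mins"))
  if (any(mins != round(mins))) stop("timestamps are not on a whole-minute grid")
  mins <- as.integer(round(mins))
  if (anyDuplicated(mins)) stop("duplicated timestamp on row ", anyDuplicated(mins))
  if (is.unsorted(mins, strictly = TRUE)) stop("timestamps are not strictly increasing")
  status <- suppressWarnings(as.integer(m[, 4]))
  cnt <- suppressWarnings(
    matrix(as.integer(m[, (count_col_offset + 1):nf[1], drop = FALSE]),
           nrow = nrow(m)))
  badc <- which(rowSums(is.na(cnt)) > 0 & status %in% ok_status)
  if (length(badc)) stop("malformed DAM file: non-integer count on row ", badc[1])
  # expand onto the full contiguous minute grid; gaps become missing rows
  span <- mins[length(mins)] + 1L
  full <- matrix(NA_integer_, span, ncol(cnt))
  full[mins + 1L, ] <- cnt
  st <- rep(NA_integer_, span)
  st[mins + 1L] <- status
  full[!(st %in% ok_status), ] <- NA_integer_
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(ncol(full)))
  lt <- as.POSIXlt(tm[1])
  monitor_table(full, schedule, channel_ids = channel_ids,
                start_clock = lt$hour * 60 + lt$min + lt$sec / 60,
                start_date = as.Date(tm[1]), status = st)
}

#' Write a monitor table as a DAM-style file
#'
#' Inverse of [read_dam()] for the bundled dialect: counts and timestamps
#' round-trip losslessly. Rows containing missing counts are written with
#' error status 51 and zero counts (the DAM dialect has no per-channel
#' missingness), which [read_dam()] masks back to `NA`.
#'
#' @param table a [monitor_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dam <- function(table, path) {
  stopifnot(inherits(table, "monitor_table"))
  n <- n_minutes(table)
  if (n == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  t0 <- as.POSIXct(paste(table$start_date, "00:00:00"), tz = "UTC") +
    round(table$start_clock * 60)
  tm <- t0 + (seq_len(n) - 1) * 60
  miss <- rowSums(is.na(table$counts)) > 0
  status <- ifelse(miss, 51L, 1L)
  cnt <- table$counts
  cnt[is.na(cnt)] <- 0L
  lines <- paste(seq_len(n), format(tm, "%d %b %y"), format(tm, "%H:%M:%S"),
                 status,
                 apply(cnt, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Map a monitor table onto zeitgeber time
#'
#' Converts the wall-clock minute axis to ZT minutes and cycle numbers:
#' `zt_min = (clock - lights_on) mod 1440`, with the cycle index incrementing
#' at each ZT0 (cycles before the first lights-on of the start date are
#' negative). Returns a tidy per-channel table; the sum of counts is invariant
#' under the mapping.
#'
#' @param table a [monitor_table()] with a schedule.
#' @return a `data.table` with columns `channel`, `minute` (0-based offset into
#'   the recording), `zt_min`, `cycle`, `count`.
#' @export
to_zt <- function(table) {
  stopifnot(inherits(table, "monitor_table"))
  if (is.null(table$schedule)) stop("monitor table has no schedule")
  n <- n_minutes(table)
  abs_min <- .abs_minutes(table)
  rel <- abs_min - table$schedule$lights_on
  zt_min <- rel %% MIN_PER_DAY
  cycle <- as.integer(floor(rel / MIN_PER_DAY))
  data.table::data.table(
    channel = rep(table$channel_ids, each = n),
    minute = rep(seq_len(n) - 1L, times = length(table$channel_ids)),
    zt_min = rep(zt_min, times = length(table$channel_ids)),
    cycle = rep(cycle, times = length(table$channel_ids)),
    count = as.integer(table$counts))
}

# 0-based minute offset (into the recording) at which cycle c starts, and the
# cycles fully covered by the recording.
.cycle_offset <- function(table, cycle) {
  cycle * MIN_PER_DAY + table$schedule$lights_on - table$start_clock
}

#' Complete cycles present in a recording
#'
#' @param table a [monitor_table()].
#' @param regime optional regime filter (`"LD"`, `"DD"`, `"LL"`).
#' @return integer vector of cycle indices for which all 1440 minutes were
#'   recorded (missing rows still count as recorded; they are explicit).
#' @export
complete_cycles <- function(table, regime = NULL) {
  n <- n_minutes(table)
  rel <- (.abs_minutes(table)[1] - table$schedule$lights_on)
  first <- as.integer(ceiling(rel / MIN_PER_DAY))
  cyc <- integer()
  c0 <- first
  repeat {
    off <- .cycle_offset(table, c0)
    if (off + MIN_PER_DAY > n) break
    cyc <- c(cyc, c0)
    c0 <- c0 + 1L
  }
  if (!is.null(regime)) {
    reg <- vapply(cyc, function(cc) .cycle_regime(table$schedule, cc), "")
    cyc <- cyc[reg == regime]
  }
  cyc
}

.cycle_regime <- function(schedule, cycle) {
  i <- cycle + 1L
  if (i < 1 || i > length(schedule$regime))
    stop("cycle ", cycle, " is outside the declared schedule")
  schedule$regime[i]
}

#' Read an experiment manifest
#'
#' The manifest maps isofemale line ids to their region label, monitor file and
#' channels (YAML or JSON; a list of records with fields `line_id`, `region`,
#' `file`, `channels`, and optionally `sex` and `haplotype`). Every referenced
#' channel must exist in its monitor file.
#'
#' @param path YAML file path.
#' @param check_files verify monitor files/channels exist (default TRUE when
#'   files are referenced with existing paths).
#' @return a `data.table` with one row per (line, channel).
#' @export
read_manifest <- function(path, check_files = TRUE) {
  raw <- yaml::read_yaml(path)
  recs <- lapply(raw, function(r) {
    stopifnot(!is.null(r$line_id), !is.null(r$region))
    data.table::data.table(
      line_id = r$line_id,
      region = r$region,
      sex = r$sex %||% "male",
      haplotype = r$haplotype %||% NA_character_,
      file = r$file %||% NA_character_,
      channel = as.character(unlist(r$channels)))
  })
  out <- data.table::rbindlist(recs)
  if (!all(out$region %in% c("tropical", "temperate")))
    stop("region labels must be 'tropical' or 'temperate'")
  if (check_files) {
    for (f in unique(stats::na.omit(out$file))) {
      if (!file.exists(f)) stop("manifest references missing monitor file: ", f)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
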
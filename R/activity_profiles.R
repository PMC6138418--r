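# Normalized, startle-corrected daily activity profiles.
#
# Order of operations (applied per fly, before any averaging):
#   1. bin counts into 30-min bins, average over the last 3 LD cycles
#   2. startle correction: the bin right after each light transition is
#      replaced by the mean of its flanking bins
#   3. peak normalization: divide by the fly's maximum bin (so each fly's
#      profile has max exactly 1.0)
#   4. group profile = mean of the individually normalized profiles
# Correction precedes normalization so transition spikes cannot set the peak.

#' Neutralize startle responses at light transitions
#'
#' Replaces the activity value of each bin immediately following an
#' environmental light transition by the arithmetic mean of the bins just
#' before and just after it. All other bins are untouched.
#'
#' @param bins numeric vector of binned activity.
#' @param transitions indices of the bins right after a transition.
#' @param circular treat the vector as circular (daily profile); if `FALSE`,
#'   a transition bin at either edge is an error because a flanking bin is
#'   missing.
#' @return corrected copy of `bins`.
#' @export
startle_correct <- function(bins, transitions, circular = FALSE) {
  n <- length(bins)
  out <- bins
  for (i in transitions) {
    stopifnot(i >= 1, i <= n)
    if (circular) {
      lo <- if (i == 1) n else i - 1L
      hi <- if (i == n) 1L else i + 1L
    } else {
      if (i == 1 || i == n)
        stop("transition bin ", i, " is at the series edge: no flanking bin")
      lo <- i - 1L
      hi <- i + 1L
    }
    out[i] <- (bins[lo] + bins[hi]) / 2
  }
  out
}

#' Normalize a daily activity profile to its peak
#'
#' Divides every bin by the profile's maximum so the peak is exactly 1.0.
#' Normalization is applied per fly, before group averaging, and is invariant
#' to rescaling the fly's counts by any positive constant.
#'
#' @param bins numeric vector with at least one positive entry.
#' @return normalized bins, max exactly 1.
#' @export
normalize_profile <- function(bins) {
  m <- max(bins)
  if (!is.finite(m) || m <= 0) stop("profile has no positive bin; cannot normalize")
  bins / m
}

#' Group daily activity profile
#'
#' Builds the per-fly binned daily activity averaged over LD cycles, applies
#' the startle correction at the bins following lights-on (ZT0) and lights-off
#' (ZT12), normalizes each fly to its peak, and averages across flies. Flies
#' with an all-zero profile cannot be normalized; they are excluded from the
#' group mean with a warning and recorded in the `excluded` attribute.
#'
#' @param table a [monitor_table()].
#' @param bin_min bin width in minutes (default 30; must divide 720).
#' @param cycles cycles to average (default last 3 complete LD cycles).
#' @param normalize per-fly peak normalization (default TRUE).
#' @param correct_startle apply the transition correction (default TRUE).
#' @return `data.frame` with `zt_min`, `mean`, `n_flies`; attributes `per_fly`
#'   (bin x fly matrix), `peak_bin` (per-fly argmax bin, for auditing which
#'   bin set the peak) and `excluded` (channels dropped as all-zero).
#' @export
activity_profile <- function(table, bin_min = 30L, cycles = NULL,
                             normalize = TRUE, correct_startle = TRUE) {
  stopifnot(720 %% bin_min == 0)
  if (is.null(cycles)) {
    ld <- complete_cycles(table, regime = "LD")
    if (length(ld) < 3) stop("need at least 3 complete LD cycles, found ", length(ld))
    cycles <- utils::tail(ld, 3L)
  }
  nb <- MIN_PER_DAY %/% bin_min
  shift <- table$start_clock - table$schedule$lights_on
  binmat <- sapply(seq_along(table$channel_ids), function(j) {
    x <- table$counts[, j]
    acc <- numeric(nb)
    for (cc in cycles) {
      off <- cc * MIN_PER_DAY - shift   # 0-based series offset of cycle start
      idx <- off + seq_len(MIN_PER_DAY)
      day <- x[idx]
      acc <- acc + vapply(seq_len(nb), function(w)
        sum(day[((w - 1) * bin_min + 1):(w * bin_min)], na.rm = TRUE), 0)
    }
    acc / length(cycles)
  })
  binmat <- matrix(binmat, nrow = nb, dimnames = list(NULL, table$channel_ids))
  if (correct_startle) {
    trans <- c(1L, 720 %/% bin_min + 1L)  # bins right after ZT0 and ZT12
    binmat <- apply(binmat, 2, startle_correct, transitions = trans,
                    circular = TRUE)
  }
  excluded <- character()
  peak_bin <- apply(binmat, 2, which.max)
  if (normalize) {
    allzero <- apply(binmat, 2, function(b) max(b) <= 0)
    if (any(allzero)) {
      excluded <- colnames(binmat)[allzero]
      warning("excluding all-zero profile(s): ", paste(excluded, collapse = ", "))
      binmat <- binmat[, !allzero, drop = FALSE]
      peak_bin <- peak_bin[!allzero]
    }
    binmat <- apply(binmat, 2, normalize_profile)
    binmat <- matrix(binmat, nrow = nb)
  }
  out <- data.frame(zt_min = seq(0, MIN_PER_DAY - bin_min, by = bin_min),
                    mean = rowMeans(binmat), n_flies = ncol(binmat))
  attr(out, "per_fly") <- binmat
  attr(out, "peak_bin") <- peak_bin
  attr(out, "excluded") <- excluded
  out
}
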
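# Independent oracle implementations used to cross-check the package: each is
# deliberately written on a different code path than the function it checks.

# Zero-run scanner: collects zero positions and splits them at gaps, rather
# than run-length encoding the state vector.
oracle_bouts <- function(x, thr = 5) {
  zeros <- which(!is.na(x) & x == 0)
  empty <- data.frame(start = integer(), end = integer(), duration_min = integer())
  if (!length(zeros)) return(empty)
  grp <- cumsum(c(1L, diff(zeros) != 1L))
  runs <- lapply(split(zeros, grp), function(z)
    data.frame(start = z[1] - 1L, end = z[length(z)],
               duration_min = length(z)))
  out <- do.call(rbind, runs)
  touches_na <- vapply(seq_len(nrow(out)), function(i) {
    s <- out$start[i]; e <- out$end[i]
    (s > 0 && is.na(x[s])) || (e < length(x) && is.na(x[e + 1]))
  }, TRUE)
  out <- out[out$duration_min >= thr & !touches_na, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive per-bout, per-window clipping (double loop).
oracle_clip <- function(bouts, edges) {
  rows <- list()
  for (b in seq_len(nrow(bouts))) {
    for (w in seq_len(length(edges) - 1)) {
      s <- max(bouts$start[b], edges[w])
      e <- min(bouts$end[b], edges[w + 1])
      if (e > s)
        rows[[length(rows) + 1]] <- data.frame(window = w, duration_min = e - s)
    }
  }
  if (!length(rows)) return(data.frame(window = integer(), duration_min = numeric()))
  do.call(rbind, rows)
}

# Hypergeometric tail by direct enumeration with choose().
oracle_fisher <- function(m, alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pk <- vapply(ks, function(k)
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1), 0)
  if (alternative == "one.sided") sum(pk[ks >= a])
  else sum(pk[pk <= pk[ks == a] * (1 + 1e-7)])
}

# One-sided permutation test on the difference of means.
oracle_perm_t <- function(a, b, n_perm = 1e4) {
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  stat <- replicate(n_perm, {
    i <- sample.int(length(pool), na)
    mean(pool[i]) - mean(pool[-i])
  })
  mean(stat >= obs)
}

# Minute-grid daily sleep profile: paints each bout onto a minute indicator.
oracle_profile <- function(bouts_by_fly, cycles, bin_min = 30) {
  nb <- 1440 %/% bin_min
  mats <- sapply(bouts_by_fly, function(b) {
    acc <- numeric(nb)
    for (cc in cycles) {
      asleep <- rep(FALSE, 1440)
      for (i in seq_len(nrow(b))) {
        s <- max(b$start[i], cc * 1440) - cc * 1440
        e <- min(b$end[i], (cc + 1) * 1440) - cc * 1440
        if (e > s) asleep[(s + 1):e] <- TRUE
      }
      acc <- acc + vapply(seq_len(nb), function(w)
        sum(asleep[((w - 1) * bin_min + 1):(w * bin_min)]), 0)
    }
    acc / length(cycles)
  })
  rowMeans(matrix(mats, nrow = nb))
}

# Random bout set on [0, span): disjoint, sorted.
random_bouts <- function(n, span = 1440) {
  pts <- sort(sample.int(span, 2 * n))
  data.frame(start = pts[seq(1, 2 * n, 2)], end = pts[seq(2, 2 * n, 2)])
}

# A tiny DAM-dialect file from a counts matrix, on a fixed date.
write_toy_dam <- function(counts, path, start = "2017-01-02 08:00:00",
                          status = rep(1L, nrow(counts))) {
  tm <- as.POSIXct(start, tz = "UTC") + (seq_len(nrow(counts)) - 1) * 60
  lines <- paste(seq_len(nrow(counts)), format(tm, "%d %b %y"),
                 format(tm, "%H:%M:%S"), status,
                 apply(counts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path)
  path
}
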
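# Stochastic generators standing in for the study's raw material: activity
# monitor records, per 3' UTR sequences, and gel band intensities.
#
# Activity model: a two-state (wake/sleep) semi-Markov process per fly on the
# 1-minute grid. While awake, the per-minute sleep-onset hazard is
#     h(phase) = siesta_propensity * f_mid(phase) + night_hazard * f_night(phase)
# where f_mid is a von-Mises-shaped mid-day bump (peak ZT6, max 1) and
# f_night a smooth night indicator; sleep-bout lengths are geometric (support
# 1, 2, ...) with day/night-specific means; awake minutes emit
# Poisson(wake_rate * A(phase)) counts, where A is a bimodal activity template
# (morning and evening peaks over a positive floor, normalized to mean 1). A
# startle spike (startle_gain * wake_rate extra Poisson intensity) hits the
# minute right after each LD light transition. In DD the templates free-run at
# free_run_period_h; in LL the circadian modulation is abolished and the
# daily-mean hazard/rate apply uniformly. Geometric bout lengths and the
# template shapes are modelling conventions, not claims about the fly.

.vm_bump <- function(phase_min, peak_min, kappa) {
  exp(kappa * (cos(2 * pi * (phase_min - peak_min) / MIN_PER_DAY) - 1))
}

.night_weight <- function(phase_min) {
  stats::plogis((phase_min - 730) / 15) * stats::plogis((1435 - phase_min) / 15)
}

.activity_template <- function(phase_min) {
  raw <- 0.7 + 1.6 * .vm_bump(phase_min, 60, 8) + 2.2 * .vm_bump(phase_min, 690, 8)
  raw / mean(0.7 + 1.6 * .vm_bump(0:1439, 60, 8) + 2.2 * .vm_bump(0:1439, 690, 8))
}

#' Default simulation parameters for a regional population
#'
#' Encodes the qualitative contrasts of the study populations as parameter
#' differences: tropical flies have a stronger mid-day sleep propensity and
#' longer sleep bouts; temperate flies have shorter, more frequent bouts with
#' night totals kept comparable via a higher night onset hazard. The siesta
#' propensity rises with holding temperature (piecewise-linear through the
#' three test temperatures) while the night hazard falls slightly, matching
#' the direction of the published temperature effects. Defaults are calibrated
#' so the tropical-vs-temperate day-sleep ordering is recoverable at the study
#' scale (8 lines x 16 flies per region).
#'
#' @param region `"tropical"` or `"temperate"`.
#' @param temperature_C holding temperature (degrees C, default 25).
#' @return list of class `sim_params`: `siesta_propensity` (per-minute onset
#'   probability scale, in `[0,1]`), `night_hazard` (idem),
#'   `mean_sleep_bout_day`/`..._night` (minutes), `wake_rate` (expected
#'   counts/min while awake), `startle_gain`, `free_run_period_h`, plus the
#'   region/temperature labels.
#' @export
sim_params <- function(region = c("tropical", "temperate"), temperature_C = 25) {
  region <- match.arg(region)
  temp_gain <- stats::approx(c(18, 25, 29), c(0.60, 1.00, 1.30),
                             xout = temperature_C, rule = 2)$y
  night_gain <- stats::approx(c(18, 25, 29), c(1.15, 1.00, 0.90),
                              xout = temperature_C, rule = 2)$y
  p <- if (region == "tropical") {
    list(siesta_propensity = 0.030 * temp_gain, night_hazard = 0.075 * night_gain,
         mean_sleep_bout_day = 25, mean_sleep_bout_night = 40)
  } else {
    list(siesta_propensity = 0.015 * temp_gain, night_hazard = 0.120 * night_gain,
         mean_sleep_bout_day = 15, mean_sleep_bout_night = 25)
  }
  p$wake_rate <- 2.0
  p$startle_gain <- 10
  p$free_run_period_h <- 24.0
  p$region <- region
  p$temperature_C <- temperature_C
  .validate_params(p)
  structure(p, class = "sim_params")
}

.validate_params <- function(p) {
  stopifnot(p$siesta_propensity >= 0, p$siesta_propensity <= 1,
            p$night_hazard >= 0, p$night_hazard <= 1,
            p$mean_sleep_bout_day >= 1, p$mean_sleep_bout_night >= 1,
            p$wake_rate >= 0, p$startle_gain >= 0,
            p$free_run_period_h >= 18, p$free_run_period_h <= 30)
  invisible(p)
}

#' Multiplicative line-to-line jitter of simulation parameters
#'
#' Applies independent lognormal factors (unit mean, coefficient of variation
#' `cv`) to the siesta propensity, night hazard and bout-length means,
#' emulating between-isofemale-line variability.
#'
#' @param params a [sim_params()] list.
#' @param cv coefficient of variation of the lognormal factors.
#' @return perturbed copy of `params`.
#' @export
jitter_params <- function(params, cv = 0.1) {
  if (cv == 0) return(params)
  s <- sqrt(log(1 + cv^2))
  f <- stats::rlnorm(4, meanlog = -s^2 / 2, sdlog = s)
  params$siesta_propensity <- min(1, params$siesta_propensity * f[1])
  params$night_hazard <- min(1, params$night_hazard * f[2])
  params$mean_sleep_bout_day <- max(1, params$mean_sleep_bout_day * f[3])
  params$mean_sleep_bout_night <- max(1, params$mean_sleep_bout_night * f[4])
  params
}

# Per-minute circadian phase (ZT-equivalent minutes) and regime label for a
# schedule of days_ld LD days followed by DD and/or LL days.
.phase_and_regime <- function(days_ld, days_dd, days_ll, free_run_period_h) {
  regime <- rep(c("LD", "DD", "LL"), times = c(days_ld, days_dd, days_ll) * MIN_PER_DAY)
  n <- length(regime)
  phase <- numeric(n)
  t_ld <- days_ld * MIN_PER_DAY
  if (t_ld > 0) phase[seq_len(t_ld)] <- (seq_len(t_ld) - 1) %% MIN_PER_DAY
  rest <- which(regime != "LD")
  if (length(rest)) {
    # free-run from the phase at the end of entrainment (ZT0 if no LD days)
    phase0 <- if (t_ld > 0) t_ld %% MIN_PER_DAY else 0
    elapsed <- seq_along(rest) - 1
    phase[rest] <- (phase0 + elapsed * 24 / free_run_period_h) %% MIN_PER_DAY
  }
  list(phase = phase, regime = regime)
}

#' Simulate beam-crossing records for one line of flies
#'
#' Generates a [monitor_table()] of `n_flies` channels plus a ground-truth log
#' of every true sleep interval and the per-minute hazard/rate templates.
#' See the model description at the top of this file.
#'
#' @param params a [sim_params()] list (or a plain list with the same fields).
#' @param n_flies number of flies (> 0).
#' @param days_ld,days_dd,days_ll days per regime, in that order.
#' @param seed RNG seed for this line.
#' @param min_wake_count if > 0, awake minutes emit at least this many counts
#'   (`max(Poisson draw, min_wake_count)`), making sleep annotation on the
#'   output exact against the truth log; 0 (default) keeps pure Poisson
#'   emission, in which occasional zero-count wake minutes can masquerade as
#'   sleep.
#' @return list: `table` (a [monitor_table()]), `truth` (data.table `channel`,
#'   `start`, `end`, `duration_min` — true sleep intervals, 0-based half-open
#'   minutes, adjacent intervals merged), `hazard`, `rate` (per-minute
#'   templates).
#' @export
simulate_activity <- function(params, n_flies = 16, days_ld = 5, days_dd = 0,
                              days_ll = 0, seed = 0, min_wake_count = 0) {
  if (n_flies < 1) stop("need at least one fly")
  .validate_params(params)
  total_days <- days_ld + days_dd + days_ll
  stopifnot(total_days >= 1)
  set.seed(seed)
  pr <- .phase_and_regime(days_ld, days_dd, days_ll, params$free_run_period_h)
  n <- length(pr$phase)
  f_mid <- .vm_bump(pr$phase, 360, 2)
  f_night <- .night_weight(pr$phase)
  act <- .activity_template(pr$phase)
  hazard <- params$siesta_propensity * f_mid + params$night_hazard * f_night
  rate <- params$wake_rate * act
  ll <- pr$regime == "LL"
  if (any(ll)) {
    hazard[ll] <- mean(params$siesta_propensity * .vm_bump(0:1439, 360, 2) +
                         params$night_hazard * .night_weight(0:1439))
    rate[ll] <- params$wake_rate
  }
  hazard <- pmin(hazard, 1)
  is_day_phase <- pr$phase < 720
  bout_mean <- ifelse(is_day_phase, params$mean_sleep_bout_day,
                      params$mean_sleep_bout_night)
  # minutes right after LD light transitions (transition at ZT0 and ZT12)
  startle_idx <- which(pr$regime == "LD" & (pr$phase == 0 | pr$phase == 720))
  counts <- matrix(0L, n, n_flies)
  truth <- vector("list", n_flies)
  for (f in seq_len(n_flies)) {
    onsets <- which(stats::runif(n) < hazard)
    asleep <- rep(FALSE, n)
    st <- en <- integer(0)
    i <- 1L
    t <- 1L
    while (i <= length(onsets)) {
      if (onsets[i] < t) { i <- i + 1L; next }
      s <- onsets[i]
      dur <- 1L + stats::rgeom(1, 1 / bout_mean[s])
      e <- min(s + dur, n + 1L)
      asleep[s:(e - 1L)] <- TRUE
      st <- c(st, s); en <- c(en, e)
      t <- e
      i <- i + 1L
    }
    x <- stats::rpois(n, rate)
    if (length(startle_idx))
      x[startle_idx] <- x[startle_idx] +
        stats::rpois(length(startle_idx), params$startle_gain * params$wake_rate)
    if (min_wake_count > 0) x <- pmax(x, as.integer(min_wake_count))
    x[asleep] <- 0L
    counts[, f] <- x
    if (length(st)) {
      # merge adjacent true intervals (behaviourally one bout)
      keep <- c(TRUE, st[-1] != en[-length(en)])
      grp <- cumsum(keep)
      truth[[f]] <- data.table::data.table(
        channel = sprintf("fly%02d", f),
        start = tapply(st, grp, min) - 1L,
        end = tapply(en, grp, max) - 1L)
    }
  }
  truth <- data.table::rbindlist(truth[!vapply(truth, is.null, TRUE)])
  if (nrow(truth)) truth$duration_min <- truth$end - truth$start
  sched <- light_schedule(lights_on = 480,
                          regime = rep(c("LD", "DD", "LL"),
                                       times = c(days_ld, days_dd, days_ll)),
                          temperature_C = params$temperature_C %||% 25)
  tab <- monitor_table(counts, sched,
                       channel_ids = sprintf("fly%02d", seq_len(n_flies)),
                       start_clock = 480)
  list(table = tab, truth = truth, hazard = hazard, rate = rate)
}

#' Simulate a two-region cohort of isofemale lines
#'
#' Runs [simulate_activity()] for `n_lines` lines per region with line-level
#' parameter jitter, at the study's default scale (8 lines x 16 flies per
#' region).
#'
#' @param n_lines lines per region.
#' @param n_flies flies per line.
#' @param temperature_C holding temperature.
#' @param days_ld,days_dd,days_ll days per regime.
#' @param line_cv coefficient of variation of line-level parameter jitter.
#' @param seed master seed; line seeds are derived from it.
#' @return list of per-line entries (`line_id`, `region`, `sim` =
#'   [simulate_activity()] output).
#' @export
simulate_cohort <- function(n_lines = 8, n_flies = 16, temperature_C = 25,
                            days_ld = 5, days_dd = 0, days_ll = 0,
                            line_cv = 0.1, seed = 0) {
  out <- list()
  k <- 0L
  for (region in c("tropical", "temperate")) {
    for (l in seq_len(n_lines)) {
      k <- k + 1L
      line_seed <- (seed * 1009L + k * 7919L) %% .Machine$integer.max
      set.seed(line_seed)
      p <- jitter_params(sim_params(region, temperature_C), cv = line_cv)
      sim <- simulate_activity(p, n_flies = n_flies, days_ld = days_ld,
                               days_dd = days_dd, days_ll = days_ll,
                               seed = (line_seed + 1L) %% .Machine$integer.max)
      out[[k]] <- list(line_id = sprintf("%s%02d", substr(region, 1, 4), l),
                       region = region, sim = sim)
    }
  }
  out
}

#' Simulate per 3' UTR sequences for a cohort of lines
#'
#' Writes one 497-bp record per line on the synthetic reference backbone: the
#' alleles at the six scored sites are set according to the line's haplotype,
#' everything else (including the dmpi8 splice-site substrings) is identical
#' across records. Record ids are `<line>|<region>`.
#'
#' In `"deterministic"` mode the per-region haplotype counts of
#' [australian_haplotypes()] are allocated exactly (no RNG), reproducing the
#' published class-by-region table. In `"stochastic"` mode each line draws its
#' haplotype from per-region frequency vectors.
#'
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param freqs for stochastic mode: named list `tropical`/`temperate` of
#'   haplotype-frequency vectors (each must sum to 1; names must be haplotype
#'   labels of `haplotypes`).
#' @param n_lines for stochastic mode: named vector of lines per region.
#' @param haplotypes haplotype definition table ([australian_haplotypes()]).
#' @param reference a [utr_reference()].
#' @param seed RNG seed (stochastic mode).
#' @return list: `fasta` (`Biostrings::DNAStringSet`), `truth` (data.frame
#'   `line_id`, `region`, `haplotype`).
#' @export
simulate_utr_fasta <- function(mode = c("deterministic", "stochastic"),
                               freqs = NULL, n_lines = NULL,
                               haplotypes = australian_haplotypes(),
                               reference = utr_reference(), seed = 0) {
  mode <- match.arg(mode)
  if (mode == "deterministic") {
    assign_tab <- do.call(rbind, lapply(c("tropical", "temperate"), function(r) {
      nn <- haplotypes[[paste0("n_", r)]]
      data.frame(region = r, haplotype = rep(haplotypes$haplotype, nn),
                 stringsAsFactors = FALSE)
    }))
  } else {
    stopifnot(is.list(freqs), !is.null(n_lines))
    set.seed(seed)
    assign_tab <- do.call(rbind, lapply(names(freqs), function(r) {
      fv <- freqs[[r]]
      if (abs(sum(fv) - 1) > 1e-8)
        stop("haplotype frequencies for region '", r, "' do not sum to 1")
      stopifnot(all(names(fv) %in% haplotypes$haplotype))
      data.frame(region = r,
                 haplotype = sample(names(fv), n_lines[[r]], replace = TRUE,
                                    prob = fv),
                 stringsAsFactors = FALSE)
    }))
  }
  assign_tab$line_id <- stats::ave(seq_len(nrow(assign_tab)), assign_tab$region,
                                   FUN = seq_along)
  assign_tab$line_id <- sprintf("%s%02d", substr(assign_tab$region, 1, 4),
                                assign_tab$line_id)
  refchars <- strsplit(reference$seq, "")[[1]]
  hidx <- match(assign_tab$haplotype, haplotypes$haplotype)
  seqs <- vapply(seq_len(nrow(assign_tab)), function(i) {
    s <- refchars
    s[reference$snps$offset + 1] <-
      unlist(haplotypes[hidx[i], HAPLO_SITES], use.names = FALSE)
    paste(s, collapse = "")
  }, "")
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- paste(assign_tab$line_id, assign_tab$region, sep = "|")
  list(fasta = dss,
       truth = assign_tab[, c("line_id", "region", "haplotype")])
}

#' Simulate gel band intensities for a splicing assay point
#'
#' Intensities follow `spliced = scale * level * eff * e1`,
#' `unspliced = scale * level * (1 - eff) * e2`, `cbp20 = scale * e3`, with
#' independent unit-mean lognormal noise factors of coefficient of variation
#' `noise_cv`. At `noise_cv = 0` the efficiency inverts exactly.
#'
#' @param true_efficiency splicing efficiency in `[0, 1]`.
#' @param dper_level relative transcript abundance (> 0).
#' @param noise_cv noise coefficient of variation (>= 0).
#' @param n number of replicate points.
#' @param scale arbitrary intensity scale.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return data.frame with `spliced`, `unspliced`, `cbp20`.
#' @export
simulate_gel <- function(true_efficiency, dper_level = 1, noise_cv = 0, n = 1,
                         scale = 1000, seed = NULL) {
  if (true_efficiency < 0 || true_efficiency > 1)
    stop("true_efficiency must be in [0, 1]")
  stopifnot(dper_level > 0, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(log(1 + noise_cv^2))
  eps <- function() if (noise_cv == 0) rep(1, n) else
    stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
  data.frame(
    spliced = scale * dper_level * true_efficiency * eps(),
    unspliced = scale * dper_level * (1 - true_efficiency) * eps(),
    cbp20 = scale * eps())
}
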
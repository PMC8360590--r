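#' Detect troughs (or peaks) of a rhythmic count series
#'
#' Smooths the series with a centered moving average, scans for local
#' minima, and enforces a minimum spacing between troughs by keeping the
#' deeper of any conflicting pair. Circadian periods are defined as the
#' intervals between successive troughs of nuclear protein.
#'
#' @param x numeric series sampled on a uniform grid.
#' @param dt grid spacing, hours.
#' @param smooth_window moving-average window, hours (default 4).
#' @param min_separation minimum spacing between reported troughs, hours
#'   (default 15, safely below a circadian period).
#' @param times optional time stamps (default `seq(0, by = dt, ...)`).
#' @return Numeric vector of trough times (empty for a constant series).
#' @examples
#' t <- seq(0, 200, by = 0.5)
#' detect_troughs(cos(2 * pi * t / 24), dt = 0.5) # ~12, 36, 60, ...
#' @export
detect_troughs <- function(x, dt, smooth_window = 4, min_separation = 15,
                           times = NULL) {
  stopifnot(dt > 0, length(x) * dt > 2 * min_separation)
  if (is.null(times)) times <- seq(0, by = dt, length.out = length(x))
  w <- max(1L, round(smooth_window / dt))
  if (w %% 2 == 0) w <- w + 1L
  s <- if (w > 1) as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) else x
  ok <- !is.na(s)
  s <- s[ok]
  tt <- times[ok]
  if (length(s) < 3 || diff(range(s)) == 0) return(numeric(0))
  idx <- local_extrema(s)
  idx <- idx[s[idx] < (s[pmax(idx - 1, 1)] + s[pmin(idx + 1, length(s))]) / 2]
  if (!length(idx)) return(numeric(0))
  # greedy pruning, deepest troughs first
  ord <- idx[order(s[idx])]
  kept <- numeric(0)
  for (i in ord)
    if (!length(kept) || all(abs(tt[i] - kept) >= min_separation))
      kept <- c(kept, tt[i])
  sort(kept)
}

#' @rdname detect_troughs
#' @export
detect_peaks <- function(x, dt, smooth_window = 4, min_separation = 15,
                         times = NULL) {
  detect_troughs(-x, dt, smooth_window, min_separation, times)
}

#' Tally transcription events per compartment over circadian periods
#'
#' Counts, for each trough-to-trough period, how many transcription events
#' each compartment's nucleus contributed, and summarizes the division of
#' labor: the fraction of periods where one compartment out-transcribes the
#' other more than two-fold (two-compartment case), and per-period fractions
#' attributed to the designated "smaller" compartment.
#'
#' @param events event log `data.frame` (`time`, `channel`, `compartment`)
#'   from [run_ssa()] with logging enabled; only `transcription` rows are
#'   used.
#' @param troughs trough times delimiting periods (e.g. from
#'   [detect_troughs()]), or a two-column `start`/`end` structure.
#' @param N number of compartments.
#' @param smaller index of the compartment whose transcription share is
#'   reported; defaults to the shortest compartment when `lengths` is given,
#'   else compartment 2 by convention.
#' @param lengths optional compartment lengths used to pick `smaller`.
#' @return Object of class `period_stats`: list with `periods` (start/end),
#'   `counts` (periods x compartments), `skew_fraction`,
#'   `fraction_smaller` (per period), and `mean_fraction_smaller`.
#' @export
tally_transcription <- function(events, troughs, N, smaller = NULL,
                                lengths = NULL) {
  if (is.null(dim(troughs))) {
    troughs <- sort(as.numeric(troughs))
    if (length(troughs) < 2) stop("need at least two troughs to form a period")
    periods <- cbind(start = head(troughs, -1), end = tail(troughs, -1))
  } else {
    periods <- as.matrix(troughs)
    if (!nrow(periods)) stop("empty period set")
  }
  tx <- events[as.character(events$channel) == "transcription", , drop = FALSE]
  nper <- nrow(periods)
  counts <- matrix(0L, nper, N)
  pi_ <- findInterval(tx$time, periods[, 1])
  inside <- pi_ >= 1 & pi_ <= nper
  inside[inside] <- tx$time[inside] < periods[pi_[inside], 2]
  tab <- table(factor(pi_[inside], levels = seq_len(nper)),
               factor(tx$compartment[inside], levels = seq_len(N)))
  counts[] <- as.integer(tab)
  if (is.null(smaller)) {
    smaller <- if (!is.null(lengths) &&
                   diff(range(lengths)) > 1e-12 * max(lengths))
      which.min(lengths) else min(2L, N)
  }
  tot <- rowSums(counts)
  frac <- ifelse(tot > 0, counts[, smaller] / tot, NA_real_)
  skew <- if (N == 2) {
    hi <- pmax(counts[, 1], counts[, 2])
    lo <- pmin(counts[, 1], counts[, 2])
    mean(hi > 2 * lo)
  } else NA_real_
  structure(list(periods = periods, counts = counts,
                 skew_fraction = skew, smaller = smaller,
                 fraction_smaller = frac,
                 mean_fraction_smaller = mean(frac, na.rm = TRUE)),
            class = "period_stats")
}

#' @export
print.period_stats <- function(x, ...) {
  cat(sprintf("Division-of-labor tally: %d periods, %d compartments\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.na(x$skew_fraction))
    cat(sprintf("  periods with >2-fold transcription skew: %.1f%%\n",
                100 * x$skew_fraction))
  cat(sprintf("  mean transcript fraction in compartment %d: %.3f\n",
              x$smaller, x$mean_fraction_smaller))
  invisible(x)
}

#' Run a division-of-labor simulation and tally it
#'
#' Convenience pipeline: simulate, segment circadian periods by troughs of
#' total nuclear protein, and tally per-compartment transcription with
#' [tally_transcription()].
#'
#' @param model a [clock_model()] (typically two compartments).
#' @param t_end simulated hours (the reference analyses use 10000 h,
#'   about 400 periods).
#' @param seed integer seed.
#' @param dt_sample sampling grid, hours.
#' @param smooth_window,min_separation trough-detection settings, hours.
#' @param ... passed to [run_ssa()].
#' @return A `period_stats` object (see [tally_transcription()]); the
#'   trajectory is attached as attribute `trajectory`.
#' @export
division_of_labor <- function(model, t_end = 10000, seed = NULL,
                              dt_sample = 0.5, smooth_window = 4,
                              min_separation = 15, ...) {
  traj <- run_ssa(model, t_end = t_end, seed = seed, dt_sample = dt_sample,
                  log = "transcription", ...)
  total_pn <- rowSums(traj$pn)
  troughs <- detect_troughs(total_pn, dt_sample, smooth_window,
                            min_separation)
  stats <- tally_transcription(traj$events, troughs, model$geometry$N,
                               lengths = model$geometry$lengths)
  attr(stats, "trajectory") <- traj
  stats
}

#' Default initial counts for the synchronization experiment
#'
#' Integer per-compartment counts at the first nuclear-protein trough of the
#' deterministic (single-compartment) trajectory, i.e. a state on the cycle
#' where all nuclei start synchronized at their protein minimum.
#'
#' @param model a [clock_model()]; only its rates are used.
#' @return Named integer vector `c(mn, mc, pc, pn)` (per compartment).
#' @export
consistency_default_init <- function(model) {
  one <- clock_model(alpha = model$alpha, beta = model$beta,
                     gamma_m = model$gamma_m, gamma_p = model$gamma_p,
                     delta_m = model$delta_m, delta_p = model$delta_p,
                     K = model$K, r = model$r, V_n = model$V_n,
                     V_c = model$V_c, N = 1)
  traj <- solve_deterministic(one, t_end = 200, dt_out = 0.1)
  pn <- traj$Pn[, 1]
  ext <- local_extrema(pn)
  mins <- ext[pn[ext] < (pn[ext - 1] + pn[ext + 1]) / 2]
  maxs <- setdiff(ext, mins)
  if (!length(maxs) || !any(mins > maxs[1]))
    stop("no deterministic trough found; supply init explicitly")
  i <- mins[mins > maxs[1]][1]
  c(mn = round(traj$Mn[i, 1] * model$V_n),
    mc = round(traj$Mc[i, 1] * model$V_c),
    pc = round(traj$Pc[i, 1] * model$V_c),
    pn = round(traj$Pn[i, 1] * model$V_n))
}

#' Peak-time consistency: protein-sharing vs independent nuclei
#'
#' Compares circadian timekeeping in a syncytium whose compartments share
#' cytoplasmic protein (the standard model) against the same compartments
#' run with redistribution disabled. Every trial starts from identical
#' per-compartment counts; per trial, peaks of *total* nuclear protein are
#' detected, each trial's first peak defines its time zero, and the standard
#' deviation of each subsequent day's peak time across trials measures
#' timing consistency.
#'
#' The primary `sigma[i]` (day `i = 1..n_days`) is computed on peaks
#' `2..(n_days+1)` after alignment, so day 1 already shows spread; the
#' variant including the alignment peak itself (whose sd is 0 by
#' construction) is returned as `sigma_incl`.
#'
#' @param model a [clock_model()]; default an 8-compartment uniform cell at
#'   the model's low transcription rate.
#' @param n_trials trials per scenario (default 100).
#' @param seed base seed; the two scenarios use disjoint seed blocks.
#' @param init named counts `c(mn, mc, pc, pn)` applied to every
#'   compartment; default [consistency_default_init()].
#' @param n_days circadian days tracked (default 5).
#' @param t_end simulated hours per trial (default covers `n_days` + slack).
#' @param dt_sample,smooth_window,min_separation peak-detection settings.
#' @return Object of class `consistency_result`: per-scenario list with the
#'   aligned `peak_times` matrix (trials x days), `sigma`, `sigma_incl`,
#'   `mean_day_length`, and `n_excluded` (trials with too few peaks), plus
#'   the shared `init`.
#' @export
consistency_experiment <- function(model = clock_model(alpha = 18, N = 8),
                                   n_trials = 100, seed = 1, init = NULL,
                                   n_days = 5, t_end = 28 * (n_days + 2),
                                   dt_sample = 0.5, smooth_window = 4,
                                   min_separation = 15) {
  stopifnot(inherits(model, "clock_model"))
  if (is.null(init)) init <- consistency_default_init(model)
  N <- model$geometry$N
  state <- clock_state(mn = init[["mn"]], mc = init[["mc"]],
                       pc = init[["pc"]], pn = init[["pn"]], N = N)
  run_scenario <- function(share, seed0) {
    peaks <- matrix(NA_real_, n_trials, n_days + 1L)
    excluded <- 0L
    for (k in seq_len(n_trials)) {
      tr <- run_ssa(model, t_end = t_end, seed = seed0 + k - 1L,
                    dt_sample = dt_sample, init = state, share = share)
      pk <- detect_peaks(rowSums(tr$pn), dt_sample, smooth_window,
                         min_separation)
      if (length(pk) < n_days + 1L) { excluded <- excluded + 1L; next }
      peaks[k, ] <- pk[seq_len(n_days + 1L)]
    }
    ok <- stats::complete.cases(peaks)
    aligned <- peaks[ok, , drop = FALSE] - peaks[ok, 1]
    list(peak_times = aligned[, -1, drop = FALSE],
         sigma = apply(aligned[, -1, drop = FALSE], 2, sd),
         sigma_incl = apply(aligned[, seq_len(n_days), drop = FALSE], 2, sd),
         mean_day_length = mean(diff(t(aligned))),
         n_excluded = excluded)
  }
  out <- list(coupled = run_scenario(TRUE, seed),
              independent = run_scenario(FALSE, seed + n_trials),
              init = init, n_trials = n_trials, model = model)
  class(out) <- "consistency_result"
  out
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("Peak-time consistency, %d trials per scenario, init (mn=%d, mc=%d, pc=%d, pn=%d)\n",
              x$n_trials, x$init[["mn"]], x$init[["mc"]], x$init[["pc"]],
              x$init[["pn"]]))
  for (sc in c("coupled", "independent")) {
    r <- x[[sc]]
    cat(sprintf("  %-11s sigma (h): %s; mean day %.1f h; excluded %d\n", sc,
                paste(sprintf("%.2f", r$sigma), collapse = ", "),
                r$mean_day_length, r$n_excluded))
  }
  invisible(x)
}
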
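CHANNELS <- c("transcription", "export", "mrna_decay", "translation",
              "import", "protein_decay")

#' Exact stochastic simulation of the compartmentalized oscillator
#'
#' Runs the Gillespie algorithm on the six-channel-per-compartment reaction
#' network: exponential waiting times at the total propensity, channel chosen
#' proportionally to its propensity. Whenever the cytoplasmic protein pool
#' changes through translation or nuclear import, the pool is redistributed
#' across compartments (see [redistribute()]); with `share = FALSE` the
#' redistribution is disabled and each compartment keeps only its own
#' proteins (the "independent nuclei" scenario).
#'
#' Counts are sampled on a uniform grid, right-continuously: the value at
#' grid time `t` is the state after the last event at or before `t`.
#' Identical `(model, init, seed)` give bit-identical trajectories.
#'
#' @param model a [clock_model()].
#' @param t_end simulated time, hours.
#' @param seed integer seed for this trial (`NULL` continues the current RNG
#'   stream).
#' @param dt_sample sampling grid spacing, hours (default 0.5, comfortably
#'   above the Nyquist requirement for circadian frequencies).
#' @param init a [clock_state()] or list of count vectors; default all zero.
#' @param log which events to record: `"none"` (fastest), `"transcription"`
#'   (enough for division-of-labor tallies), or `"all"`.
#' @param share redistribute cytoplasmic protein across compartments
#'   (`TRUE`, the syncytial model) or keep compartments independent.
#' @param method redistribution rule, see [redistribute()].
#' @return Object of class `clock_trajectory`: list with `times`, integer
#'   count matrices `mn`, `mc`, `pc`, `pn` (rows = grid times, columns =
#'   compartments), `events` (data.frame `time`, `channel`, `compartment`,
#'   or `NULL`), the `model`, `init`, `seed`, and `n_events`.
#' @examples
#' m <- clock_model(alpha = 18, N = 2)
#' tr <- run_ssa(m, t_end = 200, seed = 1, log = "transcription")
#' @export
run_ssa <- function(model, t_end = 1000, seed = NULL, dt_sample = 0.5,
                    init = NULL, log = c("none", "transcription", "all"),
                    share = TRUE,
                    method = c("largest_remainder", "multinomial")) {
  stopifnot(inherits(model, "clock_model"), t_end > 0, dt_sample > 0)
  log <- match.arg(log)
  method <- match.arg(method)
  g <- model$geometry
  if (is.null(init)) init <- clock_state(N = g$N)
  init <- validate_state(init, g$N)
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- ssa_run_cpp(model$alpha, model$beta, model$gamma_m, model$gamma_p,
                     model$delta_m, model$delta_p, model$K, model$r,
                     model$V_n, g$weights, g$uniform, share,
                     match(method, c("largest_remainder", "multinomial")) - 1L,
                     init$mn, init$mc, init$pc, init$pn,
                     t_end, dt_sample, match(log, c("none", "transcription",
                                                    "all")) - 1L)
  events <- if (log == "none") NULL else
    data.frame(time = res$ev_time,
               channel = factor(CHANNELS[res$ev_channel], levels = CHANNELS),
               compartment = res$ev_compartment)
  structure(
    list(times = seq(0, by = dt_sample, length.out = nrow(res$pn)),
         mn = res$mn, mc = res$mc, pc = res$pc, pn = res$pn,
         events = events, model = model, init = init, seed = seed,
         t_end = t_end, dt_sample = dt_sample, share = share,
         method = method, n_events = res$n_events),
    class = "clock_trajectory")
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat(sprintf(
    "Stochastic clock trajectory: N = %d, %.4g h, %s events%s, seed %s\n",
    ncol(x$pn), x$t_end, format(x$n_events, big.mark = ","),
    if (x$share) "" else " (independent compartments)",
    if (is.null(x$seed)) "<stream>" else x$seed))
  invisible(x)
}

#' @export
plot.clock_trajectory <- function(x, variable = "pn", ...) {
  graphics::matplot(x$times, x[[variable]], type = "s", lty = 1,
                    xlab = "time (h)", ylab = paste(variable, "(molecules)"),
                    ...)
  invisible(x)
}

#' Simulate replicate stochastic trajectories
#'
#' `simulate()` method for [clock_model()] objects: runs `nsim` independent
#' [run_ssa()] trials with per-trial seeds `seed + 0:(nsim-1)`.
#'
#' @param object a [clock_model()].
#' @param nsim number of trials.
#' @param seed base integer seed; trial `k` uses `seed + k - 1`.
#' @param ... passed to [run_ssa()] (`t_end`, `dt_sample`, `init`, `log`,
#'   `share`, `method`).
#' @return Object of class `clock_sims`: a list of `clock_trajectory`
#'   objects.
#' @export
simulate.clock_model <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  sims <- lapply(seeds, function(s) run_ssa(object, seed = s, ...))
  structure(sims, class = "clock_sims", seed = seed)
}

#' @export
print.clock_sims <- function(x, ...) {
  cat(sprintf("%d stochastic clock trajectories (base seed %s)\n",
              length(x), format(attr(x, "seed"))))
  if (length(x)) print(x[[1]])
  invisible(x)
}

#' Extract a nuclear-protein series matrix from simulations
#'
#' @param sims a `clock_sims` list (or a single `clock_trajectory`).
#' @param compartment compartment index, or `NULL` for the whole-cell total
#'   (sum over compartments).
#' @param variable which count to extract (`"pn"` default).
#' @return Numeric matrix, rows = grid times, one column per trial.
#' @export
pn_series <- function(sims, compartment = NULL, variable = "pn") {
  if (inherits(sims, "clock_trajectory")) sims <- list(sims)
  cols <- lapply(sims, function(tr) {
    m <- tr[[variable]]
    if (is.null(compartment)) rowSums(m) else m[, compartment]
  })
  do.call(cbind, cols)
}

#' Redistribute the cytoplasmic protein pool across compartments
#'
#' Implements the instantaneous protein-equilibration rule of the stochastic
#' model. For uniform compartments, each ends up with `floor(p_tot / N)`
#' proteins and the `p_tot %% N` leftover proteins go to distinct
#' compartments chosen uniformly at random. For unequal compartment lengths
#' the default is randomized largest-remainder apportionment on the length
#' fractions `l_i / L`: each compartment gets the floor of its real-valued
#' share and the leftover units go one-each to distinct compartments drawn
#' with probability proportional to the fractional remainders, so the
#' expectation matches [expected_allocation()] and no compartment deviates
#' from its target by more than one molecule. A pure multinomial split is
#' available for sensitivity analysis.
#'
#' @param pc non-negative integer counts per compartment.
#' @param model a [clock_model()] (supplies the geometry), or a numeric
#'   vector of compartment lengths.
#' @param method `"largest_remainder"` (default) or `"multinomial"`.
#' @return Integer counts with the same total.
#' @examples
#' set.seed(1)
#' redistribute(c(7, 0), c(1, 1))   # (4,3) or (3,4)
#' @export
redistribute <- function(pc, model,
                         method = c("largest_remainder", "multinomial")) {
  method <- match.arg(method)
  if (any(pc < 0) || any(pc != round(pc)))
    stop("pc must be non-negative integer counts")
  if (inherits(model, "clock_model")) {
    g <- model$geometry
    weights <- g$weights
    uniform <- g$uniform
  } else {
    lengths <- as.numeric(model)
    if (length(lengths) != length(pc))
      stop("lengths and pc must have the same number of compartments")
    weights <- lengths / sum(lengths)
    uniform <- diff(range(lengths)) < 1e-12 * max(lengths)
  }
  redistribute_cpp(as.integer(pc), weights, uniform,
                   match(method, c("largest_remainder", "multinomial")) - 1L)
}

#' Sample an event-driven step function on a uniform grid
#'
#' Right-continuous sampling: the value at grid time `t` is the value after
#' the last change at or before `t`.
#'
#' @param event_times strictly increasing change times, hours.
#' @param event_values value in force from each change time onward.
#' @param dt grid spacing, hours.
#' @param t_end end of the grid.
#' @param v0 value before the first change.
#' @return Numeric vector over `seq(0, t_end, by = dt)`.
#' @export
sample_on_grid <- function(event_times, event_values, dt, t_end, v0 = 0) {
  stopifnot(dt > 0, length(event_times) == length(event_values))
  grid <- seq(0, t_end, by = dt)
  idx <- findInterval(grid, event_times)
  c(v0, event_values)[idx + 1L]
}

#' Reconstruct gridded counts from a trajectory's event log
#'
#' Replays the full event log of a [run_ssa()] trajectory (run with
#' `log = "all"`) to rebuild the per-compartment count series on the same
#' sampling grid, independently of the simulator's internal sampler. Nuclear
#' mRNA, cytoplasmic mRNA and nuclear protein are always reconstructible;
#' the cytoplasmic protein pool is only reconstructible when no random
#' redistribution took place (single compartment or `share = FALSE`).
#'
#' @param traj a `clock_trajectory` with a full event log.
#' @return List of matrices `mn`, `mc`, `pn`, and `pc` (the latter `NULL`
#'   when redistribution makes it irrecoverable from the log).
#' @export
replay_event_log <- function(traj) {
  stopifnot(inherits(traj, "clock_trajectory"))
  ev <- traj$events
  if (is.null(ev) || !all(CHANNELS %in% levels(ev$channel)))
    stop("trajectory must carry a full event log (log = \"all\")")
  N <- ncol(traj$pn)
  can_pc <- N == 1L || !traj$share
  delta <- list( # per-channel count increments: (mn, mc, pc, pn)
    transcription = c(1, 0, 0, 0), export = c(-1, 1, 0, 0),
    mrna_decay = c(0, -1, 0, 0), translation = c(0, 0, 1, 0),
    import = c(0, 0, -1, 1), protein_decay = c(0, 0, 0, -1))
  out <- list()
  for (f in c("mn", "mc", "pc", "pn")) {
    if (f == "pc" && !can_pc) { out$pc <- NULL; next }
    k <- match(f, c("mn", "mc", "pc", "pn"))
    mat <- matrix(0L, length(traj$times), N)
    for (i in seq_len(N)) {
      sel <- ev$compartment == i
      d <- vapply(as.character(ev$channel[sel]), function(ch) delta[[ch]][k],
                  numeric(1))
      keep <- d != 0
      vals <- traj$init[[f]][i] + cumsum(d[keep])
      mat[, i] <- sample_on_grid(ev$time[sel][keep], vals,
                                 traj$dt_sample, traj$t_end,
                                 v0 = traj$init[[f]][i])
    }
    out[[f]] <- mat
  }
  out
}
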
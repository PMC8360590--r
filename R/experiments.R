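#' Trial-averaged spectral quality of a clock model
#'
#' The standard quality-measurement pipeline: run replicate stochastic
#' trials, discard a startup transient, average the nuclear-protein
#' periodograms over trials, and compute the quality factor and peak
#' frequency. Every trial starts from the all-zero state, so the initial
#' relaxation onto the oscillation is coherent across trials and would
#' otherwise contaminate the averaged spectrum with low-frequency power;
#' `burn_in` hours are therefore simulated and discarded before the
#' `t_end`-hour spectral record.
#'
#' @param model a [clock_model()].
#' @param n_trials number of SSA trials to average.
#' @param seed base seed (trial `k` uses `seed + k - 1`).
#' @param t_end length of the analyzed record, hours.
#' @param burn_in transient discarded before the record, hours.
#' @param compartment compartment whose nuclear protein is analyzed, or
#'   `NULL` for the whole-cell total.
#' @param dt_sample sampling grid, hours.
#' @param tau quality band half-width, hours.
#' @return A `quality_result` (see [quality_factor()]) with the averaged
#'   `power_spectrum` attached as attribute `spectrum`.
#' @export
quality_pipeline <- function(model, n_trials = 100, seed = 1, t_end = 1000,
                             burn_in = 200, compartment = NULL,
                             dt_sample = 0.5, tau = 2) {
  sims <- simulate(model, nsim = n_trials, seed = seed,
                   t_end = t_end + burn_in, dt_sample = dt_sample)
  mat <- pn_series(sims, compartment = compartment)
  if (burn_in > 0)
    mat <- mat[-seq_len(round(burn_in / dt_sample)), , drop = FALSE]
  ps <- averaged_periodogram(mat, dt_sample)
  qr <- quality_factor(ps, tau = tau)
  attr(qr, "spectrum") <- ps
  qr
}

#' Quality factor versus transcription rate
#'
#' For each transcription rate, runs replicate stochastic trials of the
#' single-compartment model, averages the nuclear-protein periodograms, and
#' reports the quality factor and peak frequency. At the full reference
#' scale (100 trials of 1000 h per rate, rates up to 180000 per hour) this
#' is an expensive computation; `n_trials` and `t_end` scale it down at the
#' cost of wider Monte-Carlo error (roughly proportional to
#' `1 / sqrt(n_trials)`).
#'
#' @param alphas transcription rates to sweep, per hour.
#' @param n_trials SSA trials per rate.
#' @param t_end record length per trial, hours.
#' @param seed base seed; rate `j` uses seeds
#'   `seed + (j-1)*n_trials + 0:(n_trials-1)`.
#' @param burn_in discarded transient per trial, hours (see
#'   [quality_pipeline()]).
#' @param dt_sample sampling grid, hours.
#' @param tau quality-factor band half-width, hours.
#' @return `data.frame` with one row per rate: `alpha`, `q`, `peak_freq`,
#'   `peak_period`; the run settings are attached as attributes.
#' @export
run_table1 <- function(alphas = c(18, 180, 1800, 18000, 180000),
                       n_trials = 100, t_end = 1000, seed = 1,
                       burn_in = 200, dt_sample = 0.5, tau = 2) {
  rows <- lapply(seq_along(alphas), function(j) {
    model <- clock_model(alpha = alphas[j], N = 1)
    qr <- quality_pipeline(model, n_trials = n_trials,
                           seed = seed + (j - 1L) * n_trials,
                           t_end = t_end, burn_in = burn_in,
                           dt_sample = dt_sample, tau = tau)
    data.frame(alpha = alphas[j], q = qr$q, peak_freq = qr$peak_freq,
               peak_period = qr$peak_period)
  })
  out <- do.call(rbind, rows)
  attr(out, "settings") <- list(n_trials = n_trials, t_end = t_end,
                                seed = seed, burn_in = burn_in,
                                dt_sample = dt_sample, tau = tau)
  out
}

#' Quality factor and peak frequency versus number of compartments
#'
#' Sweeps the number of uniform nuclear compartments at a fixed
#' transcription rate. Quality factor and peak frequency are evaluated for
#' a single compartment's nuclear protein (comparable across `N`), from the
#' trial-averaged spectrum.
#'
#' @param Ns compartment counts to sweep.
#' @param alpha transcription rate, per hour.
#' @param compartment which compartment's series to analyze (default 1).
#' @inheritParams run_table1
#' @return `data.frame` with one row per `N`: `N`, `q`, `peak_freq`,
#'   `peak_period`.
#' @export
run_compartment_sweep <- function(Ns = c(1, 2, 4, 8, 16), alpha = 18,
                                  n_trials = 100, t_end = 1000, seed = 1,
                                  burn_in = 200, dt_sample = 0.5, tau = 2,
                                  compartment = 1) {
  rows <- lapply(seq_along(Ns), function(j) {
    model <- clock_model(alpha = alpha, N = Ns[j])
    qr <- quality_pipeline(model, n_trials = n_trials,
                           seed = seed + (j - 1L) * n_trials,
                           t_end = t_end, burn_in = burn_in,
                           compartment = compartment,
                           dt_sample = dt_sample, tau = tau)
    data.frame(N = Ns[j], q = qr$q, peak_freq = qr$peak_freq,
               peak_period = qr$peak_period)
  })
  out <- do.call(rbind, rows)
  attr(out, "settings") <- list(alpha = alpha, n_trials = n_trials,
                                t_end = t_end, seed = seed,
                                burn_in = burn_in, dt_sample = dt_sample,
                                tau = tau, compartment = compartment)
  out
}

#' Division of labor and whole-cell quality across compartment-size ratios
#'
#' For two-nucleus syncytia whose compartment lengths stand in the given
#' ratios, runs (i) one long division-of-labor simulation per ratio,
#' tallying per-period transcription shares, and (ii) replicate shorter
#' trials per ratio from which the whole-cell (total nuclear protein)
#' quality factor is computed. The uniform 1:1 cell is always included in
#' the quality sweep as the benchmark.
#'
#' @param ratios larger-to-smaller compartment length ratios.
#' @param alpha transcription rate, per hour.
#' @param labor_t_end hours for the division-of-labor run (default 10000,
#'   about 400 periods).
#' @param q_trials,q_t_end trials and record length for the quality part.
#' @param seed base seed.
#' @param dt_sample sampling grid, hours.
#' @param tau quality band half-width, hours.
#' @return `data.frame` with one row per ratio (including 1.0):
#'   `ratio`, `skew_fraction`, `mean_fraction_smaller` (NA for the uniform
#'   benchmark where no compartment is smaller), `q_whole_cell`.
#' @export
run_size_ratio_sweep <- function(ratios = seq(1.1, 1.5, by = 0.1),
                                 alpha = 18, labor_t_end = 10000,
                                 q_trials = 100, q_t_end = 1000, seed = 1,
                                 burn_in = 200, dt_sample = 0.5, tau = 2) {
  all_ratios <- sort(unique(c(1, ratios)))
  rows <- lapply(seq_along(all_ratios), function(j) {
    rho <- all_ratios[j]
    model <- clock_model(alpha = alpha, lengths = c(rho, 1))
    labor <- division_of_labor(model, t_end = labor_t_end,
                               seed = seed + (j - 1L) * (q_trials + 1L),
                               dt_sample = dt_sample)
    qr <- quality_pipeline(model, n_trials = q_trials,
                           seed = seed + (j - 1L) * (q_trials + 1L) + 1L,
                           t_end = q_t_end, burn_in = burn_in,
                           compartment = NULL, dt_sample = dt_sample,
                           tau = tau)
    data.frame(ratio = rho, skew_fraction = labor$skew_fraction,
               mean_fraction_smaller =
                 if (rho == 1) NA_real_ else labor$mean_fraction_smaller,
               q_whole_cell = qr$q)
  })
  out <- do.call(rbind, rows)
  attr(out, "settings") <- list(alpha = alpha, labor_t_end = labor_t_end,
                                q_trials = q_trials, q_t_end = q_t_end,
                                seed = seed, burn_in = burn_in,
                                dt_sample = dt_sample, tau = tau)
  out
}
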
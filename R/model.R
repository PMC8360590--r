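#' Build a syncytial circadian clock model
#'
#' Constructs the parameterized model object used by every simulator and
#' analysis function in the package. The model is a negative-feedback
#' transcription-translation oscillator: nuclear mRNA is transcribed at a
#' maximum rate `alpha` under Hill repression by nuclear protein, exported to
#' the local cytoplasm, translated, and the protein is imported back into the
#' nucleus where it represses transcription and decays. The cell is a line of
#' `N` compartments, one nucleus each; cytoplasmic proteins equilibrate
#' across compartments (fast diffusion), mRNAs stay where they were made.
#'
#' The default rate set is the standard one for this oscillator:
#' `gamma_m = gamma_p = delta_m = delta_p = 2*pi/22` per hour,
#' `V_n = 0.1` pL, `V_c = 2` pL, `beta = 10` per hour, `K = 200` per pL,
#' `r` = 5, and a deliberately low transcription rate `alpha = 18` per hour
#' matching mRNA abundances observed in fungal syncytia.
#'
#' @param alpha maximum transcription rate, molecules per hour per nucleus.
#' @param beta translation rate, per hour per cytoplasmic mRNA.
#' @param gamma_m mRNA nuclear-export rate, per hour.
#' @param gamma_p protein nuclear-import rate, per hour.
#' @param delta_m cytoplasmic mRNA decay rate, per hour.
#' @param delta_p nuclear protein decay rate, per hour.
#' @param K repression half-max concentration, molecules per pL.
#' @param r Hill exponent (non-negative integer; `r` = 0 disables
#'   repression, giving independent linear birth-death chains).
#' @param V_n nuclear volume, pL.
#' @param V_c cytoplasmic volume of an average compartment, pL. Individual
#'   compartments get `V_c * l_i / mean(l)` (volume proportional to length).
#' @param N number of nuclear compartments (ignored if `lengths` given).
#' @param lengths compartment lengths (arbitrary units); default uniform.
#'
#' @return An object of class `clock_model`: a list with the rate parameters
#'   and a `geometry` component (`lengths`, `N`, `L`, length fractions
#'   `weights`, per-compartment volumes `V_c_i`, and a `uniform` flag).
#' @seealso [hopf_threshold()], [run_ssa()], [solve_deterministic()]
#' @examples
#' m <- clock_model(alpha = 18)
#' m2 <- clock_model(alpha = 18, lengths = c(1.5, 1)) # skewed two-nucleus cell
#' @export
clock_model <- function(alpha = 18, beta = 10,
                        gamma_m = 2 * pi / 22, gamma_p = 2 * pi / 22,
                        delta_m = 2 * pi / 22, delta_p = 2 * pi / 22,
                        K = 200, r = 5, V_n = 0.1, V_c = 2,
                        N = 1, lengths = NULL) {
  rates <- c(alpha = alpha, beta = beta, gamma_m = gamma_m,
             gamma_p = gamma_p, delta_m = delta_m, delta_p = delta_p,
             K = K, V_n = V_n, V_c = V_c)
  if (any(!is.finite(rates)) || any(rates[-1] <= 0) || alpha < 0)
    stop("all rates, volumes and K must be strictly positive (alpha >= 0)")
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r != round(r))
    stop("'r' must be a non-negative integer")
  if (is.null(lengths)) {
    if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
      stop("'N' must be a positive integer")
    lengths <- rep(1, N)
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all compartment lengths must be strictly positive")
  N <- length(lengths)
  uniform <- diff(range(lengths)) < 1e-12 * max(lengths)
  geometry <- list(
    lengths = as.numeric(lengths), N = N, L = sum(lengths),
    weights = as.numeric(lengths) / sum(lengths),
    V_c_i = V_c * as.numeric(lengths) / mean(lengths),
    uniform = uniform)
  structure(
    list(alpha = alpha, beta = beta, gamma_m = gamma_m, gamma_p = gamma_p,
         delta_m = delta_m, delta_p = delta_p, K = K, r = as.integer(r),
         V_n = V_n, V_c = V_c, geometry = geometry),
    class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  g <- x$geometry
  cat("Syncytial circadian clock model\n")
  cat(sprintf("  compartments: N = %d (%s)\n", g$N,
              if (g$uniform) "uniform" else
                paste0("lengths ", paste(signif(g$lengths, 4), collapse = ":"))))
  cat(sprintf("  alpha = %g /h, beta = %g /h, K = %g /pL, r = %d\n",
              x$alpha, x$beta, x$K, x$r))
  cat(sprintf("  gamma_m = %.4g, gamma_p = %.4g, delta_m = %.4g, delta_p = %.4g /h\n",
              x$gamma_m, x$gamma_p, x$delta_m, x$delta_p))
  cat(sprintf("  V_n = %g pL, V_c = %g pL\n", x$V_n, x$V_c))
  invisible(x)
}

#' @export
coef.clock_model <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, gamma_m = object$gamma_m,
    gamma_p = object$gamma_p, delta_m = object$delta_m,
    delta_p = object$delta_p, K = object$K, r = object$r,
    V_n = object$V_n, V_c = object$V_c)
}

#' @export
summary.clock_model <- function(object, ...) {
  thr <- tryCatch(hopf_threshold(object), error = function(e) NA_real_)
  ss <- steady_state(object)
  out <- list(model = object, hopf_threshold = thr, steady_state = ss)
  class(out) <- "summary.clock_model"
  out
}

#' @export
print.summary.clock_model <- function(x, ...) {
  print(x$model)
  if (is.finite(x$hopf_threshold)) {
    cat(sprintf("  deterministic oscillation threshold: alpha_crit = %.1f /h (%s)\n",
                x$hopf_threshold,
                if (x$model$alpha > x$hopf_threshold) "sustained regime"
                else "damped regime"))
  } else {
    cat("  deterministic oscillation threshold: not available for these rates\n")
  }
  ss <- x$steady_state
  cat(sprintf("  per-compartment fixed point (counts): mn = %.2f, mc = %.2f, pc = %.2f, pn = %.2f\n",
              ss["mn"], ss["mc"], ss["pc"], ss["pn"]))
  invisible(x)
}

#' Hill repression factor
#'
#' Fraction of the maximum transcription rate that survives repression by
#' nuclear protein: `(K / (K + P_n))^r` with nuclear concentration
#' `P_n = pn / V_n`. Equals 1 with no repressor and decreases monotonically
#' to 0 as nuclear protein accumulates.
#'
#' @param pn nuclear protein count(s), molecules (non-negative).
#' @param model a [clock_model()].
#' @return Numeric factor(s) in `(0, 1]`.
#' @examples
#' m <- clock_model()
#' hill_repression(0, m)                 # 1: no repression
#' hill_repression(m$K * m$V_n, m)       # (1/2)^r at the half-max count
#' @export
hill_repression <- function(pn, model) {
  stopifnot(inherits(model, "clock_model"))
  if (any(pn < 0)) stop("nuclear protein count must be non-negative")
  (model$K / (model$K + pn / model$V_n))^model$r
}

#' Reaction propensities for a system state
#'
#' Converts the concentration-level rate laws to molecule-count reaction
#' propensities. Per compartment there are six channels; all volume factors
#' cancel in the conversion except the nuclear concentration inside the Hill
#' term.
#'
#' @param state list with integer count vectors `mn`, `mc`, `pc`, `pn`
#'   (one entry per compartment), e.g. from [clock_state()].
#' @param model a [clock_model()].
#' @return Numeric matrix (`N` rows, 6 columns named `transcription`,
#'   `export`, `mrna_decay`, `translation`, `import`, `protein_decay`),
#'   rates in events per hour.
#' @export
propensities <- function(state, model) {
  stopifnot(inherits(model, "clock_model"))
  N <- model$geometry$N
  state <- validate_state(state, N)
  cbind(transcription = model$alpha * hill_repression(state$pn, model),
        export = model$gamma_m * state$mn,
        mrna_decay = model$delta_m * state$mc,
        translation = model$beta * state$mc,
        import = model$gamma_p * state$pc,
        protein_decay = model$delta_p * state$pn)
}

#' Construct and validate a system state
#'
#' @param mn,mc,pc,pn non-negative integer count vectors, one entry per
#'   compartment (recycled from scalars to length `N`).
#' @param N number of compartments.
#' @param t time stamp in hours.
#' @return A list of class `clock_state`.
#' @export
clock_state <- function(mn = 0, mc = 0, pc = 0, pn = 0, N = max(
                          length(mn), length(mc), length(pc), length(pn)),
                        t = 0) {
  st <- list(t = t, mn = rep_len(mn, N), mc = rep_len(mc, N),
             pc = rep_len(pc, N), pn = rep_len(pn, N))
  st[-1] <- lapply(st[-1], function(v) {
    if (any(v < 0) || any(v != round(v)))
      stop("counts must be non-negative integers")
    as.integer(v)
  })
  class(st) <- "clock_state"
  st
}

validate_state <- function(state, N) {
  need <- c("mn", "mc", "pc", "pn")
  if (!all(need %in% names(state)))
    stop("state must have components mn, mc, pc, pn")
  for (f in need) {
    v <- state[[f]]
    if (length(v) != N)
      stop(sprintf("state$%s must have one entry per compartment (N = %d)", f, N))
    if (any(v < 0) || any(v != round(v)))
      stop(sprintf("state$%s must be non-negative integer counts", f))
  }
  state
}

#' Critical transcription rate for sustained deterministic oscillations
#'
#' Closed-form Hopf-bifurcation threshold for the deterministic model in the
#' symmetric-rate regime where export, import and both decay rates share a
#' common value `nu` and the Hill exponent is 5:
#' `alpha_crit = 4 * 5^5 * nu^2 * K * V_n / beta`. The deterministic system
#' has a stable limit cycle iff `alpha > alpha_crit`; below it, oscillations
#' damp toward the fixed point. At the default parameter set the threshold is
#' about 2039 per hour.
#'
#' The closed form is only valid in that regime, so the function refuses
#' (rather than extrapolates) when the four rates differ or `r` is not 5; use
#' [classify_oscillation()] with [solve_deterministic()] for numerical
#' threshold bracketing in other regimes.
#'
#' @param model a [clock_model()].
#' @param tol relative tolerance for the equal-rates check.
#' @return Critical `alpha`, molecules per hour.
#' @examples
#' hopf_threshold(clock_model()) # ~2039
#' @export
hopf_threshold <- function(model, tol = 1e-8) {
  stopifnot(inherits(model, "clock_model"))
  rates <- c(model$gamma_m, model$gamma_p, model$delta_m, model$delta_p)
  if (diff(range(rates)) > tol * max(rates))
    stop("closed-form threshold requires gamma_m = gamma_p = delta_m = delta_p")
  if (model$r != 5L)
    stop("closed-form threshold is only available for Hill exponent r = 5")
  nu <- mean(rates)
  4 * 5^5 * nu^2 * model$K * model$V_n / model$beta
}

#' Expected cytoplasmic protein allocation by compartment length
#'
#' With proteins uniformly distributed along the cell, the expected number of
#' cytoplasmic proteins in compartment `i` is `l_i / sum(l) * p_tot`. This is
#' the expectation of the stochastic redistribution rule ([redistribute()]).
#'
#' @param p_tot total cytoplasmic protein count (non-negative).
#' @param model a [clock_model()] (its geometry supplies the lengths), or a
#'   numeric vector of compartment lengths.
#' @return Real-valued expected counts, summing to `p_tot`.
#' @examples
#' expected_allocation(9, c(2, 1)) # 6, 3
#' @export
expected_allocation <- function(p_tot, model) {
  if (p_tot < 0) stop("p_tot must be non-negative")
  lengths <- if (inherits(model, "clock_model")) model$geometry$lengths
             else as.numeric(model)
  if (any(lengths <= 0)) stop("lengths must be positive")
  p_tot * lengths / sum(lengths)
}

#' Deterministic fixed point of the oscillator
#'
#' Solves the steady state of the rate equations in count units. Given the
#' transcription flux `phi = alpha * (K / (K + pn / V_n))^r`, the linear
#' chain forces `mn = phi / gamma_m`, `mc = phi / delta_m`,
#' `pc = beta * phi / (delta_m * gamma_p)` and
#' `pn = beta * phi / (delta_m * delta_p)`; the nuclear protein count is the
#' unique root of the resulting scalar fixed-point equation.
#'
#' @param model a [clock_model()].
#' @return Named numeric vector of per-compartment counts
#'   (`mn`, `mc`, `pc`, `pn`).
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "clock_model"))
  cap <- model$beta * model$alpha / (model$delta_m * model$delta_p)
  if (cap == 0)
    return(c(mn = 0, mc = 0, pc = 0, pn = 0))
  g <- function(pn)
    pn - model$beta * model$alpha * hill_repression(pn, model) /
      (model$delta_m * model$delta_p)
  pn <- uniroot(g, c(0, cap * (1 + 1e-9)), tol = 1e-10)$root
  phi <- model$alpha * hill_repression(pn, model)
  c(mn = phi / model$gamma_m, mc = phi / model$delta_m,
    pc = model$beta * phi / (model$delta_m * model$gamma_p), pn = pn)
}
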
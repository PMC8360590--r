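#' Integrate the deterministic rate equations
#'
#' Solves the concentration ODEs of the oscillator with instantaneous
#' cytoplasmic-protein equalization across compartments. Two equivalent
#' formulations are available: `"shared"` treats the equalized cytoplasmic
#' protein as a single shared pool (one ODE variable; stiffness-free and the
#' default), while `"stepwise"` integrates per-compartment cytoplasmic
#' protein and resets it to the volume-weighted cell average after every
#' output step, mirroring the discrete averaging rule. For uniform geometry
#' and symmetric initial conditions the two agree to solver tolerance.
#'
#' @param model a [clock_model()].
#' @param init named list of initial concentrations (`Mn`, `Mc`, `Pc`, `Pn`,
#'   each scalar or length `N`), in molecules per pL. Default is a small
#'   nuclear mRNA pulse: `Mn = 1 / V_n`, everything else 0.
#' @param t_end integration horizon, hours.
#' @param dt_out output (and, for `"stepwise"`, averaging) step, hours.
#' @param mode `"shared"` or `"stepwise"` (see Details).
#' @param rtol,atol solver tolerances; tight defaults because damping-rate
#'   classification is sensitive to numerical dissipation.
#' @return Object of class `clock_ode`: list with `times` and concentration
#'   matrices `Mn`, `Mc`, `Pc`, `Pn` (rows = times, columns = compartments).
#' @examples
#' traj <- solve_deterministic(clock_model(alpha = 18), t_end = 200)
#' classify_oscillation(traj, transient = 50)
#' @export
solve_deterministic <- function(model, init = NULL, t_end = 500,
                                dt_out = 0.1,
                                mode = c("shared", "stepwise"),
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "clock_model"), t_end > 0, dt_out > 0)
  mode <- match.arg(mode)
  g <- model$geometry
  N <- g$N
  init <- default_ode_init(model, init)
  if (any(unlist(init) < 0)) stop("initial concentrations must be non-negative")
  times <- seq(0, t_end, by = dt_out)

  vw <- g$V_c_i / sum(g$V_c_i) # volume weights for the shared pool

  if (mode == "shared") {
    y0 <- c(init$Mn, init$Mc, sum(vw * init$Pc), init$Pn)
    deriv <- function(t, y, p) {
      Mn <- y[seq_len(N)]
      Mc <- y[N + seq_len(N)]
      Pc <- y[2 * N + 1]
      Pn <- y[2 * N + 1 + seq_len(N)]
      hill <- (model$K / (model$K + pmax(Pn, 0)))^model$r
      dMn <- model$alpha / model$V_n * hill - model$gamma_m * Mn
      dMc <- model$gamma_m * (model$V_n / g$V_c_i) * Mn - model$delta_m * Mc
      dPc <- model$beta * sum(vw * Mc) - model$gamma_p * Pc
      dPn <- model$gamma_p * (g$V_c_i / model$V_n) * Pc - model$delta_p * Pn
      list(c(dMn, dMc, dPc, dPn))
    }
    sol <- deSolve::ode(y0, times, deriv, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    check_solver(sol, times)
    Pc <- matrix(sol[, 2 * N + 2], nrow(sol), N)
    out <- list(times = sol[, 1],
                Mn = unname(sol[, 1 + seq_len(N), drop = FALSE]),
                Mc = unname(sol[, 1 + N + seq_len(N), drop = FALSE]),
                Pc = Pc,
                Pn = unname(sol[, 2 * N + 2 + seq_len(N), drop = FALSE]))
  } else {
    y <- c(init$Mn, init$Mc, init$Pc, init$Pn)
    deriv <- function(t, y, p) {
      Mn <- y[seq_len(N)]
      Mc <- y[N + seq_len(N)]
      Pc <- y[2 * N + seq_len(N)]
      Pn <- y[3 * N + seq_len(N)]
      hill <- (model$K / (model$K + pmax(Pn, 0)))^model$r
      dMn <- model$alpha / model$V_n * hill - model$gamma_m * Mn
      dMc <- model$gamma_m * (model$V_n / g$V_c_i) * Mn - model$delta_m * Mc
      dPc <- model$beta * Mc - model$gamma_p * Pc
      dPn <- model$gamma_p * (g$V_c_i / model$V_n) * Pc - model$delta_p * Pn
      list(c(dMn, dMc, dPc, dPn))
    }
    nt <- length(times)
    res <- matrix(NA_real_, nt, 4 * N)
    res[1, ] <- y
    for (k in seq_len(nt - 1)) {
      sol <- deSolve::ode(y, times[k] + c(0, dt_out), deriv, parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol)
      check_solver(sol, times[k] + c(0, dt_out))
      y <- sol[2, -1]
      # equalize cytoplasmic protein (conserves total molecules)
      pcavg <- sum(vw * y[2 * N + seq_len(N)])
      y[2 * N + seq_len(N)] <- pcavg
      res[k + 1, ] <- y
    }
    out <- list(times = times,
                Mn = res[, seq_len(N), drop = FALSE],
                Mc = res[, N + seq_len(N), drop = FALSE],
                Pc = res[, 2 * N + seq_len(N), drop = FALSE],
                Pn = res[, 3 * N + seq_len(N), drop = FALSE])
  }
  out$model <- model
  out$mode <- mode
  class(out) <- "clock_ode"
  out
}

default_ode_init <- function(model, init) {
  N <- model$geometry$N
  base <- list(Mn = rep(1 / model$V_n, N), Mc = rep(0, N),
               Pc = rep(0, N), Pn = rep(0, N))
  if (is.null(init)) return(base)
  if (!all(names(init) %in% names(base)))
    stop("init components must be among Mn, Mc, Pc, Pn")
  for (f in names(init)) base[[f]] <- rep_len(init[[f]], N)
  base
}

check_solver <- function(sol, times) {
  if (nrow(sol) < length(times) || any(!is.finite(sol[nrow(sol), ])))
    stop("ODE solver failed: ",
         paste(utils::capture.output(deSolve::diagnostics(sol)), collapse = "\n"))
  invisible(sol)
}

#' @export
print.clock_ode <- function(x, ...) {
  cat(sprintf("Deterministic clock trajectory: %d compartments, %.4g h (%s mode)\n",
              ncol(x$Pn), max(x$times), x$mode))
  invisible(x)
}

#' @export
plot.clock_ode <- function(x, variable = "Pn", ...) {
  graphics::matplot(x$times, x[[variable]], type = "l", lty = 1,
                    xlab = "time (h)",
                    ylab = paste(variable, "(molecules/pL)"), ...)
  invisible(x)
}

#' Classify a trajectory as damped, sustained, or non-oscillatory
#'
#' Operationalizes the distinction between a limit cycle and a damped
#' spiral: after discarding a transient, successive peak-to-peak amplitudes
#' of the series are compared. The oscillation is `sustained` when the
#' per-cycle amplitude ratio converges to 1 within `tol`, `damped` when the
#' ratio stays below `1 - tol`, and `non-oscillatory` when the series has no
#' alternating extrema (e.g. monotone decay to a fixed point).
#'
#' @param x a `clock_ode` trajectory (its first-compartment nuclear protein
#'   is used) or a numeric series.
#' @param times time stamps when `x` is a bare numeric series (defaults to
#'   index).
#' @param variable which concentration to classify for `clock_ode` input.
#' @param transient hours discarded before classification (default 200).
#' @param tol amplitude-ratio tolerance per cycle (default 1e-3).
#' @param min_extrema minimum alternating extrema required after the
#'   transient; fewer (while the series still oscillates) is an error.
#' @return Character scalar: `"sustained"`, `"damped"`, or
#'   `"non-oscillatory"`, with attributes `amplitude_ratio` (geometric mean
#'   of the last ratios) and `n_extrema`.
#' @export
classify_oscillation <- function(x, times = NULL, variable = "Pn",
                                 transient = 200, tol = 1e-3,
                                 min_extrema = 5) {
  if (inherits(x, "clock_ode")) {
    times <- x$times
    x <- x[[variable]][, 1]
  }
  if (is.null(times)) times <- seq_along(x)
  keep <- times >= transient
  if (sum(keep) < 10) stop("insufficient data: trajectory too short")
  y <- x[keep]
  scale <- max(abs(y), 1e-300)
  ext <- local_extrema(y)
  if (length(ext) < min_extrema) {
    if (length(ext) <= 2) {
      return(structure("non-oscillatory",
                       amplitude_ratio = NA_real_, n_extrema = length(ext)))
    }
    stop("insufficient data: fewer than ", min_extrema,
         " extrema after the transient; extend the trajectory")
  }
  amp <- abs(diff(y[ext]))
  # collapsed to numerical noise around the fixed point -> damped out
  if (stats::median(tail(amp, 3)) < 1e-7 * scale) {
    return(structure("damped",
                     amplitude_ratio = 0, n_extrema = length(ext)))
  }
  ratios <- amp[-1] / amp[-length(amp)]
  k <- min(6L, length(ratios))
  rbar <- exp(mean(log(tail(ratios, k))))
  verdict <- if (rbar >= 1 - tol) "sustained" else "damped"
  structure(verdict, amplitude_ratio = rbar, n_extrema = length(ext))
}

# indices of local extrema (sign change of the first difference; plateaus
# carry the preceding slope so each flat top counts once)
local_extrema <- function(y) {
  dy <- sign(diff(y))
  for (i in seq_along(dy)[-1]) if (dy[i] == 0) dy[i] <- dy[i - 1]
  which(diff(dy) != 0) + 1L
}
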
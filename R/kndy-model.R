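#' Parameters of the arcuate KNDy pulse-generator model
#'
#' The arcuate KNDy (kisspeptin / neurokinin B / dynorphin) population is
#' modelled as a three-variable mean-field relaxation oscillator in dynorphin
#' activity \code{D}, NKB activity \code{N} and population firing activity
#' \code{v}:
#' \deqn{\tau_D \dot D = k_D\, H(v; K_{vD}, n_{vD}) - D}
#' \deqn{\tau_N \dot N = k_N\, H(v; K_{vN}, n_{vN}) \, / \,
#'       [1 + (D/K_{DN})^{n_{DN}}] - N}
#' \deqn{\tau_v \dot v = v_{max}\, H(u; K_{uv}, n_{uv}) - v, \qquad
#'       u = \max(0,\; w_{Nv} H(N; K_{Nv}, n_{Nv}) + I_0 + I_{exc} - I_{inh})}
#' where \eqn{H(x;K,n) = x^n/(K^n + x^n)}. NKB excites firing (fast positive
#' feedback) while dynorphin suppresses NKB secretion (slow delayed negative
#' feedback); together these produce sustained relaxation oscillations over a
#' band of net input. Below a lower input threshold the network is silent; as
#' net drive rises the oscillation first accelerates and then terminates at an
#' upper threshold, leaving a depolarised high-activity quiescent state.
#'
#' All activities are dimensionless and time is in minutes. The defaults are a
#' committed calibration: at zero external input the network pulses with a
#' period of roughly 15-16 min, and under the basal inhibitory tone supplied
#' by the amygdala circuit (see [mepd_params()]) the coupled system pulses at
#' 25-30-min intervals, matching control interpulse intervals measured in
#' ovariectomised mice.
#'
#' @param tau_D,tau_N,tau_v Time constants (min) of dynorphin, NKB and firing.
#' @param k_D,k_N Maximal secretion rates (dimensionless activity units).
#' @param v_max Maximal firing activity.
#' @param K_vD,n_vD Half-activation and Hill exponent of firing-driven
#'   dynorphin secretion.
#' @param K_vN,n_vN Firing-driven NKB secretion.
#' @param K_DN,n_DN Dynorphin inhibition of NKB secretion.
#' @param w_Nv,K_Nv,n_Nv Weight, half-activation and exponent of the NKB drive
#'   onto firing.
#' @param K_uv,n_uv Half-activation and exponent of the firing response to its
#'   net input.
#' @param I0 Basal drive onto the firing population.
#' @param ... Reserved; must be empty.
#' @return An object of class \code{kndy_params} (named list).
#' @seealso [kndy_derivatives()], [kndy_simulate()], [scan_input()]
#' @export
kndy_params <- function(tau_D = 13, tau_N = 2, tau_v = 1,
                        k_D = 2, k_N = 3, v_max = 2,
                        K_vD = 1, n_vD = 2,
                        K_vN = 0.3, n_vN = 2,
                        K_DN = 0.45, n_DN = 4,
                        w_Nv = 2, K_Nv = 0.9, n_Nv = 6,
                        K_uv = 1, n_uv = 2,
                        I0 = 0.392, ...) {
  if (length(list(...)) > 0)
    stop("unknown kndy_params fields: ",
         paste(names(list(...)), collapse = ", "), call. = FALSE)
  p <- list(tau_D = tau_D, tau_N = tau_N, tau_v = tau_v,
            k_D = k_D, k_N = k_N, v_max = v_max,
            K_vD = K_vD, n_vD = n_vD, K_vN = K_vN, n_vN = n_vN,
            K_DN = K_DN, n_DN = n_DN,
            w_Nv = w_Nv, K_Nv = K_Nv, n_Nv = n_Nv,
            K_uv = K_uv, n_uv = n_uv, I0 = I0)
  check_finite(p, "kndy_params")
  with(p, {
    if (any(c(tau_D, tau_N, tau_v) <= 0))
      stop("time constants must be > 0", call. = FALSE)
    if (any(c(n_vD, n_vN, n_DN, n_Nv, n_uv) < 1))
      stop("Hill exponents must be >= 1", call. = FALSE)
    if (any(c(K_vD, K_vN, K_DN, K_Nv, K_uv) <= 0))
      stop("half-activation constants must be > 0", call. = FALSE)
  })
  structure(p, class = "kndy_params")
}

#' KNDy population state
#'
#' @param D Dynorphin activity (>= 0).
#' @param N NKB activity (>= 0).
#' @param v Population firing activity (>= 0).
#' @return Named numeric vector of class \code{kndy_state}.
#' @export
kndy_state <- function(D = 0, N = 0, v = 0) {
  s <- c(D = D, N = N, v = v)
  check_finite(s, "kndy_state")
  if (any(s < 0)) {
    bad <- names(s)[s < 0][1L]
    stop(sprintf("negative value in kndy_state: field '%s'", bad),
         call. = FALSE)
  }
  structure(s, class = "kndy_state")
}

#' External input onto the KNDy firing population
#'
#' Excitatory drive arrives through the glutamatergic projection from the
#' amygdala; inhibitory drive through the GABAergic efferents. Both are
#' non-negative; they enter the firing equation as \code{I_exc - I_inh}.
#'
#' @param I_exc Excitatory input (>= 0).
#' @param I_inh Inhibitory input (>= 0).
#' @return Named numeric vector of class \code{arc_input}.
#' @export
arc_input <- function(I_exc = 0, I_inh = 0) {
  x <- c(I_exc = I_exc, I_inh = I_inh)
  check_finite(x, "arc_input")
  if (any(x < 0))
    stop("arc_input components must be non-negative", call. = FALSE)
  structure(x, class = "arc_input")
}

#' Time derivatives of the KNDy model
#'
#' Right-hand side of the three KNDy ODEs (see [kndy_params()] for the
#' equations). Increasing \code{I_exc} never decreases \eqn{dv/dt} and
#' increasing \code{I_inh} never increases it, holding the state fixed.
#'
#' @param state Named numeric (D, N, v) or a [kndy_state()].
#' @param params A [kndy_params()] object.
#' @param input An [arc_input()] (defaults to zero input).
#' @return Named numeric vector (dD, dN, dv).
#' @export
kndy_derivatives <- function(state, params, input = arc_input()) {
  check_finite(state, "kndy_state")
  check_finite(params, "kndy_params")
  check_finite(input, "arc_input")
  kndy_rhs_core(c(state[["D"]], state[["N"]], state[["v"]]), params,
                input[["I_exc"]], input[["I_inh"]])
}

# Unvalidated right-hand side shared by the derivative entry point and the
# integrators; y = c(D, N, v).
kndy_rhs_core <- function(y, p, I_exc, I_inh) {
  D <- y[1L]; N <- y[2L]; v <- y[3L]
  u <- p$w_Nv * hill(N, p$K_Nv, p$n_Nv) + p$I0 + I_exc - I_inh
  if (u < 0) u <- 0
  c(dD = (p$k_D * hill(v, p$K_vD, p$n_vD) - D) / p$tau_D,
    dN = (p$k_N * hill(v, p$K_vN, p$n_vN) /
            (1 + (D / p$K_DN)^p$n_DN) - N) / p$tau_N,
    dv = (p$v_max * hill(u, p$K_uv, p$n_uv) - v) / p$tau_v)
}

#' Simulate the KNDy model
#'
#' Integrates the KNDy ODEs with an adaptive explicit Runge-Kutta scheme
#' (Dormand-Prince 4(5), via \pkg{deSolve}) and resamples the dense output
#' onto a regular grid. Deterministic: identical arguments give identical
#' trajectories.
#'
#' @param params A [kndy_params()] object.
#' @param input_fn Function of time (min) returning an [arc_input()]; the
#'   default is zero external input. Must be piecewise-constant or smooth;
#'   discontinuity times can be passed via \code{switch_times} so the
#'   integrator is restarted there.
#' @param t_span Length-2 numeric, start and end time (min), start < end.
#' @param dt_out Output grid spacing (min).
#' @param init Initial [kndy_state()]; defaults to the origin.
#' @param atol,rtol Absolute and relative integration tolerances.
#' @param switch_times Times (min) at which \code{input_fn} jumps.
#' @return A \code{pg_trajectory}: data frame with columns
#'   \code{time_min, D, N, v} and attribute \code{v_max}.
#' @export
kndy_simulate <- function(params, input_fn = function(t) arc_input(),
                          t_span = c(0, 300), dt_out = 0.1,
                          init = kndy_state(),
                          atol = 1e-8, rtol = 1e-6,
                          switch_times = numeric(0)) {
  stopifnot(length(t_span) == 2, t_span[1] < t_span[2], dt_out > 0)
  rhs <- function(t, y, parms) {
    inp <- input_fn(t)
    list(kndy_rhs_core(y, parms, inp[["I_exc"]], inp[["I_inh"]]))
  }
  out <- integrate_piecewise(rhs, unclass(init), params, t_span, dt_out,
                             atol, rtol, switch_times)
  traj <- data.frame(time_min = out[, "time"], D = out[, "D"],
                     N = out[, "N"], v = out[, "v"])
  structure(traj, class = c("pg_trajectory", "data.frame"),
            v_max = params$v_max)
}

# Integrate an ODE system piecewise between input discontinuities so the
# adaptive solver never steps across a jump. Returns the deSolve matrix on
# the full dt_out grid.
integrate_piecewise <- function(rhs, y0, parms, t_span, dt_out, atol, rtol,
                                switch_times) {
  cuts <- sort(unique(switch_times))
  cuts <- cuts[cuts > t_span[1] & cuts < t_span[2]]
  bounds <- c(t_span[1], cuts, t_span[2])
  grid <- seq(t_span[1], t_span[2], by = dt_out)
  if (grid[length(grid)] < t_span[2]) grid <- c(grid, t_span[2])
  pieces <- vector("list", length(bounds) - 1L)
  y <- y0
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    times <- unique(c(lo, grid[grid > lo & grid < hi], hi))
    sol <- tryCatch(
      deSolve::ode(y = y, times = times, func = rhs, parms = parms,
                   method = "ode45", atol = atol, rtol = rtol),
      error = function(e) stop(sprintf(
        "integration failed on [%g, %g] min: %s", lo, hi,
        conditionMessage(e)), call. = FALSE))
    if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol)))
      stop(sprintf("integration failed near t = %g min", hi), call. = FALSE)
    pieces[[i]] <- sol
    y <- sol[nrow(sol), -1L]
  }
  out <- do.call(rbind, lapply(seq_along(pieces), function(i) {
    m <- pieces[[i]]
    if (i < length(pieces)) m[-nrow(m), , drop = FALSE] else m
  }))
  # keep only the requested grid (piece boundaries may add points)
  out[out[, "time"] %in% grid | seq_len(nrow(out)) == nrow(out), ,
      drop = FALSE]
}

#' Pulse-generator event times from a firing-activity trajectory
#'
#' Marks one event per oscillation cycle at the upward crossing of the firing
#' activity through \code{frac_threshold * max(v)}; crossing times are
#' linearly interpolated between output samples. A trace that never crosses
#' (silent, or quiescent-high) yields no events.
#'
#' @param traj A \code{pg_trajectory} from [kndy_simulate()] or
#'   [simulate_coupled()].
#' @param frac_threshold Fraction of the trajectory maximum used as the event
#'   threshold, in (0, 1).
#' @return Numeric vector of event times (min), class \code{pulse_train}.
#' @export
pulse_times_from_activity <- function(traj, frac_threshold = 0.5) {
  stopifnot(frac_threshold > 0, frac_threshold < 1)
  if (nrow(traj) < 2)
    stop("trajectory must contain at least 2 samples", call. = FALSE)
  v <- traj$v; t <- traj$time_min
  thr <- frac_threshold * max(v)
  if (thr <= 0) return(pulse_train(numeric(0)))
  below <- v < thr
  idx <- which(below[-length(v)] & !below[-1L])
  if (length(idx) == 0) return(pulse_train(numeric(0)))
  frac <- (thr - v[idx]) / (v[idx + 1L] - v[idx])
  pulse_train(t[idx] + frac * (t[idx + 1L] - t[idx]))
}

#' Construct a pulse train (strictly increasing event times)
#'
#' @param times Numeric vector of event times (min).
#' @return Numeric vector with class \code{pulse_train}.
#' @export
pulse_train <- function(times = numeric(0)) {
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("pulse times must be finite", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("pulse times must be strictly increasing", call. = FALSE)
  structure(times, class = "pulse_train")
}

#' Scan the excitatory input axis of the KNDy model
#'
#' Simulates the KNDy network at each value of a sorted grid of constant
#' excitatory inputs (at fixed inhibitory input), discards a transient, and
#' reports the pulse frequency and dynamical regime at each grid point. The
#' regimes partition the grid into contiguous bands: silent at low net drive,
#' pulsatile in the middle, and quiescent-high above the upper bifurcation
#' threshold where rising drive terminates the oscillation.
#'
#' @param params A [kndy_params()] object.
#' @param I_exc_grid Sorted ascending numeric grid of excitatory inputs
#'   (>= 2 points).
#' @param I_inh Fixed inhibitory input (scalar >= 0).
#' @param t_sim Total simulated time per grid point (min); the final
#'   \code{t_window} minutes are analysed.
#' @param t_window Analysis window length (min).
#' @return Data frame with columns \code{I_exc}, \code{frequency} (cycles per
#'   hour; \code{0} when non-pulsatile) and \code{regime} (factor with levels
#'   silent, pulsatile, quiescent_high).
#' @export
scan_input <- function(params, I_exc_grid, I_inh = 0,
                       t_sim = 360, t_window = 120) {
  if (length(I_exc_grid) < 2)
    stop("I_exc_grid must contain at least 2 points", call. = FALSE)
  if (is.unsorted(I_exc_grid))
    stop("I_exc_grid must be sorted ascending", call. = FALSE)
  res <- lapply(I_exc_grid, function(Ie) {
    traj <- kndy_simulate(params,
                          input_fn = function(t) arc_input(Ie, I_inh),
                          t_span = c(0, t_sim), dt_out = 0.1)
    win <- traj[traj$time_min >= t_sim - t_window, , drop = FALSE]
    regime <- classify_regime(traj, c(t_sim - 60, t_sim))
    freq <- 0
    if (regime == "pulsatile") {
      # cycle rate from mid-level upward crossings: robust to the amplitude
      # shrinkage just below the upper bifurcation threshold, where a
      # fixed fraction of the peak no longer intersects every cycle
      mid <- (max(win$v) + min(win$v)) / 2
      below <- win$v < mid
      idx <- which(below[-nrow(win)] & !below[-1L])
      if (length(idx) >= 2) {
        tc <- win$time_min[idx]
        freq <- 60 / mean(diff(tc))
      }
    }
    data.frame(I_exc = Ie, frequency = freq, regime = regime)
  })
  out <- do.call(rbind, res)
  out$regime <- factor(out$regime,
                       levels = c("silent", "pulsatile", "quiescent_high"))
  out
}
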
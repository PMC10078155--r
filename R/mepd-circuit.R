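#' Parameters of the MePD firing-rate circuit
#'
#' Lumped firing-rate model of the posterodorsal medial amygdala (MePD)
#' circuit that modulates the arcuate pulse generator. Four populations are
#' tracked: the Kiss1 population \code{K}, a GABAergic interneuron population
#' \code{G1}, a glutamatergic population \code{E}, and the GABAergic efferent
#' (projection) population \code{G2}. Each relaxes with common time constant
#' \code{tau_m} towards a rectified saturating function \code{S} of its net
#' input:
#' \deqn{K \to \kappa_0 + \kappa_{opt}\,[light]}
#' \deqn{G1 \to S(w_{KG1} K)}
#' \deqn{E \to S(w_{KE} K + e_0)}
#' \deqn{G2 \to S(g_0 + (1-\beta_{glu}) w_{EG2} E
#'              - ((1-\beta_A) w_A + (1-\beta_B) w_B)\, G1)}
#' Kisspeptin drive thus excites the interneurons, which inhibit the efferent
#' projection (GABA-GABA disinhibition), and excites glutamatergic neurons
#' that both re-excite the efferents (intranuclear synapse, blockable by
#' ionotropic glutamate antagonists) and project to the arcuate nucleus. The
#' circuit output onto the pulse generator is \code{I_exc = w_Eout * E},
#' \code{I_inh = w_G2out * G2} (see [mepd_output()]).
#'
#' The inhibitory weight onto the efferents is split into a fast GABA-A-type
#' component \code{w_A} and a slow GABA-B-type component \code{w_B} so that
#' the two antagonist classes can be blocked separately; their default sizes
#' are calibrated so that GABA-A blockade during stimulation reverses the net
#' output (slowing the pulse generator) whereas GABA-B blockade merely
#' cancels the stimulatory gain.
#'
#' The defaults are a committed calibration against the pulse-generator core:
#' with the light off and basal kisspeptin activity at zero, the circuit
#' supplies a pure inhibitory tone that holds the coupled system at a
#' 25-30-min interpulse interval, and the six optogenetics-by-pharmacology
#' conditions reproduce the experimental direction pattern (see
#' [run_direction_table()]).
#'
#' @param tau_m Common relaxation time constant (min).
#' @param kappa0 Basal Kiss1 activity (0 in ovariectomised animals without
#'   steroid replacement).
#' @param kappa_opt Kiss1 activity increment while the optical stimulus is on.
#' @param w_KG1 Kiss1 to GABA-interneuron weight.
#' @param w_A,w_B GABA-A-type (fast) and GABA-B-type (slow) components of the
#'   interneuron-to-efferent inhibitory weight.
#' @param w_KE Kiss1 to glutamate weight.
#' @param e0 Basal drive to the glutamatergic population.
#' @param w_EG2 Glutamate to efferent excitatory weight (intranuclear).
#' @param g0 Basal drive to the efferent population.
#' @param w_G2out Efferent to inhibitory-output gain.
#' @param w_Eout Glutamate to excitatory-output gain.
#' @param slope_G1,thr_G1,slope_E,thr_E,slope_G2,thr_G2 Slope and threshold of
#'   each population's saturating gain function.
#' @param ... Reserved; must be empty.
#' @return An object of class \code{mepd_params}.
#' @export
mepd_params <- function(tau_m = 1, kappa0 = 0, kappa_opt = 1,
                        w_KG1 = 2, w_A = 0.67657, w_B = 0.47043,
                        w_KE = 1.5, e0 = 0, w_EG2 = 1.21690, g0 = 0.25968,
                        w_G2out = 0.5, w_Eout = 0.19665,
                        slope_G1 = 1, thr_G1 = 0,
                        slope_E = 1, thr_E = 0,
                        slope_G2 = 1, thr_G2 = 0, ...) {
  if (length(list(...)) > 0)
    stop("unknown mepd_params fields: ",
         paste(names(list(...)), collapse = ", "), call. = FALSE)
  p <- list(tau_m = tau_m, kappa0 = kappa0, kappa_opt = kappa_opt,
            w_KG1 = w_KG1, w_A = w_A, w_B = w_B, w_KE = w_KE, e0 = e0,
            w_EG2 = w_EG2, g0 = g0, w_G2out = w_G2out, w_Eout = w_Eout,
            slope_G1 = slope_G1, thr_G1 = thr_G1,
            slope_E = slope_E, thr_E = thr_E,
            slope_G2 = slope_G2, thr_G2 = thr_G2)
  check_finite(p, "mepd_params")
  with(p, {
    if (tau_m <= 0) stop("tau_m must be > 0", call. = FALSE)
    if (any(c(w_KG1, w_A, w_B, w_KE, w_EG2, w_G2out, w_Eout) < 0))
      stop("synaptic weights and gains must be >= 0", call. = FALSE)
    if (w_A + w_B <= 0) stop("w_A + w_B must be > 0", call. = FALSE)
  })
  structure(p, class = "mepd_params")
}

#' MePD population state
#'
#' @param K,G1,E,G2 Activities of the Kiss1, GABA-interneuron, glutamatergic
#'   and GABAergic-efferent populations (all >= 0, dimensionless).
#' @return Named numeric vector of class \code{mepd_state}.
#' @export
mepd_state <- function(K = 0, G1 = 0, E = 0, G2 = 0) {
  s <- c(K = K, G1 = G1, E = E, G2 = G2)
  check_finite(s, "mepd_state")
  if (any(s < 0)) stop("mepd_state fields must be >= 0", call. = FALSE)
  structure(s, class = "mepd_state")
}

#' Receptor-blockade condition
#'
#' Fractions of each receptor class blocked by an intra-MePD antagonist
#' infusion: \code{beta_A} for GABA-A (bicuculline), \code{beta_B} for GABA-B
#' (CGP-35348) and \code{beta_glu} for the intranuclear ionotropic glutamate
#' synapse onto the efferents (AP5 + CNQX cocktail). The antagonist effect
#' steps to its full value at \code{onset_min} (bolus) and is held constant
#' thereafter (continuous infusion).
#'
#' @param beta_A,beta_B,beta_glu Blockade fractions in [0, 1].
#' @param onset_min Time (min) the bolus takes effect.
#' @return An object of class \code{drug_condition}.
#' @export
drug_condition <- function(beta_A = 0, beta_B = 0, beta_glu = 0,
                           onset_min = 50) {
  b <- c(beta_A = beta_A, beta_B = beta_B, beta_glu = beta_glu)
  check_finite(c(b, onset_min = onset_min), "drug_condition")
  if (any(b < 0 | b > 1))
    stop("blockade fractions must lie in [0, 1]", call. = FALSE)
  structure(list(beta_A = beta_A, beta_B = beta_B, beta_glu = beta_glu,
                 onset_min = onset_min),
            class = "drug_condition")
}

#' Stimulation and infusion protocol
#'
#' The standard 150-min experiment: a 60-min control window with no
#' intervention, an antagonist bolus taking effect 10 min before the light
#' (50 min), and optical stimulation (when \code{light = TRUE}) from 60 min
#' to the end with continuous drug infusion.
#'
#' @param light Logical; optical stimulation during the treatment window.
#' @param drug A [drug_condition()].
#' @param t_total,control_end,light_on,light_off,drug_onset Protocol times
#'   (min), ordered \code{0 <= drug_onset <= light_on <= light_off <=
#'   t_total}.
#' @return An object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(light = TRUE, drug = drug_condition(),
                          t_total = 150, control_end = 60,
                          light_on = 60, light_off = 150,
                          drug_onset = drug$onset_min) {
  if (!(0 <= drug_onset && drug_onset <= light_on && light_on <= light_off &&
        light_off <= t_total))
    stop("protocol times must satisfy 0 <= drug_onset <= light_on <= ",
         "light_off <= t_total", call. = FALSE)
  structure(list(light = isTRUE(light), drug = drug, t_total = t_total,
                 control_end = control_end, light_on = light_on,
                 light_off = light_off, drug_onset = drug_onset),
            class = "stim_protocol")
}

#' Time derivatives of the MePD circuit
#'
#' @param state A [mepd_state()] or named numeric (K, G1, E, G2).
#' @param params A [mepd_params()].
#' @param drug A [drug_condition()]; blockade fractions are applied in full
#'   (onset timing is handled by [simulate_coupled()]).
#' @param light_on Logical; whether the optical stimulus is currently on.
#' @return Named numeric vector (dK, dG1, dE, dG2).
#' @export
mepd_derivatives <- function(state, params, drug = drug_condition(),
                             light_on = FALSE) {
  check_finite(state, "mepd_state")
  check_finite(params, "mepd_params")
  tgt <- mepd_targets(state, params, drug, light_on)
  cur <- c(state[["K"]], state[["G1"]], state[["E"]], state[["G2"]])
  d <- (tgt - cur) / params$tau_m
  names(d) <- c("dK", "dG1", "dE", "dG2")
  d
}

# Relaxation targets of the four populations; shared by the derivative
# function and the closed-form steady state (the wiring is feedforward).
mepd_targets <- function(state, params, drug, light_on) {
  p <- params
  K <- state[["K"]]; G1 <- state[["G1"]]; E <- state[["E"]]
  k_tgt <- p$kappa0 + if (isTRUE(light_on)) p$kappa_opt else 0
  g1_tgt <- sat(p$w_KG1 * K, p$slope_G1, p$thr_G1)
  e_tgt <- sat(p$w_KE * K + p$e0, p$slope_E, p$thr_E)
  w_inh <- (1 - drug$beta_A) * p$w_A + (1 - drug$beta_B) * p$w_B
  g2_tgt <- sat(p$g0 + (1 - drug$beta_glu) * p$w_EG2 * E - w_inh * G1,
                p$slope_G2, p$thr_G2)
  c(k_tgt, g1_tgt, e_tgt, g2_tgt)
}

#' Steady state of the MePD circuit
#'
#' The circuit wiring is feedforward (K drives G1 and E; G1 and E drive G2),
#' so the steady state follows in closed form by propagating the relaxation
#' targets through the chain.
#'
#' @inheritParams mepd_derivatives
#' @return A [mepd_state()].
#' @export
mepd_steady_state <- function(params, drug = drug_condition(),
                              light_on = FALSE) {
  p <- params
  K <- p$kappa0 + if (isTRUE(light_on)) p$kappa_opt else 0
  G1 <- sat(p$w_KG1 * K, p$slope_G1, p$thr_G1)
  E <- sat(p$w_KE * K + p$e0, p$slope_E, p$thr_E)
  w_inh <- (1 - drug$beta_A) * p$w_A + (1 - drug$beta_B) * p$w_B
  G2 <- sat(p$g0 + (1 - drug$beta_glu) * p$w_EG2 * E - w_inh * G1,
            p$slope_G2, p$thr_G2)
  mepd_state(K = K, G1 = G1, E = E, G2 = G2)
}

#' MePD output onto the arcuate pulse generator
#'
#' Linear readout of the projection populations: excitatory drive from the
#' glutamatergic population, inhibitory drive from the GABAergic efferents.
#'
#' @param state A [mepd_state()].
#' @param params A [mepd_params()].
#' @return An [arc_input()] with \code{I_exc = w_Eout * E},
#'   \code{I_inh = w_G2out * G2}.
#' @export
mepd_output <- function(state, params) {
  check_finite(state, "mepd_state")
  arc_input(I_exc = params$w_Eout * state[["E"]],
            I_inh = params$w_G2out * state[["G2"]])
}

#' Simulate the coupled MePD + KNDy system under a protocol
#'
#' Integrates the seven-dimensional coupled system (three KNDy variables,
#' four MePD populations) with light and drug switched at the protocol times;
#' the solver is restarted at each switch so the adaptive steps never cross a
#' discontinuity. Deterministic for fixed arguments.
#'
#' @param kndy A [kndy_params()].
#' @param mepd A [mepd_params()].
#' @param protocol A [stim_protocol()].
#' @param t_span Length-2 numeric (min); defaults to the full protocol.
#' @param dt_out Output grid spacing (min).
#' @param atol,rtol Integration tolerances.
#' @param init_kndy,init_mepd Initial states; the MePD default is its
#'   pre-treatment steady state so the control window is stationary.
#' @return A \code{pg_trajectory} with columns
#'   \code{time_min, D, N, v, K, G1, E, G2}.
#' @export
simulate_coupled <- function(kndy, mepd, protocol = stim_protocol(),
                             t_span = c(0, protocol$t_total), dt_out = 0.1,
                             atol = 1e-8, rtol = 1e-6,
                             init_kndy = kndy_state(),
                             init_mepd = mepd_steady_state(mepd)) {
  stopifnot(inherits(kndy, "kndy_params"), inherits(mepd, "mepd_params"),
            inherits(protocol, "stim_protocol"))
  no_drug <- drug_condition(onset_min = protocol$drug_onset)
  p <- mepd
  rhs <- function(t, y, parms) {
    light_now <- protocol$light && t >= protocol$light_on &&
      t < protocol$light_off
    drug_now <- if (t >= protocol$drug_onset) protocol$drug else no_drug
    K <- y[4L]; G1 <- y[5L]; E <- y[6L]; G2 <- y[7L]
    dk <- kndy_rhs_core(y[1:3], kndy, p$w_Eout * E, p$w_G2out * G2)
    k_tgt <- p$kappa0 + if (light_now) p$kappa_opt else 0
    g1_tgt <- sat(p$w_KG1 * K, p$slope_G1, p$thr_G1)
    e_tgt <- sat(p$w_KE * K + p$e0, p$slope_E, p$thr_E)
    w_inh <- (1 - drug_now$beta_A) * p$w_A + (1 - drug_now$beta_B) * p$w_B
    g2_tgt <- sat(p$g0 + (1 - drug_now$beta_glu) * p$w_EG2 * E - w_inh * G1,
                  p$slope_G2, p$thr_G2)
    list(c(dk, (c(k_tgt, g1_tgt, e_tgt, g2_tgt) - y[4:7]) / p$tau_m))
  }
  y0 <- c(unclass(init_kndy), unclass(init_mepd))
  switches <- c(protocol$drug_onset, protocol$light_on, protocol$light_off)
  out <- integrate_piecewise(rhs, y0, NULL, t_span, dt_out, atol, rtol,
                             switches)
  traj <- as.data.frame(out[, c("time", "D", "N", "v", "K", "G1", "E",
                                "G2")])
  names(traj)[1] <- "time_min"
  structure(traj, class = c("pg_trajectory", "data.frame"),
            v_max = kndy$v_max)
}
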
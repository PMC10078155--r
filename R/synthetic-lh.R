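#' Parameters for synthetic LH blood-sampling series
#'
#' Describes the generative model for tail-tip LH sampling data: a
#' gamma-renewal pulse train with mean interpulse interval \code{mu_ipi} and
#' interval coefficient of variation \code{cv_ipi}; lognormal pulse
#' amplitudes; instantaneous secretion followed by mono-exponential clearance
#' with time constant \code{tau_clear}; sampling every \code{sample_dt} min;
#' and multiplicative lognormal assay noise with coefficient of variation
#' \code{assay_cv} (default 4.6\%, the intra-assay variation of the LH
#' ELISA).
#'
#' @param mu_ipi Mean interpulse interval (min, > 0).
#' @param cv_ipi Interval coefficient of variation, in [0, 1).
#' @param amp_mean,amp_cv Mean (ng/ml) and coefficient of variation of the
#'   lognormal pulse-amplitude distribution.
#' @param baseline Basal LH concentration (ng/ml, >= 0).
#' @param tau_clear Clearance time constant (min, > 0).
#' @param assay_cv Multiplicative assay noise CV (>= 0).
#' @param sample_dt Sampling interval (min).
#' @param duration Total sampled duration (min).
#' @param switch_at Time (min) at which a cohort switches from pre- to
#'   post-treatment interval statistics.
#' @param ... Reserved; must be empty.
#' @return An object of class \code{lh_gen_params}.
#' @export
lh_gen_params <- function(mu_ipi = 25, cv_ipi = 0.2,
                          amp_mean = 2, amp_cv = 0.3,
                          baseline = 0.5, tau_clear = 15,
                          assay_cv = 0.046,
                          sample_dt = 5, duration = 150, switch_at = 60,
                          ...) {
  if (length(list(...)) > 0)
    stop("unknown lh_gen_params fields: ",
         paste(names(list(...)), collapse = ", "), call. = FALSE)
  p <- list(mu_ipi = mu_ipi, cv_ipi = cv_ipi, amp_mean = amp_mean,
            amp_cv = amp_cv, baseline = baseline, tau_clear = tau_clear,
            assay_cv = assay_cv, sample_dt = sample_dt, duration = duration,
            switch_at = switch_at)
  check_finite(p, "lh_gen_params")
  with(p, {
    if (mu_ipi <= 0) stop("mu_ipi must be > 0", call. = FALSE)
    if (cv_ipi < 0 || cv_ipi >= 1) stop("cv_ipi must be in [0, 1)",
                                        call. = FALSE)
    if (assay_cv < 0) stop("assay_cv must be >= 0", call. = FALSE)
    if (sample_dt <= 0) stop("sample_dt must be > 0", call. = FALSE)
    if (tau_clear <= 0) stop("tau_clear must be > 0", call. = FALSE)
    if (switch_at >= duration) stop("switch_at must be < duration",
                                    call. = FALSE)
  })
  structure(p, class = "lh_gen_params")
}

#' Sampled LH concentration series
#'
#' @param time_min Sampling grid (min), regular spacing.
#' @param lh_ngml LH concentrations (ng/ml, >= 0, finite).
#' @param animal_id Optional animal identifier.
#' @param arm Optional experimental-arm label.
#' @return Data frame of class \code{lh_series} with columns
#'   \code{time_min, lh_ngml} and attributes \code{animal_id}, \code{arm}.
#' @export
lh_series <- function(time_min, lh_ngml, animal_id = NA_character_,
                      arm = NA_character_) {
  if (length(time_min) != length(lh_ngml))
    stop("time and value vectors must have equal length", call. = FALSE)
  if (any(!is.finite(lh_ngml)) || any(lh_ngml < 0))
    stop("LH values must be finite and non-negative", call. = FALSE)
  if (length(time_min) > 2) {
    dts <- diff(time_min)
    if (any(abs(dts - dts[1]) > 1e-8))
      stop("sampling grid must be regular", call. = FALSE)
  }
  structure(data.frame(time_min = time_min, lh_ngml = lh_ngml),
            class = c("lh_series", "data.frame"),
            animal_id = animal_id, arm = arm)
}

# Evaluate a function with a temporary RNG state seeded at `seed`, restoring
# the caller's state afterwards so generators compose without side effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  expr
}

#' Sample pulse onset times as a gamma-renewal process
#'
#' Intervals are gamma distributed with mean \code{mu_ipi} and coefficient of
#' variation \code{cv_ipi} (shape \eqn{1/cv^2}); \code{cv_ipi = 0}
#' degenerates to exactly periodic intervals. The first pulse is uniformly
#' offset within one mean interval of the window start.
#'
#' @param params An [lh_gen_params()].
#' @param window Length-2 numeric (min), start <= end; an empty window
#'   yields an empty train.
#' @param rng_seed Integer seed; the result is reproducible for a fixed seed
#'   and the caller's RNG state is left untouched.
#' @return A [pulse_train()] of onset times within the window.
#' @export
sample_pulse_times <- function(params, window, rng_seed = NULL) {
  stopifnot(inherits(params, "lh_gen_params"), length(window) == 2)
  if (window[1] > window[2]) stop("window must be ordered", call. = FALSE)
  if (params$mu_ipi <= 0) stop("mu_ipi must be > 0", call. = FALSE)
  with_seed(rng_seed, {
    width <- window[2] - window[1]
    if (width == 0) return(pulse_train(numeric(0)))
    draw_gap <- function(n) {
      if (params$cv_ipi == 0) rep(params$mu_ipi, n)
      else {
        shape <- 1 / params$cv_ipi^2
        stats::rgamma(n, shape = shape, rate = shape / params$mu_ipi)
      }
    }
    t <- window[1] + stats::runif(1, 0, params$mu_ipi)
    times <- numeric(0)
    while (t <= window[2]) {
      times <- c(times, t)
      t <- t + draw_gap(1)
    }
    pulse_train(times)
  })
}

#' Render a noise-free LH series from a pulse train
#'
#' Each pulse deposits a lognormal amplitude that decays exponentially with
#' the clearance time constant; the series is the baseline plus the
#' superposition of all decaying pulses, evaluated on the regular sampling
#' grid from 0 to \code{duration}.
#'
#' @param train A [pulse_train()].
#' @param params An [lh_gen_params()].
#' @param rng_seed Seed for the amplitude draws.
#' @param animal_id,arm Passed to [lh_series()].
#' @return An [lh_series()] (noise-free).
#' @export
render_lh <- function(train, params, rng_seed = NULL,
                      animal_id = NA_character_, arm = NA_character_) {
  stopifnot(inherits(params, "lh_gen_params"))
  grid <- seq(0, params$duration, by = params$sample_dt)
  amps <- with_seed(rng_seed, rlnorm_mean_cv(length(train), params$amp_mean,
                                             params$amp_cv))
  vals <- rep(params$baseline, length(grid))
  for (i in seq_along(train)) {
    after <- grid >= train[i]
    vals[after] <- vals[after] +
      amps[i] * exp(-(grid[after] - train[i]) / params$tau_clear)
  }
  lh_series(grid, vals, animal_id = animal_id, arm = arm)
}

# Lognormal deviates parameterised by arithmetic mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (n == 0) return(numeric(0))
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Apply multiplicative assay noise to an LH series
#'
#' Each measurement is multiplied by an independent lognormal factor with
#' mean 1 and coefficient of variation \code{assay_cv}, emulating intra-assay
#' variability of the ELISA; \code{assay_cv = 0} returns the input unchanged.
#'
#' @param series An [lh_series()].
#' @param assay_cv Noise coefficient of variation (>= 0).
#' @param rng_seed Seed for the noise draws.
#' @return An [lh_series()] with noisy values.
#' @export
apply_assay_noise <- function(series, assay_cv, rng_seed = NULL) {
  stopifnot(inherits(series, "lh_series"))
  if (assay_cv < 0) stop("assay_cv must be >= 0", call. = FALSE)
  if (assay_cv == 0) return(series)
  factors <- with_seed(rng_seed,
                       rlnorm_mean_cv(nrow(series), 1, assay_cv))
  lh_series(series$time_min, series$lh_ngml * factors,
            animal_id = attr(series, "animal_id"), arm = attr(series, "arm"))
}

#' Generate a synthetic sampling cohort
#'
#' Produces \code{n_animals} independent LH series over the full experiment:
#' interval statistics follow \code{pre} up to \code{switch_at} and
#' \code{post} thereafter, with per-animal seeds derived deterministically
#' from the cohort seed. The ground-truth pulse trains are returned alongside
#' the noisy series so detector performance can be scored.
#'
#' @param pre,post [lh_gen_params()] for the control and treatment windows;
#'   grid settings (\code{sample_dt}, \code{duration}, \code{switch_at}) and
#'   amplitude/clearance settings must agree.
#' @param n_animals Number of animals (>= 1).
#' @param seed Cohort seed.
#' @param arm Arm label attached to each series.
#' @return List of length \code{n_animals}; each element is a list with
#'   components \code{series} (an [lh_series()]) and \code{train} (the true
#'   [pulse_train()]).
#' @export
generate_cohort <- function(pre, post = pre, n_animals = 7, seed = 1,
                            arm = NA_character_) {
  stopifnot(inherits(pre, "lh_gen_params"), inherits(post, "lh_gen_params"))
  if (n_animals < 1) stop("n_animals must be >= 1", call. = FALSE)
  same <- c("sample_dt", "duration", "switch_at", "amp_mean", "amp_cv",
            "baseline", "tau_clear", "assay_cv")
  if (!isTRUE(all.equal(pre[same], post[same])))
    stop("pre and post must share grid, amplitude and noise settings",
         call. = FALSE)
  lapply(seq_len(n_animals), function(i) {
    s <- (as.numeric(seed) * 1000 + i) %% .Machine$integer.max
    tr_pre <- sample_pulse_times(pre, c(0, pre$switch_at), rng_seed = s)
    tr_post <- sample_pulse_times(post, c(post$switch_at, post$duration),
                                  rng_seed = s + 500)
    train <- pulse_train(c(unclass(tr_pre), unclass(tr_post)))
    clean <- render_lh(train, pre, rng_seed = s + 750,
                       animal_id = sprintf("animal%02d", i), arm = arm)
    noisy <- apply_assay_noise(clean, pre$assay_cv, rng_seed = s + 250)
    list(series = noisy, train = train)
  })
}
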
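#' Pulse-detector parameters
#'
#' A two-threshold rise detector for sampled LH series: a candidate peak is
#' accepted when its rise above the preceding nadir exceeds both a fixed
#' fraction of the nadir level and a multiple of the expected assay noise at
#' that level, and calls are separated by a refractory interval. The defaults
#' were tuned on synthetic cohorts to reach at least 90\% sensitivity with at
#' most 0.1 false calls per hour at the default noise level.
#'
#' @param min_rise_frac Minimum fractional rise from the preceding nadir
#'   (> 0).
#' @param k_sigma Minimum rise in units of assay noise at the nadir level
#'   (>= 0).
#' @param refractory_min Minimum spacing between calls (min, >= 0).
#' @param assay_cv Assay coefficient of variation used for the noise-scaled
#'   threshold.
#' @return An object of class \code{detector_params}.
#' @export
detector_params <- function(min_rise_frac = 0.2, k_sigma = 3,
                            refractory_min = 10, assay_cv = 0.046) {
  if (min_rise_frac <= 0) stop("min_rise_frac must be > 0", call. = FALSE)
  if (k_sigma < 0) stop("k_sigma must be >= 0", call. = FALSE)
  if (refractory_min < 0) stop("refractory_min must be >= 0", call. = FALSE)
  if (assay_cv < 0) stop("assay_cv must be >= 0", call. = FALSE)
  structure(list(min_rise_frac = min_rise_frac, k_sigma = k_sigma,
                 refractory_min = refractory_min, assay_cv = assay_cv),
            class = "detector_params")
}

#' Detect LH pulses in a sampled series
#'
#' Scans the series for local maxima and accepts a peak as a pulse call when
#' its rise from the preceding nadir (the minimum since the previous call, or
#' since the start of the series) exceeds
#' \code{max(min_rise_frac, k_sigma * assay_cv) * nadir}, enforcing the
#' refractory spacing between consecutive calls. Deterministic; shifting the
#' series by a whole number of samples shifts all calls identically.
#'
#' @param series An [lh_series()] with at least 3 samples on a regular grid.
#' @param det A [detector_params()].
#' @return Data frame of class \code{pulse_calls} with columns
#'   \code{time_min}, \code{lh_ngml} (value at the peak) and \code{rise}
#'   (ng/ml above the preceding nadir).
#' @export
detect_pulses <- function(series, det = detector_params()) {
  stopifnot(inherits(series, "lh_series"))
  y <- series$lh_ngml; t <- series$time_min
  n <- length(y)
  if (n < 3) stop("series must contain at least 3 samples", call. = FALSE)
  dts <- diff(t)
  if (any(abs(dts - dts[1]) > 1e-8))
    stop("series is not on a regular sampling grid", call. = FALSE)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               y[n] > y[n - 1])
  calls <- integer(0)
  nadir_start <- 1L
  last_call_t <- -Inf
  for (i in which(is_peak)) {
    nadir <- min(y[nadir_start:i])
    rise <- y[i] - nadir
    thr <- max(det$min_rise_frac, det$k_sigma * det$assay_cv) * nadir
    if (rise > thr && (t[i] - last_call_t) >= det$refractory_min) {
      calls <- c(calls, i)
      last_call_t <- t[i]
      nadir_start <- i
    }
  }
  structure(data.frame(time_min = t[calls], lh_ngml = y[calls],
                       rise = y[calls] - vapply(seq_along(calls), function(k) {
                         lo <- if (k == 1L) 1L else calls[k - 1L]
                         min(y[lo:calls[k]])
                       }, numeric(1))),
            class = c("pulse_calls", "data.frame"))
}

#' Mean interpulse interval within a window, with censoring
#'
#' Averages successive call-time differences for calls falling in the
#' window. Windows are left-open/right-closed, except that a window starting
#' at 0 includes a call at exactly 0; a pulse exactly on the boundary between
#' control and treatment windows therefore belongs to the earlier window.
#' When fewer than two calls fall in the window no interval is observable and
#' the result is censored at \code{censor_value} (90 min by convention: the
#' value assigned when no pulses are seen in the post-treatment interval).
#'
#' @param calls A \code{pulse_calls} data frame, a [pulse_train()], or a
#'   numeric vector of call times (min).
#' @param window Length-2 numeric (min), ordered.
#' @param censor_value Interval (min) assigned to censored windows.
#' @return An object of class \code{ipi_result}: list with fields
#'   \code{window}, \code{n_pulses}, \code{mean_ipi}, \code{censored}.
#' @export
compute_ipi <- function(calls, window, censor_value = 90) {
  times <- if (is.data.frame(calls)) calls$time_min else as.numeric(calls)
  if (length(window) != 2 || window[1] > window[2])
    stop("window must be ordered", call. = FALSE)
  keep <- times > window[1] & times <= window[2]
  if (window[1] == 0) keep <- keep | times == 0
  times <- sort(times[keep])
  censored <- length(times) < 2
  structure(list(window = window, n_pulses = length(times),
                 mean_ipi = if (censored) censor_value else mean(diff(times)),
                 censored = censored),
            class = "ipi_result")
}

#' Summarise pre/post interpulse intervals for one experimental arm
#'
#' @param results List with one element per animal, each a list with
#'   components \code{pre} and \code{post} (both [compute_ipi()] results) and
#'   optionally \code{animal_id}.
#' @param arm Arm label.
#' @return An object of class \code{arm_summary}: list with a per-animal
#'   data frame (\code{animal_id, pre_ipi, post_ipi, delta_ipi,
#'   pre_censored, post_censored}) and group statistics (mean and SEM of the
#'   pre and post intervals, \code{n}).
#' @export
summarize_arm <- function(results, arm = NA_character_) {
  if (length(results) == 0) stop("empty cohort", call. = FALSE)
  per <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r$pre, "ipi_result"), inherits(r$post, "ipi_result"))
    data.frame(
      animal_id = if (!is.null(r$animal_id)) r$animal_id
                  else sprintf("animal%02d", i),
      pre_ipi = r$pre$mean_ipi, post_ipi = r$post$mean_ipi,
      delta_ipi = r$post$mean_ipi - r$pre$mean_ipi,
      pre_censored = r$pre$censored, post_censored = r$post$censored)
  }))
  n <- nrow(per)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(arm = arm, per_animal = per, n = n,
                 pre_mean = mean(per$pre_ipi), pre_sem = sem(per$pre_ipi),
                 post_mean = mean(per$post_ipi),
                 post_sem = sem(per$post_ipi)),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("Arm %s (n = %d)\n", x$arm, x$n))
  cat(sprintf("  pre  IPI: %.2f +/- %.2f min\n", x$pre_mean, x$pre_sem))
  cat(sprintf("  post IPI: %.2f +/- %.2f min\n", x$post_mean, x$post_sem))
  invisible(x)
}

#' Two-way repeated-measures comparison of interpulse intervals
#'
#' Thin wrapper around a standard two-way repeated-measures analysis of
#' variance with time (pre/post, within-animal) and arm (between-animal)
#' factors, fitted with [stats::aov()] with an animal error stratum. Returns
#' the F statistics, degrees of freedom and p values for the arm, time and
#' interaction terms; the interaction term carries the question of interest
#' (does the treatment change the interval more than control does).
#'
#' @param summaries List of [summarize_arm()] objects (>= 2 arms).
#' @return Data frame with columns \code{effect, df, df_resid, F, p}.
#' @export
compare_windows <- function(summaries) {
  if (length(summaries) < 2)
    stop("at least two arms are required", call. = FALSE)
  long <- do.call(rbind, lapply(summaries, function(s) {
    p <- s$per_animal
    data.frame(arm = s$arm,
               animal = paste(s$arm, p$animal_id, sep = ":"),
               time = rep(c("pre", "post"), each = nrow(p)),
               ipi = c(p$pre_ipi, p$post_ipi))
  }))
  counts <- table(long$animal)
  if (any(counts != 2))
    stop("unbalanced design: every animal needs exactly one pre and one ",
         "post interval", call. = FALSE)
  long$arm <- factor(long$arm)
  long$time <- factor(long$time, levels = c("pre", "post"))
  long$animal <- factor(long$animal)
  fit <- stats::aov(ipi ~ arm * time + Error(animal / time), data = long)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- as.data.frame(stratum[[1]])
    effs <- trimws(rownames(tab))
    resid_df <- tab$Df[effs == "Residuals"]
    for (k in which(effs %in% c("arm", "time", "arm:time"))) {
      rows[[effs[k]]] <- data.frame(
        effect = effs[k], df = tab$Df[k],
        df_resid = if (length(resid_df)) resid_df else NA_real_,
        F = tab$`F value`[k], p = tab$`Pr(>F)`[k])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
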
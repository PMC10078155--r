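#' Classify the dynamical regime of a firing-activity trajectory
#'
#' Applies the committed operational thresholds to the firing activity
#' \code{v} over a time window:
#' \itemize{
#'   \item \strong{silent} — \code{max(v) < 0.10 * v_max}: the network sits at
#'     a low fixed point.
#'   \item \strong{quiescent_high} — peak-to-trough variation
#'     \code{< 0.05 * v_max} while activity stays at or above
#'     \code{0.10 * v_max}: the depolarised, oscillation-terminated state
#'     reached above the upper bifurcation threshold.
#'   \item \strong{pulsatile} — everything else.
#' }
#' The window must be at least 30 min long so that at least one full cycle of
#' a physiological-range oscillation would fall inside it.
#'
#' @param traj A \code{pg_trajectory}.
#' @param window Length-2 numeric (min), contained in the trajectory.
#' @param v_max Maximal firing activity used to scale the thresholds;
#'   defaults to the trajectory's \code{v_max} attribute.
#' @return One of \code{"silent"}, \code{"pulsatile"},
#'   \code{"quiescent_high"}.
#' @export
classify_regime <- function(traj, window, v_max = attr(traj, "v_max")) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (is.null(v_max)) stop("v_max not supplied and not an attribute of traj",
                           call. = FALSE)
  if (diff(window) < 30)
    stop("window must span at least 30 min", call. = FALSE)
  if (window[1] < min(traj$time_min) - 1e-9 ||
      window[2] > max(traj$time_min) + 1e-9)
    stop("window must lie inside the trajectory", call. = FALSE)
  v <- traj$v[traj$time_min >= window[1] & traj$time_min <= window[2]]
  if (max(v) < 0.10 * v_max) return("silent")
  if (max(v) - min(v) < 0.05 * v_max && min(v) >= 0.10 * v_max)
    return("quiescent_high")
  "pulsatile"
}
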
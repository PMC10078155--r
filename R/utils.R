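#' Hill activation function
#'
#' Standard increasing Hill function \eqn{x^n / (K^n + x^n)}, used for all
#' saturating activation terms in the pulse-generator model.
#'
#' @param x Input (non-negative scalar or vector).
#' @param K Half-activation constant (> 0).
#' @param n Hill exponent (>= 1).
#' @return Value in [0, 1).
#' @keywords internal
hill <- function(x, K, n) {
  xn <- pmax(x, 0)^n
  xn / (K^n + xn)
}

#' Rectified saturating activation for firing-rate populations
#'
#' Monotone, saturating gain function used by the amygdala firing-rate
#' populations: \code{max(0, tanh(slope * (x - threshold)))}. It is exactly
#' zero at and below threshold, which makes basal quiescence exact rather
#' than asymptotic.
#'
#' @param x Net synaptic input.
#' @param slope Gain slope (> 0).
#' @param threshold Activation threshold.
#' @return Activity in [0, 1).
#' @keywords internal
sat <- function(x, slope = 1, threshold = 0) {
  pmax(0, tanh(slope * (x - threshold)))
}

# Stop with the name of the first non-finite element of a named numeric
# vector; used by derivative entry points to reject bad states/params.
check_finite <- function(x, what) {
  bad <- !is.finite(unlist(x))
  if (any(bad)) {
    stop(sprintf("non-finite value in %s: field '%s'", what,
                 names(unlist(x))[bad][1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Double-labelling fraction from mean cell counts
#'
#' Percentage of a reporter-expressing population co-labelled with a second
#' marker, from per-animal mean counts (e.g., the fraction of tdTomato
#' kisspeptin cells that are also EYFP positive after viral transduction).
#'
#' @param n_double Mean number of double-labelled cells.
#' @param n_total Mean number of cells in the reference population (> 0).
#' @return Percentage in [0, 100] (can exceed 100 only if counts do).
#' @examples
#' labelling_fraction(20.33, 24.50)
#' @export
labelling_fraction <- function(n_double, n_total) {
  stopifnot(is.numeric(n_double), is.numeric(n_total), n_total > 0,
            n_double >= 0)
  100 * n_double / n_total
}
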
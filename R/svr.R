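#' Linear epsilon-insensitive support-vector regression (no intercept)
#'
#' Solves `min_w 0.5 * ||w||^2 + C * sum_i max(0, |x_i'w - y_i| - epsilon)`
#' by coordinate descent on the dual: one box-constrained variable
#' `beta_i in [-C, C]` per observation, updated by a soft-threshold step,
#' with `w = X' beta` maintained incrementally. No intercept is fitted:
#' the mixture identity `B = S * F` has none, and a fitted intercept would
#' absorb background signal.
#'
#' Deterministic: coordinates are swept in fixed order until the largest
#' single-coordinate move falls below `tol` (or `max_iter` sweeps).
#'
#' @param X numeric matrix (observations x predictors).
#' @param y numeric response vector.
#' @param C box constraint (regularization strength; larger fits harder).
#' @param epsilon half-width of the insensitive tube, in units of `y`.
#' @param tol convergence tolerance on the coordinate step.
#' @param max_iter maximum number of full sweeps.
#' @return list with `w` (coefficients), `iterations`, `converged`.
#' @export
svr_linear <- function(X, y, C = 1, epsilon = 0.001, tol = 1e-10,
                       max_iter = 20000L) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) {
    tcsp_error("tcsp_input_error", "svr_linear: length(y) must equal nrow(X)")
  }
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    tcsp_error("tcsp_input_error", "svr_linear: non-finite input")
  }
  .svr_dcd(X, as.numeric(y), C, epsilon, tol, as.integer(max_iter))
}
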
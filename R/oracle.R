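#' Brute-force regression oracle for information measures
#'
#' Independent reference for the state-space backend: simulates one long
#' realization of the specified VAR process and estimates every partial
#' variance by ordinary least squares of the target's present on the
#' designated past lag sets, then applies the half-log-ratio formulas.
#' Converges to the model-implied values as `n_oracle` grows.
#'
#' Removing processes from a VAR's observation set leaves a VARMA
#' process, whose exact partial variance involves the whole past; the
#' oracle therefore regresses on a long lag window (default
#' `max(20, 4 * spec$m)` lags), long enough that the truncation error is
#' far below the sampling error at the default realization length.
#'
#' @param spec a stable [var_spec()].
#' @param n_oracle realization length (default 1e5).
#' @param seed optional integer for a reproducible realization.
#' @param m regression lag window for every partial variance.
#' @return an `info_measures` object (backend `"oracle"`).
#' @export
oracle_measures <- function(spec, n_oracle = 1e5, seed = NULL,
                            m = max(20L, 4L * spec$m)) {
  stopifnot(inherits(spec, "var_spec"))
  n_oracle <- as.integer(n_oracle)
  if (n_oracle - m <= spec$M * m + 1)
    stop("n_oracle too small to invert the regression design")
  X <- simulate_var(spec, n_oracle, seed = seed)
  mom <- lagged_moments(X, m)
  pv <- lapply(seq_len(spec$M), function(j) regression_partial_variances(mom, j))
  out <- measures_from_pv(pv, spec$labels, "oracle", m, n_oracle)
  attr(out, "partial_variances") <- pv
  out
}
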
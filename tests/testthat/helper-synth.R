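# Shared fixtures, built in code.

# Fraction of truth events matched by detections within tol seconds
# (sensitivity), and of detections matching truth (precision).
match_rates <- function(detected, truth, tol = 0.004) {
  sens <- mean(vapply(truth, function(t) min(abs(detected - t)), numeric(1)) <= tol + 1e-9)
  prec <- mean(vapply(detected, function(p) min(abs(truth - p)), numeric(1)) <= tol + 1e-9)
  c(sensitivity = sens, precision = prec)
}

# A small random stable VAR spec for property loops.
random_stable_spec <- function(M = 3, m = 1, max_rho = 0.9) {
  repeat {
    A <- lapply(seq_len(m), function(l)
      matrix(stats::rnorm(M * M, 0, 0.3 / sqrt(m)), M, M))
    rho <- netinfodyn:::spectral_radius(netinfodyn:::companion_matrix(A))
    if (rho < max_rho && rho > 0.1) {
      # random SPD innovation covariance
      L <- matrix(stats::rnorm(M * M, 0, 0.3), M, M)
      Sigma <- crossprod(L) + diag(M)
      return(var_spec(A, Sigma))
    }
  }
}

# One default synthetic recording reused across preprocessing tests.
default_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_recording(duration = 400, state = "MA",
                                                  seed = 424242)
    cache
  }
})
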
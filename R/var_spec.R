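#' VAR process specification
#'
#' Defines a stationary vector autoregressive process
#' \eqn{X_n = \sum_{l=1}^{m} A_l X_{n-l} + E_n}, \eqn{E_n \sim N(0, \Sigma)},
#' used both as ground truth for benchmark networks and as the parametric
#' model underlying all information measures.
#'
#' The convention throughout is `A[[l]][j, i]`: effect of series `i` at lag
#' `l` on series `j` (directed link i -> j).
#'
#' @param A list of m coefficient matrices (M x M), or a single matrix for
#'   an order-1 process.
#' @param Sigma innovation covariance (M x M, symmetric positive definite);
#'   defaults to the identity.
#' @param labels optional character vector of node names.
#' @param check if `TRUE` (default), reject unstable specifications.
#' @return An object of class `var_spec` with fields `M`, `m`, `A`, `Sigma`,
#'   `labels` and `truth_adjacency` (`truth_adjacency[i, j]` is `TRUE` iff
#'   some lag has a nonzero coefficient from i to j, diagonal excluded).
#' @export
var_spec <- function(A, Sigma = NULL, labels = NULL, check = TRUE) {
  if (is.matrix(A)) A <- list(A)
  if (!is.list(A) || !length(A)) stop("A must be a matrix or a list of matrices")
  M <- nrow(A[[1]])
  for (Al in A) {
    if (!is.matrix(Al) || nrow(Al) != M || ncol(Al) != M)
      stop("all coefficient blocks must be square M x M matrices")
  }
  if (is.null(Sigma)) Sigma <- diag(M)
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != M || ncol(Sigma) != M) stop("Sigma must be M x M")
  if (max(abs(Sigma - t(Sigma))) > 1e-10) stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  if (is.null(labels)) labels <- paste0("X", seq_len(M))
  truth <- matrix(FALSE, M, M)
  for (Al in A) truth <- truth | (t(Al) != 0)
  diag(truth) <- FALSE
  spec <- structure(
    list(M = M, m = length(A), A = A, Sigma = Sigma,
         labels = labels, truth_adjacency = truth),
    class = "var_spec")
  rho <- spectral_radius(companion_matrix(A))
  spec$spectral_radius <- rho
  if (check && rho >= 1)
    stop(sprintf("unstable VAR specification: companion spectral radius %.4f >= 1", rho))
  spec
}

#' @export
print.var_spec <- function(x, ...) {
  cat(sprintf("var_spec: M = %d nodes, order m = %d, spectral radius %.3f\n",
              x$M, x$m, x$spectral_radius))
  cat("nodes:", paste(x$labels, collapse = ", "), "\n")
  cat(sprintf("true directed links: %d\n", sum(x$truth_adjacency)))
  invisible(x)
}

# Companion matrix of the coefficient blocks (mM x mM).
companion_matrix <- function(A) {
  if (is.matrix(A)) A <- list(A)
  m <- length(A)
  M <- nrow(A[[1]])
  F <- matrix(0, m * M, m * M)
  F[seq_len(M), ] <- do.call(cbind, A)
  if (m > 1)
    F[(M + 1):(m * M), seq_len((m - 1) * M)] <- diag((m - 1) * M)
  F
}

spectral_radius <- function(F) {
  max(Mod(eigen(F, only.values = TRUE)$values))
}

# Discrete Lyapunov equation P = F P F' + Q, solved by doubling:
# P_{k+1} = P_k + F_k P_k F_k',  F_{k+1} = F_k^2, converging to
# sum_{i>=0} F^i Q F'^i for spectral radius < 1.
dlyap_solve <- function(F, Q, tol = 1e-12, max_iter = 200L) {
  P <- Q
  Fk <- F
  for (k in seq_len(max_iter)) {
    Pn <- P + Fk %*% P %*% t(Fk)
    if (max(abs(Pn - P)) < tol) return((Pn + t(Pn)) / 2)
    P <- Pn
    Fk <- Fk %*% Fk
  }
  stop("Lyapunov doubling did not converge (process too close to instability?)")
}

# Run fn with a locally seeded RNG, restoring the caller's stream afterwards.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a realization of a VAR process
#'
#' Draws Gaussian innovations with covariance `Sigma` and iterates the VAR
#' recursion; an initial burn-in segment is discarded so the returned
#' samples are (to numerical accuracy) a draw from the stationary process.
#'
#' @param spec a [var_spec()].
#' @param n_samples number of samples to return (must exceed the order).
#' @param seed optional integer; when given, output is reproducible and the
#'   caller's RNG stream is left untouched.
#' @param burn_in number of initial samples discarded (>= 500).
#' @return numeric matrix M x n_samples, rownames = node labels.
#' @export
simulate_var <- function(spec, n_samples, seed = NULL, burn_in = 500L) {
  stopifnot(inherits(spec, "var_spec"))
  if (spec$spectral_radius >= 1)
    stop(sprintf("cannot simulate unstable VAR (spectral radius %.4f)", spec$spectral_radius))
  if (n_samples <= spec$m) stop("n_samples must exceed the model order")
  burn_in <- max(as.integer(burn_in), 500L)
  M <- spec$M; m <- spec$m
  ntot <- n_samples + burn_in + m
  with_seed(seed, function() {
    L <- chol(spec$Sigma)
    E <- matrix(stats::rnorm(M * ntot), ntot, M) %*% L   # ntot x M
    X <- matrix(0, M, ntot)
    for (n in (m + 1):ntot) {
      x <- E[n, ]
      for (l in seq_len(m)) x <- x + spec$A[[l]] %*% X[, n - l]
      X[, n] <- x
    }
    out <- X[, (ntot - n_samples + 1):ntot, drop = FALSE]
    rownames(out) <- spec$labels
    out
  })
}

#' Benchmark VAR presets with known topology
#'
#' Three fixed specifications used to validate estimators end to end:
#' \describe{
#'   \item{independent}{7 uncoupled AR(1) nodes (no directed links).}
#'   \item{chain3}{3 nodes, X1 -> X2 -> X3, order 1; the 1 -> 3 influence
#'     is fully mediated by node 2, so the conditional transfer
#'     T(1 -> 3 | 2) is exactly zero.}
#'   \item{paperlike7}{7 nodes labelled RR, RESP, PAT, delta, theta,
#'     alpha, beta, mimicking a consistent peripheral topology:
#'     bidirectional RR/RESP coupling (negative-feedback loop, which keeps
#'     the strongly self-predictable pair stable), RR -> PAT, RESP -> PAT,
#'     and two brain-to-peripheral links (beta -> RR, alpha -> PAT).
#'     Self-coefficients give the storage ordering
#'     S_RR > S_RESP > S_PAT > band nodes.}
#' }
#'
#' Presets are deterministic; `seed` is accepted for interface uniformity
#' and ignored.
#'
#' @param name one of `"independent"`, `"chain3"`, `"paperlike7"`.
#' @param seed ignored (presets are fixed).
#' @return a [var_spec()].
#' @export
benchmark_preset <- function(name, seed = NULL) {
  name <- match.arg(name, c("independent", "chain3", "paperlike7"))
  if (name == "independent") {
    a <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3)
    return(var_spec(diag(a), labels = paste0("X", 1:7)))
  }
  if (name == "chain3") {
    A <- matrix(0, 3, 3)
    diag(A) <- 0.6
    A[2, 1] <- 0.4   # 1 -> 2
    A[3, 2] <- 0.4   # 2 -> 3
    return(var_spec(A, labels = c("X1", "X2", "X3")))
  }
  labels <- c("RR", "RESP", "PAT", "delta", "theta", "alpha", "beta")
  A <- matrix(0, 7, 7, dimnames = list(labels, labels))
  diag(A) <- c(0.85, 0.75, 0.45, 0.30, 0.30, 0.30, 0.30)
  A["RR", "RESP"]  <-  0.35   # RESP -> RR (respiratory sinus arrhythmia)
  A["RESP", "RR"]  <- -0.30   # RR -> RESP (cardiorespiratory feedback)
  A["PAT", "RR"]   <-  0.35   # RR -> PAT
  A["PAT", "RESP"] <-  0.30   # RESP -> PAT
  A["RR", "beta"]  <-  0.30   # brain -> peripheral
  A["PAT", "alpha"] <- 0.30   # brain -> peripheral
  var_spec(A, labels = labels)
}
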
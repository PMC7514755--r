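#' Fit a VAR model by least squares
#'
#' Block least-squares regression of \eqn{X_n} on the m stacked lags, with
#' no intercept (series are assumed zero-mean, as produced by
#' [standardize()]). The residual covariance uses the 1/(N - m)
#' normalization so that `Sigma[j, j]` equals the full-model partial
#' variance of target j used by the information measures.
#'
#' @param X numeric matrix, M x N (one row per series).
#' @param m model order (number of lags).
#' @return object of class `var_model`: fields `m`, `M`, `A` (list of m
#'   M x M blocks, `A[[l]][j, i]` = coefficient of series i, lag l, on
#'   series j), `Sigma`, `n_used` (effective sample count N - m),
#'   `residuals` ((N - m) x M), `stable`, `spectral_radius`, `labels`.
#' @export
fit_var <- function(X, m) {
  X <- as.matrix(X)
  M <- nrow(X); N <- ncol(X)
  m <- as.integer(m)
  if (m < 1) stop("order m must be >= 1")
  if (N - m <= M * m)
    stop(sprintf("series too short for identification: N - m = %d <= M*m = %d",
                 N - m, M * m))
  Y <- t(X[, (m + 1):N, drop = FALSE])                      # (N-m) x M
  Z <- lag_design(X, m)                                     # (N-m) x (M*m)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- setdiff(seq_len(ncol(Z)), qz$pivot[seq_len(qz$rank)])
    lab <- rownames(X); if (is.null(lab)) lab <- paste0("X", seq_len(M))
    nm <- paste(sprintf("%s(lag %d)", lab[(bad - 1) %% M + 1], (bad - 1) %/% M + 1),
                collapse = ", ")
    stop("rank-deficient lag design; collinear regressors: ", nm)
  }
  B <- qr.coef(qz, Y)                                       # (M*m) x M
  E <- Y - Z %*% B
  Sigma <- crossprod(E) / (N - m)
  A <- lapply(seq_len(m), function(l) t(B[((l - 1) * M + 1):(l * M), , drop = FALSE]))
  rho <- spectral_radius(companion_matrix(A))
  labels <- rownames(X); if (is.null(labels)) labels <- paste0("X", seq_len(M))
  structure(list(m = m, M = M, A = A, Sigma = Sigma, n_used = N - m,
                 residuals = E, stable = rho < 1, spectral_radius = rho,
                 labels = labels),
            class = "var_model")
}

# Lag design matrix: row n (for time index m+n) holds
# [x_{1,n+m-1},...,x_{M,n+m-1}, x_{1,n+m-2},...] -- lag-1 block first.
lag_design <- function(X, m) {
  M <- nrow(X); N <- ncol(X)
  Z <- matrix(0, N - m, M * m)
  for (l in seq_len(m))
    Z[, ((l - 1) * M + 1):(l * M)] <- t(X[, (m + 1 - l):(N - l), drop = FALSE])
  Z
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("var_model: M = %d, order m = %d, n_used = %d, spectral radius %.3f (%s)\n",
              x$M, x$m, x$n_used, x$spectral_radius,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Select the VAR order by the Akaike Information Criterion
#'
#' Fits orders 1..`max_order` and returns the one minimizing
#' \eqn{AIC(p) = N_{eff} \log\det\hat\Sigma(p) + 2 p M^2}; ties resolve to
#' the smallest order.
#'
#' @param X M x N series matrix (or a `network_series`).
#' @param max_order largest candidate order.
#' @return the selected order (integer); the AIC trace is attached as
#'   attribute `"aic"`.
#' @export
select_order_aic <- function(X, max_order = 12L) {
  if (inherits(X, "network_series")) X <- X$X
  X <- as.matrix(X)
  M <- nrow(X); N <- ncol(X)
  max_order <- as.integer(max_order)
  if (N <= M * max_order + 10)
    stop("series too short for the requested maximum order")
  aic <- rep(NA_real_, max_order)
  for (p in seq_len(max_order)) {
    fit <- fit_var(X, p)
    ld <- determinant(fit$Sigma, logarithm = TRUE)
    if (ld$sign <= 0) next
    aic[p] <- fit$n_used * as.numeric(ld$modulus) + 2 * p * M^2
  }
  if (all(is.na(aic))) stop("all candidate fits were singular")
  sel <- which.min(aic)   # first minimum = smallest order on ties
  attr(sel, "aic") <- aic
  sel
}

#' Convert a VAR model to its innovations-form state space
#'
#' Companion-form construction: state \eqn{z_n = [x_{n-1}; ...; x_{n-m}]}
#' (dimension mM), observation \eqn{x_n = C z_n + e_n} with
#' `C = [A_1 ... A_m]`, state transition `A_ss` the companion matrix, gain
#' `K = [I_M; 0]` and innovation covariance `V = Sigma`.
#'
#' @param var a `var_model` or `var_spec`.
#' @return object of class `ss_model` with fields `A_ss`, `C`, `K`, `V`,
#'   `M`, `m`, `labels`.
#' @export
var_to_ss <- function(var) {
  if (inherits(var, "var_spec"))
    var <- list(A = var$A, Sigma = var$Sigma, M = var$M, m = var$m,
                spectral_radius = var$spectral_radius, labels = var$labels)
  rho <- var$spectral_radius
  if (is.null(rho)) rho <- spectral_radius(companion_matrix(var$A))
  if (rho >= 1)
    stop(sprintf("unstable VAR (spectral radius %.4f): state-space measures undefined", rho))
  M <- var$M; m <- var$m
  K <- rbind(diag(M), matrix(0, (m - 1) * M, M))
  structure(list(A_ss = companion_matrix(var$A),
                 C = do.call(cbind, var$A),
                 K = K, V = var$Sigma, M = M, m = m, labels = var$labels),
            class = "ss_model")
}

# Discrete algebraic Riccati equation with cross-covariance:
#   P = F P F' + Q - (F P C' + S) (C P C' + R)^{-1} (F P C' + S)'
# The cross term is absorbed first (Ft = F - S R^{-1} C,
# Qt = Q - S R^{-1} S'), then the standard filter DARE is solved by the
# structure-preserving doubling algorithm (quadratic convergence, which a
# plain Riccati-difference iteration lacks for near-unit-root models);
# a fixed-point iteration remains as fallback. Returns the stabilizing
# state prediction-error covariance P.
dare_solve <- function(F, C, Q, R, S, tol = 1e-12, max_iter = 100L) {
  SRinv <- t(solve(R, t(S)))           # S R^{-1}
  Ft <- F - SRinv %*% C
  Qt <- Q - SRinv %*% t(S)
  Qt <- (Qt + t(Qt)) / 2
  n <- nrow(F)
  P <- tryCatch({
    Ak <- t(Ft)
    Gk <- t(C) %*% solve(R, C)
    Hk <- Qt
    P <- NULL
    for (k in seq_len(max_iter)) {
      W <- diag(n) + Gk %*% Hk
      WiA <- solve(W, Ak)
      An <- Ak %*% WiA
      Gn <- Gk + Ak %*% solve(W, Gk) %*% t(Ak)
      Hn <- Hk + t(Ak) %*% Hk %*% WiA
      Hn <- (Hn + t(Hn)) / 2
      if (max(abs(Hn - Hk)) < tol) { P <- Hn; break }
      Ak <- An; Gk <- (Gn + t(Gn)) / 2; Hk <- Hn
    }
    P
  }, error = function(e) NULL)
  if (is.null(P)) P <- dare_fixed_point(Ft, C, Qt, R, tol = tol)
  resid <- dare_residual(P, Ft, C, Qt, R)
  if (resid > 1e-8 * max(1, max(abs(P))))
    stop(sprintf("Riccati solver did not converge: residual norm %.3e", resid))
  P
}

dare_residual <- function(P, F, C, Q, R) {
  G <- F %*% P %*% t(C)
  max(abs(F %*% P %*% t(F) + Q - G %*% solve(C %*% P %*% t(C) + R, t(G)) - P))
}

dare_fixed_point <- function(F, C, Q, R, tol = 1e-12, max_iter = 10000L) {
  P <- Q
  for (k in seq_len(max_iter)) {
    G <- F %*% P %*% t(C)
    Pn <- F %*% P %*% t(F) + Q - G %*% solve(C %*% P %*% t(C) + R, t(G))
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol) return(Pn)
    P <- Pn
  }
  P
}

#' Innovation covariance of a reduced (sub-)model
#'
#' Removes the observation rows of all processes not in `keep` while
#' retaining the full mM-dimensional state, then solves the discrete
#' algebraic Riccati equation of the reduced model for the steady-state
#' innovation covariance of the kept processes. This is the partial
#' variance engine: the (j, j) entry of the result is the prediction-error
#' variance of process j given the past of exactly the processes in
#' `keep`.
#'
#' @param ss an `ss_model` from [var_to_ss()].
#' @param keep integer vector of retained process indices (subset of 1..M).
#' @return covariance matrix |keep| x |keep| (order follows `keep`).
#' @export
reduced_innovation_variance <- function(ss, keep) {
  stopifnot(inherits(ss, "ss_model"))
  keep <- sort(unique(as.integer(keep)))
  if (!length(keep) || any(keep < 1L | keep > ss$M))
    stop("keep must be a nonempty subset of 1..M")
  if (length(keep) == ss$M) return(ss$V)   # no reduction
  Ck <- ss$C[keep, , drop = FALSE]
  Q <- ss$K %*% ss$V %*% t(ss$K)
  R <- ss$V[keep, keep, drop = FALSE]
  S <- ss$K %*% ss$V[, keep, drop = FALSE]
  P <- dare_solve(ss$A_ss, Ck, Q, R, S)
  V <- Ck %*% P %*% t(Ck) + R
  (V + t(V)) / 2
}

#' All partial variances for one target process
#'
#' For target j computes, from the model (not from data):
#' \describe{
#'   \item{sigma2_j}{stationary process variance (discrete Lyapunov
#'     solution for the companion form).}
#'   \item{sigma2_j_self}{prediction-error variance given the target's own
#'     past only (reduced model keeping only j).}
#'   \item{sigma2_j_minus_i}{for every source i, the variance given the
#'     past of all processes except i (reduced model dropping i).}
#'   \item{sigma2_j_full}{variance given the past of all processes:
#'     `Sigma[j, j]` of the unreduced model.}
#' }
#' Nesting holds by construction:
#' `sigma2_j_full <= sigma2_j_minus_i <= sigma2_j` and
#' `sigma2_j_self <= sigma2_j`.
#'
#' @param var a stable `var_model` or `var_spec`.
#' @param j target process index.
#' @return list of class `partial_variances`.
#' @export
partial_variances <- function(var, j) {
  ss <- var_to_ss(var)
  M <- ss$M
  j <- as.integer(j)
  if (j < 1L || j > M) stop("target index out of range")
  Pz <- dlyap_solve(ss$A_ss, ss$K %*% ss$V %*% t(ss$K))
  Px <- ss$C %*% Pz %*% t(ss$C) + ss$V
  s2_minus <- rep(NA_real_, M)
  for (i in seq_len(M)) {
    if (i == j) next
    keep <- setdiff(seq_len(M), i)
    V <- reduced_innovation_variance(ss, keep)
    s2_minus[i] <- V[match(j, keep), match(j, keep)]
  }
  structure(list(j = j,
                 sigma2_j = Px[j, j],
                 sigma2_j_self = reduced_innovation_variance(ss, j)[1, 1],
                 sigma2_j_minus_i = s2_minus,
                 sigma2_j_full = ss$V[j, j]),
            class = "partial_variances")
}

#' Serialize / restore a VAR model as JSON
#'
#' @param var a `var_model` or `var_spec`.
#' @param path output file path.
#' @export
write_var_json <- function(var, path) {
  obj <- list(M = var$M, m = var$m,
              A = lapply(var$A, function(Al) unname(as.matrix(Al))),
              Sigma = unname(as.matrix(var$Sigma)),
              labels = var$labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_var_json
#' @return `read_var_json` returns a [var_spec()].
#' @export
read_var_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- obj$A
  if (is.array(A) && length(dim(A)) == 3)
    A <- lapply(seq_len(dim(A)[1]), function(l) A[l, , ])
  if (is.matrix(A)) A <- list(A)
  var_spec(lapply(A, as.matrix), as.matrix(obj$Sigma), labels = obj$labels)
}
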
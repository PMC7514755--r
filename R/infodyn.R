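# Information measures of Gaussian network processes, all in nats.
# For a jointly Gaussian stationary process the entropy of target j is
# H_j = 0.5*ln(2*pi*e*sigma2_j) and each predictive measure is half a log
# ratio of nested partial variances, so the decomposition
# H = S + T + N telescopes exactly when all four quantities are computed
# from one consistent set of variances.

LOG_2PIE <- log(2 * pi * exp(1))

#' Gaussian entropy of a node
#'
#' @param sigma2_j process variance (> 0).
#' @return entropy in nats: `0.5 * log(2*pi*e*sigma2_j)`.
#' @export
node_entropy <- function(sigma2_j) {
  if (any(sigma2_j <= 0)) stop("variance must be positive")
  0.5 * (LOG_2PIE + log(sigma2_j))
}

#' New information of a node
#'
#' Conditional entropy of the present given the past of the whole network:
#' `0.5 * log(2*pi*e*sigma2_full)` where `sigma2_full` is the full-model
#' partial variance.
#'
#' @param pv a `partial_variances` object (or a positive scalar).
#' @return new information N_j in nats.
#' @export
node_new_information <- function(pv) {
  s2 <- if (inherits(pv, "partial_variances")) pv$sigma2_j_full else pv
  if (s2 <= 0) stop("partial variance must be positive")
  0.5 * (LOG_2PIE + log(s2))
}

#' Information storage of a node
#'
#' Mutual information between the present and the node's own past:
#' `0.5 * log(sigma2_j / sigma2_self)`. Zero iff the own past carries no
#' information.
#'
#' @param pv a `partial_variances` object.
#' @return storage S_j in nats.
#' @export
node_storage <- function(pv) {
  stopifnot(inherits(pv, "partial_variances"))
  if (pv$sigma2_j <= 0 || pv$sigma2_j_self <= 0) stop("variances must be positive")
  0.5 * log(pv$sigma2_j / pv$sigma2_j_self)
}

#' Total (joint) information transfer to a node
#'
#' Information the present of the target receives from the pasts of all
#' sources beyond its own past:
#' `0.5 * log(sigma2_self / sigma2_full)`.
#'
#' @param pv a `partial_variances` object.
#' @return joint transfer entropy T_j in nats.
#' @export
node_total_transfer <- function(pv) {
  stopifnot(inherits(pv, "partial_variances"))
  if (pv$sigma2_j_self <= 0 || pv$sigma2_j_full <= 0) stop("variances must be positive")
  0.5 * log(pv$sigma2_j_self / pv$sigma2_j_full)
}

#' Conditional transfer entropy from one source
#'
#' Information transferred from source i to target j beyond the target's
#' own past and the pasts of all remaining sources k:
#' `0.5 * log(sigma2_{j|j,k} / sigma2_{j|j,s})`.
#'
#' @param pv a `partial_variances` object for target j.
#' @param i source index (i != j).
#' @return conditional transfer in nats.
#' @export
conditional_transfer <- function(pv, i) {
  stopifnot(inherits(pv, "partial_variances"))
  i <- as.integer(i)
  if (i == pv$j) stop("source must differ from target")
  s2k <- pv$sigma2_j_minus_i[i]
  if (is.na(s2k)) stop("source index out of range")
  0.5 * log(s2k / pv$sigma2_j_full)
}

# ---- regression (OLS) backend -------------------------------------------
# Second-moment matrix of [present; stacked lags], from which the residual
# variance of any OLS regression of a present value on a subset of lagged
# regressors is a Schur complement. Normalization 1/(N - m), matching
# fit_var's Sigma, so moment-based RSS values equal explicit OLS to
# machine precision.
lagged_moments <- function(X, m, chunk = 2e7) {
  X <- as.matrix(X)
  M <- nrow(X); N <- ncol(X)
  ncols <- M * (m + 1)
  if ((N - m) * ncols <= chunk) {
    W <- cbind(t(X[, (m + 1):N, drop = FALSE]), lag_design(X, m))
    G <- crossprod(W)
  } else {
    # accumulate W'W over row blocks to bound memory on long realizations
    G <- matrix(0, ncols, ncols)
    bs <- max(1000L, floor(chunk / ncols))
    starts <- seq(m + 1L, N, by = bs)
    for (s in starts) {
      e <- min(s + bs - 1L, N)
      rows <- s:e
      W <- matrix(0, length(rows), ncols)
      W[, seq_len(M)] <- t(X[, rows, drop = FALSE])
      for (l in seq_len(m))
        W[, (l * M + 1):((l + 1) * M)] <- t(X[, rows - l, drop = FALSE])
      G <- G + crossprod(W)
    }
  }
  list(G = G / (N - m), M = M, m = m, n_eff = N - m)
}

# Residual variance of regressing present of target j on the lag columns
# in `cols` (indices into the M*m lag block); cols empty -> raw second
# moment of the target over the regression sample.
moment_resid_var <- function(mom, j, cols) {
  G <- mom$G
  M <- mom$M
  gyy <- G[j, j]
  if (!length(cols)) return(gyy)
  zc <- M + cols
  Gzz <- G[zc, zc, drop = FALSE]
  gzy <- G[zc, j]
  R <- chol(Gzz)
  w <- backsolve(R, backsolve(R, gzy, transpose = TRUE))
  max(gyy - sum(gzy * w), 0)
}

lag_cols_for <- function(sources, M, m) {
  # columns of the lag design corresponding to the given source processes
  as.vector(outer(sources, (seq_len(m) - 1L) * M, `+`))
}

# Partial variances of target j by explicit least squares on the data.
regression_partial_variances <- function(mom, j) {
  M <- mom$M; m <- mom$m
  all_cols <- seq_len(M * m)
  s2_minus <- rep(NA_real_, M)
  for (i in seq_len(M)) {
    if (i == j) next
    s2_minus[i] <- moment_resid_var(mom, j, lag_cols_for(setdiff(seq_len(M), i), M, m))
  }
  structure(list(j = j,
                 sigma2_j = moment_resid_var(mom, j, integer(0)),
                 sigma2_j_self = moment_resid_var(mom, j, lag_cols_for(j, M, m)),
                 sigma2_j_minus_i = s2_minus,
                 sigma2_j_full = moment_resid_var(mom, j, all_cols)),
            class = "partial_variances")
}

# ---- assembly ------------------------------------------------------------

measures_from_pv <- function(pv_list, labels, backend, m, n) {
  M <- length(pv_list)
  H <- S <- Tt <- Nn <- numeric(M)
  Tcond <- matrix(NA_real_, M, M, dimnames = list(labels, labels))
  for (j in seq_len(M)) {
    pv <- pv_list[[j]]
    H[j]  <- node_entropy(pv$sigma2_j)
    S[j]  <- node_storage(pv)
    Tt[j] <- node_total_transfer(pv)
    Nn[j] <- node_new_information(pv)
    for (i in seq_len(M)) if (i != j) Tcond[i, j] <- conditional_transfer(pv, i)
  }
  structure(list(nodes = data.frame(node = labels, H = H, S = S, T = Tt, N = Nn,
                                    predictive = S + Tt,
                                    stringsAsFactors = FALSE),
                 Tcond = Tcond, labels = labels,
                 provenance = list(backend = backend, m = m, N = n)),
            class = "info_measures")
}

#' @export
print.info_measures <- function(x, ...) {
  cat(sprintf("info_measures (%s backend, m = %d, N = %s), nats:\n",
              x$provenance$backend, x$provenance$m, x$provenance$N))
  print(x$nodes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Model-implied information measures of a VAR specification
#'
#' Exact measures computed from the coefficients (no data): process
#' variances from the discrete Lyapunov equation and partial variances
#' from state-space submodel reduction.
#'
#' @param spec a [var_spec()] or fitted `var_model`.
#' @return an `info_measures` object (backend `"model"`).
#' @export
model_measures <- function(spec) {
  M <- spec$M
  pv <- lapply(seq_len(M), function(j) partial_variances(spec, j))
  measures_from_pv(pv, spec$labels, "model", spec$m, NA)
}

#' Information decomposition of a network time series
#'
#' Fits a VAR model (order by AIC unless given) to a standardized network
#' series and computes per-node entropy H, storage S, total transfer T and
#' new information N, plus the M x M conditional-transfer matrix
#' (`Tcond[i, j]` = transfer i -> j). The identity H = S + T + N holds to
#' numerical precision for both backends because H and S use the same
#' process variance as the other measures.
#'
#' @param net a `network_series` (standardized) or plain zero-mean M x N
#'   matrix.
#' @param m model order, or `"auto"` for AIC selection.
#' @param backend `"state-space"` (partial variances via Riccati submodels
#'   of the fitted VAR) or `"regression"` (explicit
#'   least squares of the target's present on each lag set; exact
#'   finite-sample decomposition).
#' @param max_order AIC search limit when `m = "auto"`.
#' @return an `info_measures` object; the fitted model is attached as
#'   attribute `"var_model"`.
#' @export
decompose_network <- function(net, m = "auto", backend = c("state-space", "regression"),
                              max_order = 12L) {
  backend <- match.arg(backend)
  if (inherits(net, "network_series")) {
    if (!isTRUE(net$standardized))
      stop("network series must be standardized before decomposition")
    X <- net$X
  } else X <- as.matrix(net)
  if (identical(m, "auto")) m <- select_order_aic(X, max_order)
  m <- as.integer(m)
  fit <- fit_var(X, m)
  labels <- fit$labels
  if (backend == "state-space") {
    if (!fit$stable)
      stop(sprintf("fitted VAR is unstable (spectral radius %.4f); state-space measures undefined",
                   fit$spectral_radius))
    pv <- lapply(seq_len(fit$M), function(j) partial_variances(fit, j))
  } else {
    mom <- lagged_moments(X, m)
    pv <- lapply(seq_len(fit$M), function(j) regression_partial_variances(mom, j))
  }
  out <- measures_from_pv(pv, labels, backend, m, ncol(X))
  attr(out, "var_model") <- fit
  out
}

#' Export information measures as tidy tables
#'
#' Writes one row per node (`subject, state, node, H, S, T, N`) and,
#' optionally, the square conditional-transfer matrix.
#'
#' @param im an `info_measures` object.
#' @param path output CSV path for the node table.
#' @param subject,state identifiers recorded in the table.
#' @param tcond_path optional path for the M x M conditional-transfer CSV.
#' @export
write_measures <- function(im, path, subject = NA, state = NA, tcond_path = NULL) {
  tab <- cbind(data.frame(subject = subject, state = state), im$nodes)
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(tcond_path))
    utils::write.csv(data.frame(source = rownames(im$Tcond), im$Tcond,
                                check.names = FALSE),
                     tcond_path, row.names = FALSE)
  invisible(path)
}
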
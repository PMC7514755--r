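# Per-subject significance of information transfer via the nested
# least-squares F-test, and the cross-subject consensus topology.

#' Nested-regression F-test for information transfer
#'
#' Compares the full linear prediction of the target's present from all
#' M*m lagged regressors against the restricted model omitting the m lags
#' of each removed source (both models re-estimated by least squares, no
#' intercept, zero-mean series):
#' `F = ((RSS_r - RSS_f)/q) / (RSS_f/d)` with `q = m * |removed|` and
#' `d = (N - m) - M*m`. Removing a single source tests the conditional
#' transfer from that source; removing all sources tests the total
#' transfer to the target.
#'
#' @param X M x N zero-mean series matrix (or `network_series`).
#' @param j target index.
#' @param removed source indices to omit (default: all sources, i.e. the
#'   total-transfer test).
#' @param m model order.
#' @return list of class `link_test`: `j`, `removed`, `F`, `df` (q, d),
#'   `p_value`, plus the two residual sums of squares.
#' @export
nested_f_test <- function(X, j, removed = NULL, m = 2L) {
  if (inherits(X, "network_series")) X <- X$X
  X <- as.matrix(X)
  M <- nrow(X); N <- ncol(X)
  j <- as.integer(j)
  if (is.null(removed)) removed <- setdiff(seq_len(M), j)
  removed <- as.integer(removed)
  if (j %in% removed) stop("cannot remove the target's own past")
  d <- (N - m) - M * m
  if (d <= 0) stop("nonpositive residual degrees of freedom")
  mom <- lagged_moments(X, m)
  full_cols <- seq_len(M * m)
  keep_cols <- lag_cols_for(setdiff(seq_len(M), removed), M, m)
  rss_f <- mom$n_eff * moment_resid_var(mom, j, full_cols)
  rss_r <- mom$n_eff * moment_resid_var(mom, j, keep_cols)
  q <- m * length(removed)
  Fstat <- if (q == 0) 0 else max(0, ((rss_r - rss_f) / q) / (rss_f / d))
  if (q == 0) q <- 1L   # degenerate comparison of identical models
  structure(list(j = j, removed = removed, F = Fstat, df = c(q = q, d = d),
                 p_value = stats::pf(Fstat, q, d, lower.tail = FALSE),
                 rss_full = rss_f, rss_restricted = rss_r),
            class = "link_test")
}

#' @export
print.link_test <- function(x, ...) {
  cat(sprintf("link_test: target %d, removed {%s}: F(%d, %d) = %.3f, p = %.4g\n",
              x$j, paste(x$removed, collapse = ","), x$df["q"], x$df["d"],
              x$F, x$p_value))
  invisible(x)
}

#' Per-subject significant-link graph
#'
#' Runs the nested F-test for every directed pair (i -> j, removing
#' source i at target j) and, per target, for the total transfer
#' (removing all sources at once).
#'
#' @param X M x N zero-mean series matrix or `network_series`.
#' @param m model order, or `"auto"` for AIC selection.
#' @param alpha significance level of each test.
#' @param max_order AIC search limit.
#' @return list of class `link_graph`: `adjacency` (M x M logical,
#'   entry (i, j) = source i significant into target j), `p_values`,
#'   `F`, `total` (data.frame of per-target total-transfer tests), `m`,
#'   `alpha`, `labels`.
#' @export
subject_link_graph <- function(X, m = "auto", alpha = 0.05, max_order = 12L) {
  labels <- if (inherits(X, "network_series")) X$labels else rownames(X)
  if (inherits(X, "network_series")) X <- X$X
  X <- as.matrix(X)
  M <- nrow(X)
  if (is.null(labels)) labels <- paste0("X", seq_len(M))
  if (identical(m, "auto")) m <- select_order_aic(X, max_order)
  m <- as.integer(m)
  mom <- lagged_moments(X, m)
  n_eff <- mom$n_eff
  d <- n_eff - M * m
  if (d <= 0) stop("nonpositive residual degrees of freedom")
  full_cols <- seq_len(M * m)
  P <- Fm <- matrix(NA_real_, M, M, dimnames = list(labels, labels))
  tot <- data.frame(target = labels, F = NA_real_, p_value = NA_real_,
                    significant = NA)
  for (j in seq_len(M)) {
    rss_f <- n_eff * moment_resid_var(mom, j, full_cols)
    for (i in seq_len(M)) {
      if (i == j) next
      keep <- lag_cols_for(setdiff(seq_len(M), i), M, m)
      rss_r <- n_eff * moment_resid_var(mom, j, keep)
      q <- m
      Fs <- max(0, ((rss_r - rss_f) / q) / (rss_f / d))
      Fm[i, j] <- Fs
      P[i, j] <- stats::pf(Fs, q, d, lower.tail = FALSE)
    }
    rss_r <- n_eff * moment_resid_var(mom, j, lag_cols_for(j, M, m))
    q <- m * (M - 1)
    Fs <- max(0, ((rss_r - rss_f) / q) / (rss_f / d))
    tot$F[j] <- Fs
    tot$p_value[j] <- stats::pf(Fs, q, d, lower.tail = FALSE)
  }
  tot$significant <- tot$p_value < alpha
  structure(list(adjacency = !is.na(P) & P < alpha, p_values = P, F = Fm,
                 total = tot, m = m, alpha = alpha, labels = labels),
            class = "link_graph")
}

#' Cross-subject consensus network
#'
#' Counts, per directed pair, the subjects whose link test was
#' significant and classifies links with the display thresholds: absent
#' (< `thin`), thin (`thin`..`thick`), thick (> `thick`). Node weights
#' are the mean total transfer across subjects when measures are given.
#'
#' @param graphs list of `link_graph` objects (one per subject).
#' @param measures optional list of `info_measures` (same order) for the
#'   node weights.
#' @param thin minimum count for a link to appear.
#' @param thick count above which a link is drawn thick.
#' @return list of class `consensus_graph`: `counts` (M x M), `class`
#'   (character M x M: "absent"/"thin"/"thick"), `n_subjects`,
#'   `mean_T` (per node, or NULL), `thresholds`, `labels`.
#' @export
consensus_graph <- function(graphs, measures = NULL, thin = 7L, thick = 12L) {
  if (!length(graphs)) stop("need at least one subject graph")
  labels <- graphs[[1]]$labels
  M <- length(labels)
  for (g in graphs)
    if (!identical(dim(g$adjacency), c(M, M)))
      stop("subject graphs have mismatched shapes")
  counts <- Reduce(`+`, lapply(graphs, function(g) {
    a <- g$adjacency; a[is.na(a)] <- FALSE; a * 1L
  }))
  dimnames(counts) <- list(labels, labels)
  cls <- matrix("absent", M, M, dimnames = list(labels, labels))
  cls[counts >= thin] <- "thin"
  cls[counts > thick] <- "thick"
  diag(cls) <- ""
  mean_T <- NULL
  if (!is.null(measures)) {
    Tmat <- vapply(measures, function(im) im$nodes$T, numeric(M))
    mean_T <- rowMeans(Tmat)
    names(mean_T) <- labels
  }
  structure(list(counts = counts, class = cls, n_subjects = length(graphs),
                 mean_T = mean_T, thresholds = c(thin = thin, thick = thick),
                 labels = labels),
            class = "consensus_graph")
}

#' @export
print.consensus_graph <- function(x, ...) {
  cat(sprintf("consensus_graph: %d subjects, thresholds >=%d thin / >%d thick\n",
              x$n_subjects, x$thresholds["thin"], x$thresholds["thick"]))
  edges <- which(x$class %in% c("thin", "thick"))
  if (!length(edges)) { cat("no consensus links\n"); return(invisible(x)) }
  idx <- arrayInd(edges, dim(x$counts))
  for (r in seq_len(nrow(idx)))
    cat(sprintf("  %s -> %s: %d subjects (%s)\n",
                x$labels[idx[r, 1]], x$labels[idx[r, 2]],
                x$counts[idx[r, 1], idx[r, 2]],
                x$class[idx[r, 1], idx[r, 2]]))
  invisible(x)
}

#' Export link results
#'
#' `write_link_graph` writes a per-subject edge list
#' (`source,target,F,p,significant`); `write_consensus` writes the
#' consensus edge list with counts and class, plus a JSON graph (nodes
#' with mean total transfer, edges with counts) for graph-exchange
#' tooling.
#'
#' @param g a `link_graph`.
#' @param path output CSV path.
#' @export
write_link_graph <- function(g, path) {
  M <- length(g$labels)
  idx <- which(upper.tri(matrix(0, M, M)) | lower.tri(matrix(0, M, M)))
  ij <- arrayInd(idx, c(M, M))
  tab <- data.frame(source = g$labels[ij[, 1]], target = g$labels[ij[, 2]],
                    F = g$F[idx], p = g$p_values[idx],
                    significant = g$adjacency[idx])
  tab <- tab[order(tab$target, tab$source), ]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_link_graph
#' @param cg a `consensus_graph`.
#' @param json_path optional path for the JSON graph export.
#' @export
write_consensus <- function(cg, path, json_path = NULL) {
  M <- length(cg$labels)
  idx <- which(row(cg$counts) != col(cg$counts))
  ij <- arrayInd(idx, c(M, M))
  tab <- data.frame(source = cg$labels[ij[, 1]], target = cg$labels[ij[, 2]],
                    count = cg$counts[idx], class = cg$class[idx])
  tab <- tab[order(tab$target, tab$source), ]
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(json_path)) {
    nodes <- lapply(seq_len(M), function(i)
      list(id = cg$labels[i],
           mean_T = if (is.null(cg$mean_T)) NULL else cg$mean_T[[i]]))
    edges <- lapply(which(tab$count > 0), function(r)
      list(source = tab$source[r], target = tab$target[r],
           count = tab$count[r], class = tab$class[r]))
    jsonlite::write_json(list(n_subjects = cg$n_subjects,
                              thresholds = as.list(cg$thresholds),
                              nodes = nodes, edges = edges),
                         json_path, digits = NA, auto_unbox = TRUE,
                         null = "null")
  }
  invisible(path)
}
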
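# End-to-end orchestration: study configuration, per-subject runs
# (raw recording -> network series -> information measures -> link
# tests) and multi-subject studies with per-state median tables and
# consensus graphs.

#' Study configuration
#'
#' Bundles every tunable of the pipeline with its default: the three
#' mental states, the 300-sample analysis window with its per-state
#' offsets, the EEG bands and epoching, the AIC search limit, the
#' significance level, the consensus display thresholds and the
#' measure backend.
#'
#' @param states analysed states.
#' @param n_window analysis window length (1 Hz samples).
#' @param rest_offset,task_offset window start offsets (s) for REST and
#'   for the task states (task offset configurable 60-120 s).
#' @param bands EEG bands (named list of Hz ranges).
#' @param epoch,hop EEG epoch length and hop (s).
#' @param max_order AIC search limit for the VAR order.
#' @param alpha per-test significance level.
#' @param thin,thick consensus count thresholds.
#' @param backend `"state-space"` or `"regression"`.
#' @param seed master seed for study generation.
#' @return list of class `study_config`.
#' @export
study_config <- function(states = c("REST", "MA", "SG"), n_window = 300L,
                         rest_offset = 180, task_offset = 60,
                         bands = eeg_bands(), epoch = 2, hop = 1,
                         max_order = 12L, alpha = 0.05,
                         thin = 7L, thick = 12L,
                         backend = c("state-space", "regression"),
                         seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(n_window > 0, rest_offset > 0, task_offset > 0,
            max_order >= 1, alpha > 0, alpha < 1, thin > 0, thick >= thin)
  if (task_offset < 60 || task_offset > 120)
    warning("task offset outside the 60-120 s range")
  structure(list(states = states, n_window = as.integer(n_window),
                 rest_offset = rest_offset, task_offset = task_offset,
                 bands = bands, epoch = epoch, hop = hop,
                 max_order = as.integer(max_order), alpha = alpha,
                 thin = as.integer(thin), thick = as.integer(thick),
                 backend = backend, seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a full synthetic study
#'
#' One recording per subject and state, with subject-specific
#' physiological parameters drawn around the generator defaults (mean
#' cardiac period, respiration rate, baseline pulse arrival time), so
#' subjects differ the way a small healthy cohort does. REST recordings
#' last 720 s (the protocol's 12-min rest phase), task recordings 420 s
#' (7-min phases).
#'
#' @param n_subjects number of subjects.
#' @param config a [study_config()]; its `seed` drives all draws.
#' @param dir optional directory; when given, each recording is written
#'   under `dir/<subject>_<state>/` and the manifest paths are returned.
#' @return nested list `recordings[[subject]][[state]]` of
#'   `raw_recording` objects (or manifest paths when `dir` is given).
#' @export
synth_study <- function(n_subjects = 18L, config = study_config(), dir = NULL) {
  with_seed(config$seed, function() {
    recs <- vector("list", n_subjects)
    names(recs) <- sprintf("S%02d", seq_len(n_subjects))
    for (s in seq_len(n_subjects)) {
      rr_mean <- stats::runif(1, 0.7, 0.95)
      resp_rate <- stats::runif(1, 0.2, 0.3)
      pat_base <- stats::runif(1, 0.2, 0.3)
      recs[[s]] <- lapply(stats::setNames(config$states, config$states),
                          function(st) {
        rec <- synth_recording(
          duration = if (st == "REST") 720 else 420,
          state = st, subject_id = names(recs)[s],
          rr_mean = rr_mean, resp_rate = resp_rate, pat_base = pat_base,
          seed = sample.int(.Machine$integer.max, 1))
        if (is.null(dir)) rec
        else write_recording(rec, file.path(dir, paste0(names(recs)[s], "_", st)))
      })
    }
    recs
  })
}

#' Run the pipeline for one subject recording
#'
#' Preprocesses the recording into the aligned network series, selects
#' and standardizes the analysis window, screens stationarity (failures
#' are flagged, not excluded), computes the information decomposition
#' and the per-link F-tests.
#'
#' @param rec a `raw_recording` or path to its manifest.
#' @param config a [study_config()].
#' @return list of class `subject_result`: `network`
#'   (standardized `network_series`), `measures` (`info_measures`),
#'   `links` (`link_graph`), `stationarity` (per-node results), `flags`
#'   (character vector), `subject_id`, `state`, `m`. On a stage failure
#'   an error condition is raised naming the stage.
#' @export
run_subject <- function(rec, config = study_config()) {
  if (is.character(rec)) rec <- read_recording(rec)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  aligned <- stage("preprocess", align_recording(rec, bands = config$bands))
  net <- stage("window", select_window(
    aligned, rec$state, n_window = config$n_window,
    rest_offset = config$rest_offset, task_offset = config$task_offset))
  flags <- character(0)
  stat <- apply(net$X, 1, function(x) check_stationarity(x, seed = config$seed))
  names(stat) <- net$labels
  nonstat <- names(stat)[!vapply(stat, `[[`, logical(1), "pass")]
  if (length(nonstat)) {
    flags <- c(flags, paste0("nonstationary:", nonstat))
    warning(sprintf("subject %s [%s]: stationarity check failed for %s; proceeding",
                    rec$subject_id, rec$state, paste(nonstat, collapse = ", ")))
  }
  net <- standardize(net)
  net$stationarity <- lapply(stat, function(s)
    list(pass = s$pass, n_reject = s$n_reject))
  measures <- stage("decompose", {
    m <- select_order_aic(net$X, config$max_order)
    tryCatch(decompose_network(net, m = m, backend = config$backend),
             error = function(e) {
               if (!grepl("unstable", conditionMessage(e))) stop(e)
               # near-unit-root windows have no state-space measures;
               # the finite-sample regression decomposition is still
               # defined, but the window is flagged and later excluded
               # from the consensus
               decompose_network(net, m = m, backend = "regression")
             })
  })
  fit <- attr(measures, "var_model")
  if (!fit$stable) flags <- c(flags, "unstable_fit")
  links <- stage("infer", subject_link_graph(net, m = measures$provenance$m,
                                             alpha = config$alpha))
  structure(list(network = net, measures = measures, links = links,
                 stationarity = stat, flags = flags,
                 subject_id = rec$subject_id, state = rec$state,
                 m = measures$provenance$m),
            class = "subject_result")
}

#' Run a multi-subject study
#'
#' Applies [run_subject()] to every recording, then per state assembles
#' the median tables of S, N and T across subjects (one column per node,
#' mirroring a per-state summary of the cohort) and the consensus graph.
#' Subjects whose VAR fit was flagged unstable are excluded from the
#' consensus (with a message) but kept in the measure tables.
#'
#' @param recordings nested list `[[subject]][[state]]` of
#'   `raw_recording` objects or manifest paths (as from [synth_study()]).
#' @param config a [study_config()].
#' @return list of class `study_result`: `subjects` (per-subject,
#'   per-state `subject_result`s), `measure_table` (tidy data.frame:
#'   subject, state, node, H, S, T, N), `medians` (list per measure of
#'   state x node median matrices), `consensus` (per-state
#'   `consensus_graph`), `excluded` (subject/state pairs left out of the
#'   consensus).
#' @export
run_study <- function(recordings, config = study_config()) {
  if (!length(recordings)) stop("need at least one subject")
  subjects <- names(recordings)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_along(recordings))
  results <- list()
  rows <- list()
  excluded <- character(0)
  for (s in seq_along(recordings)) {
    for (st in names(recordings[[s]])) {
      res <- run_subject(recordings[[s]][[st]], config)
      key <- paste0(subjects[s], ".", st)
      results[[key]] <- res
      rows[[key]] <- cbind(data.frame(subject = subjects[s], state = st),
                           res$measures$nodes)
      if ("unstable_fit" %in% res$flags) excluded <- c(excluded, key)
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  states <- unique(tab$state)
  labels <- results[[1]]$measures$labels
  medians <- lapply(c(S = "S", N = "N", T = "T"), function(meas) {
    out <- matrix(NA_real_, length(states), length(labels),
                  dimnames = list(states, labels))
    for (st in states) for (nd in labels)
      out[st, nd] <- stats::median(tab[tab$state == st & tab$node == nd, meas])
    out
  })
  if (length(excluded))
    message("excluded from consensus (unstable fit): ",
            paste(excluded, collapse = ", "))
  consensus <- lapply(stats::setNames(states, states), function(st) {
    keys <- names(results)[vapply(results, function(r) r$state == st, logical(1))]
    keys <- setdiff(keys, excluded)
    consensus_graph(lapply(results[keys], `[[`, "links"),
                    lapply(results[keys], `[[`, "measures"),
                    thin = config$thin, thick = config$thick)
  })
  structure(list(subjects = results, measure_table = tab, medians = medians,
                 consensus = consensus, excluded = excluded, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  ns <- length(unique(x$measure_table$subject))
  cat(sprintf("study_result: %d subjects x %d states\n", ns,
              length(unique(x$measure_table$state))))
  cat("\nmedian information storage S (nats):\n")
  print(round(x$medians$S, 3))
  cat("\nmedian total transfer T (nats):\n")
  print(round(x$medians$T, 3))
  invisible(x)
}

#' Write study outputs
#'
#' Per-state median tables (S, N, T; one row per state, one column per
#' node), the tidy per-subject measure table, and per-state consensus
#' edge lists with JSON graphs.
#'
#' @param study a `study_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$measure_table, file.path(dir, "measures.csv"),
                   row.names = FALSE)
  for (meas in names(study$medians))
    utils::write.csv(data.frame(state = rownames(study$medians[[meas]]),
                                study$medians[[meas]], check.names = FALSE),
                     file.path(dir, paste0("median_", meas, ".csv")),
                     row.names = FALSE)
  for (st in names(study$consensus))
    write_consensus(study$consensus[[st]],
                    file.path(dir, paste0("consensus_", st, ".csv")),
                    file.path(dir, paste0("consensus_", st, ".json")))
  invisible(dir)
}
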
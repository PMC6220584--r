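#' Write a trial table to CSV
#'
#' One row per trial, pulse strengths in columns `pulse_1..pulse_N`. The
#' generating configuration and seed should be written alongside with
#' [write_run_config()] so a session is fully reproducible.
#'
#' @param trials Trial table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads a CSV trial table and validates the schema: required columns
#' present, the expected number of `pulse_<i>` columns, binary choices, and
#' (unless `continuous = TRUE`, for external datasets with non-quantized
#' strengths) pulse strengths on the element lattice
#' `{-n_elements..n_elements}/n_elements`.
#'
#' @param path CSV path.
#' @param n_pulses Expected number of pulse columns; `NULL` accepts
#'   whatever the header provides.
#' @param n_elements Element-grid size used for the lattice check (19).
#' @param continuous Skip the lattice check.
#' @return A validated trial table.
#' @export
read_trial_table <- function(path, n_pulses = NULL, n_elements = 19L,
                             continuous = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)

  required <- c("session_id", "subject_id", "condition", "trial_index",
                "distribution_mu", "net_strength", "rewarded_direction",
                "frozen_seed", "choice", "correct")
  missing <- setdiff(required, colnames(trials))
  if (length(missing)) stop("missing required column(s): ", paste(missing, collapse = ", "))

  pcols <- grep("^pulse_[0-9]+$", colnames(trials), value = TRUE)
  if (length(pcols) == 0L) stop("no pulse_<i> columns found")
  if (!is.null(n_pulses) && length(pcols) != n_pulses) {
    stop("expected ", n_pulses, " pulse columns, found ", length(pcols))
  }

  ch <- trials$choice[!is.na(trials$choice)]
  if (length(ch) && !all(ch %in% c(0L, 1L))) {
    bad <- which(!is.na(trials$choice) & !(trials$choice %in% c(0L, 1L)))[1L]
    stop("non-binary choice at row ", bad)
  }
  if (!all(trials$rewarded_direction %in% c(-1L, 1L))) {
    bad <- which(!(trials$rewarded_direction %in% c(-1L, 1L)))[1L]
    stop("rewarded_direction must be -1/+1; offending row ", bad)
  }
  if (!continuous) {
    P <- pulse_matrix(trials)
    cnt <- P * n_elements
    off <- abs(cnt - round(cnt)) > 1e-8 | abs(cnt) > n_elements + 1e-8
    if (any(off)) {
      bad <- which(apply(off, 1L, any))[1L]
      stop("pulse strength off the element lattice at row ", bad,
           " (use continuous = TRUE for external data)")
    }
  }
  trials$frozen_seed <- as.logical(trials$frozen_seed)
  attr(trials, "n_pulses") <- length(pcols)
  attr(trials, "n_elements") <- as.integer(n_elements)
  trials
}

#' Run configuration for the full pipeline
#'
#' Bundles a stimulus configuration, an observer, and session/seed settings
#' into one reproducible run description. A fixed seed makes the whole run
#' (trial tables and reports) byte-identical.
#'
#' @param stimulus A [stimulus_config()].
#' @param observer An observer object (see [linear_observer()]).
#' @param n_trials Trials per session.
#' @param n_sessions Number of sessions to simulate.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param subject_id Subject identifier for the simulated sessions.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stimulus = stimulus_config(),
                       observer = linear_observer(rep(3, stimulus$n_pulses)),
                       n_trials = 500L, n_sessions = 3L, seed = 1L,
                       subject_id = "sim1") {
  stopifnot(inherits(stimulus, "stimulus_config"),
            inherits(observer, "observer"),
            n_trials >= 1, n_sessions >= 1)
  structure(
    list(stimulus = stimulus, observer = observer,
         n_trials = as.integer(n_trials), n_sessions = as.integer(n_sessions),
         seed = as.integer(seed), subject_id = subject_id),
    class = "run_config"
  )
}

# serializable form of a run config (for the sidecar JSON)
config_as_list <- function(config) {
  list(
    stimulus = unclass(config$stimulus),
    observer = c(list(type = class(config$observer)[1L]), unclass(config$observer)),
    n_trials = config$n_trials,
    n_sessions = config$n_sessions,
    seed = config$seed,
    subject_id = config$subject_id
  )
}

#' Write the sidecar run configuration
#'
#' Records the generating configuration and seed as JSON next to the trial
#' tables.
#'
#' @param config A [run_config()] (or a [stimulus_config()], wrapped as-is).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  obj <- if (inherits(config, "run_config")) config_as_list(config) else unclass(config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort of sessions, applies session QC, fits the
#' psychometric function (net strengths z-scored per subject across all of
#' that subject's sessions) and the temporal weighting kernel per session,
#' summarizes kernels (slope, energy), and runs the group statistics on the
#' QC-included sessions. All randomness derives from the single configured
#' seed via per-stage substream seeds, so identical configs produce
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes per-session trial
#'   tables (CSV), the session summary table (CSV), the cohort report
#'   (JSON) and the sidecar config (JSON, with its MD5 recorded in the
#'   report).
#' @param verbose Log per-stage timings and counts via [message()].
#' @return List of class `cohort_report`: `sessions` (summary data.frame
#'   with slope, energy, threshold, QC status), `group` (group statistics
#'   on included sessions, when >= 2 conditions... see
#'   [group_statistics()]), `seed`, `config_md5` (when written).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  set.seed(config$seed)
  stage_seeds <- sample.int(2^31 - 1, config$n_sessions * 2L)
  stim_seeds <- stage_seeds[seq_len(config$n_sessions)]
  obs_seeds <- stage_seeds[config$n_sessions + seq_len(config$n_sessions)]

  sessions <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    trials <- generate_session(config$stimulus, config$n_trials,
                               seed = stim_seeds[s],
                               session_id = sprintf("S%03d", s),
                               subject_id = config$subject_id)
    set.seed(obs_seeds[s])
    sessions[[s]] <- with_choices(trials, config$observer)
  }
  say("simulated %d sessions x %d trials (%.1fs)", config$n_sessions,
      config$n_trials, proc.time()[["elapsed"]] - t0)

  all_trials <- do.call(rbind, sessions)
  z_all <- zscore_strengths(all_trials$net_strength, all_trials$subject_id)

  summary_rows <- vector("list", config$n_sessions)
  offset <- 0L
  strong_mu <- max(abs(config$stimulus$mu_set))
  for (s in seq_len(config$n_sessions)) {
    trials <- sessions[[s]]
    z <- z_all[offset + seq_len(nrow(trials))]
    offset <- offset + nrow(trials)

    pf <- fit_psychometric(z, trials$choice)
    kf <- fit_kernel(trials)
    sl <- kernel_slope(kf)
    strong <- abs(trials$distribution_mu) >= strong_mu - 1e-12
    summary_rows[[s]] <- data.frame(
      session_id = trials$session_id[1L],
      subject_id = trials$subject_id[1L],
      condition = trials$condition[1L],
      n_trials = nrow(trials),
      strong_accuracy = mean(trials$correct[strong]),
      alpha = pf$alpha, beta = pf$beta, gamma = pf$gamma,
      threshold = pf$threshold75,
      lambda = kf$lambda,
      slope = sl[["slope"]], intercept = sl[["intercept"]],
      energy = kernel_energy(kf),
      stringsAsFactors = FALSE
    )
  }
  summary_df <- do.call(rbind, summary_rows)
  say("fitted psychometric + kernel for %d sessions (%.1fs total)",
      config$n_sessions, proc.time()[["elapsed"]] - t0)

  summary_df <- session_qc(summary_df)
  included <- summary_df[summary_df$included, ]

  group <- NULL
  if (nrow(included) >= 2L) {
    group <- tryCatch(
      group_statistics(included$slope, included$condition),
      error = function(e) NULL
    )
  }

  report <- structure(
    list(sessions = summary_df, group = group, seed = config$seed,
         config_md5 = NA_character_),
    class = "cohort_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(out_dir, "run_config.json")
    write_run_config(config, cfg_path)
    report$config_md5 <- unname(tools::md5sum(cfg_path))
    for (s in seq_len(config$n_sessions)) {
      write_trial_table(sessions[[s]],
                        file.path(out_dir, sprintf("trials_S%03d.csv", s)))
    }
    utils::write.csv(summary_df, file.path(out_dir, "session_summary.csv"),
                     row.names = FALSE)
    json_report <- list(
      seed = config$seed,
      config_md5 = report$config_md5,
      n_sessions = config$n_sessions,
      n_included = sum(summary_df$included),
      sessions = summary_df,
      group = if (is.null(group)) NULL else list(
        per_condition = group$per_condition,
        anova_p = group$anova_p,
        bartlett = group$bartlett
      )
    )
    jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  say("pipeline done in %.1fs", proc.time()[["elapsed"]] - t0)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d sessions (%d included by QC), seed %d\n",
              nrow(x$sessions), sum(x$sessions$included), x$seed))
  print(x$sessions[, c("session_id", "condition", "n_trials", "threshold",
                       "slope", "energy", "included")])
  if (!is.null(x$group)) {
    cat("Group statistics (included sessions):\n")
    print(x$group$per_condition)
  }
  invisible(x)
}
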
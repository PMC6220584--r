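#' Stimulus configuration for the pulse-based motion task
#'
#' Builds a validated configuration for the generative motion stimulus: a
#' trial is a sequence of brief motion pulses whose signed strengths (the
#' proportion of coherently drifting Gabor elements, sign = direction) are
#' drawn from one of five Gaussian generating distributions. The mean of the
#' generating distribution can be held constant over pulses (`"flat"`), or
#' ramped down (`"early"`) or up (`"late"`) across the trial via a smooth
#' logistic transition.
#'
#' @param n_pulses Number of motion pulses per trial (default 7).
#' @param pulse_duration_ms Duration of each pulse in milliseconds
#'   (150 by default; 100 for the short variant).
#' @param n_elements Number of Gabor elements in the stimulus grid (19).
#'   Realized strengths live on the lattice `{-n_elements..n_elements}/n_elements`.
#' @param mu_set The five signed generating means, as proportions in
#'   \[-1, 1\] (strong left, weak left, zero-mean, weak right, strong right).
#' @param sigma Gaussian SD of pulse strength, as a proportion (0.15).
#' @param condition One of `"flat"`, `"early"`, `"late"`.
#' @param transition_midpoint Pulse index at which the logistic transition is
#'   centred (4).
#' @param transition_slope Scale of the logistic transition (0.3); smaller
#'   values give a sharper switch between the first and last pulses.
#' @param frozen_seed_fraction Fraction of trials in a session that repeat a
#'   single fixed zero-sum pulse sequence, in \[0, 0.10\] typically.
#' @param trial_type_probabilities Probability of each generating
#'   distribution in `mu_set`; must sum to 1.
#'
#' @return An object of class `stimulus_config`.
#' @examples
#' cfg <- stimulus_config()
#' cfg$n_pulses * cfg$pulse_duration_ms  # total stimulus duration, ms
#' @export
stimulus_config <- function(n_pulses = 7L,
                            pulse_duration_ms = 150,
                            n_elements = 19L,
                            mu_set = c(-0.50, -0.10, 0, 0.10, 0.50),
                            sigma = 0.15,
                            condition = c("flat", "early", "late"),
                            transition_midpoint = 4,
                            transition_slope = 0.3,
                            frozen_seed_fraction = 0,
                            trial_type_probabilities = rep(1 / length(mu_set), length(mu_set))) {
  condition <- match.arg(condition)
  n_pulses <- as.integer(n_pulses)
  n_elements <- as.integer(n_elements)
  stopifnot(
    n_pulses >= 1L,
    n_elements >= 1L,
    sigma >= 0,
    all(mu_set >= -1 & mu_set <= 1),
    length(trial_type_probabilities) == length(mu_set),
    all(trial_type_probabilities >= 0),
    frozen_seed_fraction >= 0, frozen_seed_fraction <= 1,
    transition_slope > 0
  )
  if (abs(sum(trial_type_probabilities) - 1) > 1e-8) {
    stop("trial_type_probabilities must sum to 1")
  }
  structure(
    list(
      n_pulses = n_pulses,
      pulse_duration_ms = pulse_duration_ms,
      n_elements = n_elements,
      mu_set = mu_set,
      sigma = sigma,
      condition = condition,
      transition_midpoint = transition_midpoint,
      transition_slope = transition_slope,
      frozen_seed_fraction = frozen_seed_fraction,
      trial_type_probabilities = trial_type_probabilities
    ),
    class = "stimulus_config"
  )
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat("Pulse-stimulus configuration\n")
  cat(sprintf("  %d pulses x %g ms = %g ms, %d Gabor elements\n",
              x$n_pulses, x$pulse_duration_ms,
              x$n_pulses * x$pulse_duration_ms, x$n_elements))
  cat(sprintf("  condition: %s;  generating means: %s;  sigma: %g\n",
              x$condition, paste(x$mu_set, collapse = ", "), x$sigma))
  if (x$frozen_seed_fraction > 0) {
    cat(sprintf("  frozen-seed fraction: %g\n", x$frozen_seed_fraction))
  }
  invisible(x)
}

# round half away from zero, so +/-x round symmetrically
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-pulse mean profile for one trial type
#'
#' Expands a generating mean `mu` into the vector of per-pulse means implied
#' by the stimulus condition. In the flat condition every pulse has mean
#' `mu`. In the late condition the mean starts at exactly 0 on pulse 1 and
#' reaches exactly `mu` on the last pulse, following a logistic transition
#' (midpoint and slope from the config) affinely rescaled to pin the two
#' endpoints. The early condition is the exact time-reverse of late. A
#' zero-mean trial (`mu = 0`) has an all-zero profile in every condition.
#'
#' @param config A [stimulus_config()].
#' @param mu A generating mean from `config$mu_set`.
#' @return Numeric vector of length `config$n_pulses` of per-pulse means.
#' @examples
#' condition_profile(stimulus_config(condition = "late"), 0.10)
#' @export
condition_profile <- function(config, mu) {
  stopifnot(inherits(config, "stimulus_config"))
  if (!any(abs(config$mu_set - mu) < 1e-12)) {
    stop("mu must be one of config$mu_set")
  }
  n <- config$n_pulses
  if (config$condition == "flat" || mu == 0 || n == 1L) {
    return(rep(mu, n))
  }
  i <- seq_len(n)
  t_raw <- stats::plogis((i - config$transition_midpoint) / config$transition_slope)
  # pin endpoints: exactly 0 at pulse 1, exactly 1 at pulse n
  t_scaled <- (t_raw - t_raw[1L]) / (t_raw[n] - t_raw[1L])
  if (config$condition == "early") t_scaled <- rev(t_scaled)
  mu * t_scaled
}

#' Sample the stimulus of a single trial
#'
#' Draws each pulse independently from a Gaussian with the per-pulse mean of
#' `profile` and SD `config$sigma`, then quantizes to the physical grid:
#' strength times `n_elements` is rounded half-away-from-zero to a signed
#' element count and clipped to `+/-n_elements`. Consumes the current RNG
#' state.
#'
#' @param profile Per-pulse mean vector from [condition_profile()].
#' @param config A [stimulus_config()].
#' @return A list with `pulse_strengths` (realized, post-rounding),
#'   `pulse_element_counts` (signed integers) and `net_strength`
#'   (sum of realized strengths).
#' @export
sample_trial <- function(profile, config) {
  stopifnot(length(profile) == config$n_pulses)
  x <- stats::rnorm(config$n_pulses, mean = profile, sd = config$sigma)
  counts <- round_half_away(x * config$n_elements)
  counts <- pmax(pmin(counts, config$n_elements), -config$n_elements)
  strengths <- counts / config$n_elements
  list(
    pulse_strengths = strengths,
    pulse_element_counts = as.integer(counts),
    net_strength = sum(strengths)
  )
}

# Rejection-sample a pulse sequence from the zero-mean distribution whose
# element counts sum to exactly zero (used for frozen-seed trials).
frozen_pulse_sequence <- function(config, max_tries = 10000L) {
  profile <- rep(0, config$n_pulses)
  for (i in seq_len(max_tries)) {
    tr <- sample_trial(profile, config)
    if (sum(tr$pulse_element_counts) == 0L) return(tr)
  }
  stop("could not construct a zero-sum frozen-seed sequence in ", max_tries, " tries")
}

#' Generate a session of stimulus trials
#'
#' Draws `n_trials` trials: each trial's generating distribution is sampled
#' from `config$trial_type_probabilities`; a `config$frozen_seed_fraction`
#' share of trials instead repeat one fixed pulse sequence whose element
#' counts sum to exactly zero. The rewarded direction is the sign of the net
#' (summed) realized strength; exact-zero sums are rewarded at random.
#' Choice-dependent columns (`choice`, `correct`) are left `NA` until an
#' observer (see [simulate_choices()]) or external data supplies them.
#'
#' @param config A [stimulus_config()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @param session_id,subject_id Identifier strings stored per trial.
#' @return A `data.frame` with one row per trial: identifiers, condition,
#'   `trial_index`, `distribution_mu`, pulse strengths in columns
#'   `pulse_1..pulse_N`, `net_strength`, `rewarded_direction` (-1/+1),
#'   `frozen_seed`, and `NA` placeholders for `choice` and `correct`.
#' @examples
#' trials <- generate_session(stimulus_config(), 100, seed = 1)
#' table(trials$distribution_mu)
#' @export
generate_session <- function(config, n_trials, seed = NULL,
                             session_id = "S1", subject_id = "subj1") {
  stopifnot(inherits(config, "stimulus_config"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_trials <- as.integer(n_trials)

  n_frozen <- as.integer(round(config$frozen_seed_fraction * n_trials))
  frozen_idx <- if (n_frozen > 0L) sort(sample.int(n_trials, n_frozen)) else integer(0)
  frozen_tr <- if (n_frozen > 0L) frozen_pulse_sequence(config) else NULL

  mu_idx <- sample.int(length(config$mu_set), n_trials, replace = TRUE,
                       prob = config$trial_type_probabilities)
  mus <- config$mu_set[mu_idx]

  # cache the profile for each distinct mu
  profiles <- lapply(config$mu_set, function(m) condition_profile(config, m))

  P <- matrix(0, n_trials, config$n_pulses)
  net <- numeric(n_trials)
  frozen <- logical(n_trials)
  frozen[frozen_idx] <- TRUE
  for (t in seq_len(n_trials)) {
    if (frozen[t]) {
      mus[t] <- 0
      P[t, ] <- frozen_tr$pulse_strengths
      net[t] <- frozen_tr$net_strength
    } else {
      tr <- sample_trial(profiles[[mu_idx[t]]], config)
      P[t, ] <- tr$pulse_strengths
      net[t] <- tr$net_strength
    }
  }

  rewarded <- sign(net)
  n_zero <- sum(rewarded == 0)
  if (n_zero > 0) {
    rewarded[rewarded == 0] <- sample(c(-1, 1), n_zero, replace = TRUE)
  }

  out <- data.frame(
    session_id = session_id,
    subject_id = subject_id,
    condition = config$condition,
    trial_index = seq_len(n_trials),
    distribution_mu = mus,
    stringsAsFactors = FALSE
  )
  colnames(P) <- paste0("pulse_", seq_len(config$n_pulses))
  out <- cbind(out, as.data.frame(P))
  out$net_strength <- net
  out$rewarded_direction <- as.integer(rewarded)
  out$frozen_seed <- frozen
  out$choice <- NA_integer_
  out$correct <- NA_integer_
  attr(out, "n_pulses") <- config$n_pulses
  attr(out, "n_elements") <- config$n_elements
  out
}

#' Extract the pulse-strength matrix from a trial table
#'
#' @param trials A trial table from [generate_session()] or
#'   [read_trial_table()].
#' @return Numeric matrix, one row per trial, one column per pulse.
#' @export
pulse_matrix <- function(trials) {
  cols <- grep("^pulse_[0-9]+$", colnames(trials), value = TRUE)
  if (length(cols) == 0L) stop("no pulse_<i> columns found")
  ord <- order(as.integer(sub("^pulse_", "", cols)))
  as.matrix(trials[, cols[ord], drop = FALSE])
}

#' Signed element counts of a trial table
#'
#' Converts realized pulse strengths back to signed Gabor element counts.
#'
#' @param trials A trial table.
#' @param n_elements Number of elements in the grid; taken from the table's
#'   attribute when present.
#' @return Integer matrix of signed counts.
#' @export
pulse_counts <- function(trials, n_elements = NULL) {
  if (is.null(n_elements)) n_elements <- attr(trials, "n_elements")
  if (is.null(n_elements)) stop("n_elements not supplied and not stored on the table")
  cnt <- pulse_matrix(trials) * n_elements
  storage.mode(cnt) <- "double"
  round_half_away(cnt)
}
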
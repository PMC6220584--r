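# Shared fixtures, built in code.

# Ground-truth kernel shapes used in recovery experiments: uniform, linear
# ramps, a late hump with a final-pulse dip, and a steep early profile.
kernel_shapes <- function() {
  list(
    flat = rep(1, 7),
    linear_down = seq(1.3, 0.7, length.out = 7),
    linear_up = seq(0.7, 1.3, length.out = 7),
    late_humped = c(0.1, 0.2, 0.3, 0.45, 0.55, 0.5, 0.35),
    early_steep = c(0.55, 0.5, 0.4, 0.2, 0.12, 0.08, 0.05)
  )
}

unit_norm <- function(w) w / sqrt(sum(w^2))

# zero-mean-only stimulus: every trial from the mu = 0 distribution, the
# classical reverse-correlation design
zero_mean_config <- function(...) {
  stimulus_config(trial_type_probabilities = c(0, 0, 1, 0, 0), ...)
}

# simulate a cohort of one session viewed by a linear observer
linear_cohort <- function(kernel, n_trials, config = stimulus_config(),
                          stim_seed = 101, obs_seed = 202, lapse = 0) {
  trials <- generate_session(config, n_trials, seed = stim_seed)
  set.seed(obs_seed)
  with_choices(trials, linear_observer(kernel, lapse = lapse))
}

# build a minimal valid trial table directly from a matrix of signed
# element counts (one row per trial), for hand-constructed examples
trial_table_from_counts <- function(counts, n_elements = 19L, choice = NA_integer_) {
  counts <- as.matrix(counts)
  P <- counts / n_elements
  colnames(P) <- paste0("pulse_", seq_len(ncol(P)))
  net <- rowSums(P)
  rewarded <- sign(net)
  rewarded[rewarded == 0] <- 1L
  out <- data.frame(
    session_id = "S1", subject_id = "subj1", condition = "flat",
    trial_index = seq_len(nrow(P)), distribution_mu = 0,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(P))
  out$net_strength <- net
  out$rewarded_direction <- as.integer(rewarded)
  out$frozen_seed <- FALSE
  out$choice <- as.integer(choice)
  out$correct <- ifelse(is.na(out$choice), NA_integer_,
                        as.integer(out$choice == as.integer(out$rewarded_direction > 0)))
  attr(out, "n_pulses") <- ncol(P)
  attr(out, "n_elements") <- as.integer(n_elements)
  out
}

# the constructed 10-session QC fixture: one subject, sessions 1-2 too
# short, session 3 under the strong-trial accuracy floor, session 10 a
# threshold outlier (3 unscaled MADs above the median)
qc_fixture <- function() {
  data.frame(
    session_id = sprintf("S%02d", 1:10),
    subject_id = "A",
    n_trials = c(200L, 200L, rep(600L, 8)),
    strong_accuracy = c(0.95, 0.95, 0.80, rep(0.95, 7)),
    threshold = c(1.0, 1.1, 0.9, 1.05, 0.95, 1.0, 1.1, 0.9, 1.0, 1.225),
    stringsAsFactors = FALSE
  )
}

# expected mean realized pulse strength for a Gaussian draw pushed through
# the round-to-element-count rule with clipping: independent numerical
# oracle via the Gaussian CDF over lattice cells
expected_rounded_strength <- function(mu, sigma, n_elements = 19L) {
  cells <- (-n_elements):n_elements
  p <- numeric(length(cells))
  for (j in seq_along(cells)) {
    c_ <- cells[j]
    lo <- if (c_ == -n_elements) -Inf else (c_ - 0.5) / n_elements
    hi <- if (c_ == n_elements) Inf else (c_ + 0.5) / n_elements
    p[j] <- pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma)
  }
  sum(cells / n_elements * p)
}
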
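#' Simulated observers with known ground truth
#'
#' Observer objects generate binary choices from trial tables so that every
#' estimation stage (psychometric fit, kernel estimation, summaries) can be
#' validated by parameter recovery. Three decision rules are provided:
#'
#' * `linear_observer()`: the generative inverse of the reverse-correlation
#'   model. P(rightward) = lapse + (1 - 2 lapse) * logistic(kernel . pulses + bias).
#' * `accumulator_observer()`: a discrete-pulse evidence accumulator with
#'   optional leak, absorbing bound, and per-pulse Gaussian noise. A tight
#'   bound yields early weighting (later pulses ignored after absorption); a
#'   leak yields late weighting (early evidence decays).
#' * `extrema_observer()`: ignores integration entirely and reports the sign
#'   of the single strongest pulse (largest absolute element count, earliest
#'   pulse on ties).
#'
#' @param kernel Numeric vector of per-pulse weights (length `n_pulses`).
#' @param bias Additive bias on the log-odds scale.
#' @param lapse Stimulus-independent error probability, in \[0, 0.5).
#' @return An observer object (classes `linear_observer`,
#'   `accumulator_observer` or `extrema_observer`, all inheriting
#'   `observer`).
#' @name observers
#' @examples
#' obs <- linear_observer(kernel = rep(2, 7))
#' trials <- generate_session(stimulus_config(), 50, seed = 1)
#' choices <- simulate_choices(trials, obs)
NULL

#' @rdname observers
#' @export
linear_observer <- function(kernel, bias = 0, lapse = 0) {
  stopifnot(is.numeric(kernel), length(kernel) >= 1, lapse >= 0, lapse < 0.5)
  structure(list(kernel = kernel, bias = bias, lapse = lapse),
            class = c("linear_observer", "observer"))
}

#' @rdname observers
#' @param gain Multiplier applied to each pulse strength before accumulation.
#' @param bound Absorbing bound on |state|; `Inf` for a perfect integrator.
#' @param leak Per-pulse leak rate in \[0, 1\]: state decays by
#'   `state * (1 - leak)` before each update.
#' @param noise_sd SD of Gaussian noise added at each pulse update.
#' @export
accumulator_observer <- function(gain = 1, bound = Inf, leak = 0, noise_sd = 0) {
  stopifnot(bound > 0, leak >= 0, leak <= 1, noise_sd >= 0)
  structure(list(gain = gain, bound = bound, leak = leak, noise_sd = noise_sd),
            class = c("accumulator_observer", "observer"))
}

#' @rdname observers
#' @export
extrema_observer <- function() {
  structure(list(), class = c("extrema_observer", "observer"))
}

#' @export
print.observer <- function(x, ...) {
  cat(class(x)[1L], "\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(signif(x[[nm]], 4), collapse = ", ")))
  }
  invisible(x)
}

#' Simulate choices for a trial table
#'
#' Applies an observer's decision rule to every trial and returns the binary
#' choice vector (1 = rightward, the positive-strength direction). Consumes
#' the current RNG state; set a seed beforehand for reproducibility.
#'
#' @param trials A trial table (see [generate_session()]).
#' @param observer An observer object (see [linear_observer()]).
#' @param ... Passed to methods.
#' @return Integer vector of choices in `{0, 1}`, one per trial.
#' @export
simulate_choices <- function(trials, observer, ...) UseMethod("simulate_choices", observer)

#' @export
simulate_choices.linear_observer <- function(trials, observer, ...) {
  X <- pulse_matrix(trials)
  if (ncol(X) != length(observer$kernel)) {
    stop("kernel length (", length(observer$kernel),
         ") does not match pulse count (", ncol(X), ")")
  }
  eta <- drop(X %*% observer$kernel) + observer$bias
  p <- observer$lapse + (1 - 2 * observer$lapse) * stats::plogis(eta)
  as.integer(stats::runif(nrow(X)) < p)
}

#' @export
simulate_choices.accumulator_observer <- function(trials, observer, ...) {
  X <- pulse_matrix(trials)
  n <- nrow(X)
  state <- numeric(n)
  absorbed <- logical(n)
  for (i in seq_len(ncol(X))) {
    upd <- state * (1 - observer$leak) + observer$gain * X[, i]
    if (observer$noise_sd > 0) upd <- upd + stats::rnorm(n, sd = observer$noise_sd)
    state <- ifelse(absorbed, state, upd)
    absorbed <- absorbed | abs(state) >= observer$bound
  }
  sign_to_choice(sign(state))
}

#' @export
simulate_choices.extrema_observer <- function(trials, observer, ...) {
  C <- pulse_counts(trials)
  # which.max returns the earliest index on ties
  idx <- apply(abs(C), 1L, which.max)
  strongest <- C[cbind(seq_len(nrow(C)), idx)]
  sign_to_choice(sign(strongest))
}

# map -1/0/+1 state signs to 0/1 choices, breaking exact ties at random
sign_to_choice <- function(s) {
  ch <- as.integer(s > 0)
  zero <- s == 0
  if (any(zero)) ch[zero] <- as.integer(stats::runif(sum(zero)) < 0.5)
  ch
}

#' Attach simulated choices to a trial table
#'
#' Fills the `choice` column and scores `correct` against the rewarded
#' direction.
#'
#' @param trials A trial table.
#' @param choices Binary choice vector, or an observer object (in which case
#'   [simulate_choices()] is called).
#' @return The trial table with `choice` and `correct` populated.
#' @export
with_choices <- function(trials, choices) {
  if (inherits(choices, "observer")) choices <- simulate_choices(trials, choices)
  stopifnot(length(choices) == nrow(trials), all(choices %in% c(0L, 1L)))
  trials$choice <- as.integer(choices)
  trials$correct <- as.integer(trials$choice == as.integer(trials$rewarded_direction > 0))
  trials
}
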
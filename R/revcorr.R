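#' Design matrix for reverse correlation
#'
#' Builds the logistic-regression design from a trial table: one column per
#' pulse strength plus a trailing intercept column of ones (capturing choice
#' bias), the binary choice vector, and a mask marking zero-mean trials
#' (generating mean 0), on which classical reverse correlation would be run.
#'
#' @param trials Trial table with a populated `choice` column.
#' @return List of class `trial_matrix`: `X` (n x (n_pulses + 1)), `Y`
#'   (0/1), `zero_mean_mask`, `n_pulses`.
#' @export
trial_matrix <- function(trials) {
  if (anyNA(trials$choice)) stop("trial table has missing choices")
  P <- pulse_matrix(trials)
  Y <- as.integer(trials$choice)
  if (!all(Y %in% c(0L, 1L))) stop("choices must be binary 0/1")
  structure(
    list(
      X = cbind(P, intercept = 1),
      Y = Y,
      zero_mean_mask = trials$distribution_mu == 0,
      n_pulses = ncol(P)
    ),
    class = "trial_matrix"
  )
}

# numerically safe log(1 + exp(eta))
log1pexp <- function(eta) ifelse(eta > 35, eta, log1p(exp(eta)))

kernel_logpost <- function(w, X, Y, lambda, pen_idx) {
  eta <- drop(X %*% w)
  sum(Y * eta - log1pexp(eta)) - lambda * sum(w[pen_idx]^2)
}

#' MAP temporal weighting kernel at fixed ridge penalty
#'
#' Maximizes the penalized Bernoulli log posterior
#' \deqn{L(w) = \sum_i [Y_i w^T X_i - \log(1 + e^{w^T X_i})] - \lambda \|w_{pulse}\|^2}
#' by Newton's method with step halving. The ridge penalty applies to the
#' pulse weights only; the bias (intercept) is unpenalized. The objective is
#' strictly concave for `lambda > 0`, so the optimum is unique.
#'
#' @param tm A [trial_matrix()], or a trial table (converted automatically).
#' @param lambda Ridge hyperparameter, >= 0. See
#'   [estimate_lambda_evidence()] for data-driven selection.
#' @param zero_mean_only Fit on zero-mean trials only (classical reverse
#'   correlation) instead of all trials.
#' @return An object of class `kernel_fit`: `weights` (pulse weights),
#'   `bias`, `lambda`, `weights_normalized` (unit Euclidean norm),
#'   `log_posterior`, `loglik`, `n`.
#' @examples
#' trials <- generate_session(stimulus_config(), 500, seed = 2)
#' trials <- with_choices(trials, linear_observer(rep(3, 7)))
#' fit_kernel_map(trials, lambda = 1)
#' @export
fit_kernel_map <- function(tm, lambda, zero_mean_only = FALSE) {
  if (!inherits(tm, "trial_matrix")) tm <- trial_matrix(tm)
  stopifnot(lambda >= 0)
  X <- tm$X
  Y <- tm$Y
  if (zero_mean_only) {
    if (sum(tm$zero_mean_mask) < 1L) stop("no zero-mean trials available")
    X <- X[tm$zero_mean_mask, , drop = FALSE]
    Y <- Y[tm$zero_mean_mask]
  }
  if (length(unique(Y)) < 2L) stop("both choice classes must be present")

  d <- ncol(X)
  pen_idx <- seq_len(d - 1L)          # all but the intercept
  pen_diag <- c(rep(1, d - 1L), 0)

  w <- numeric(d)
  obj <- kernel_logpost(w, X, Y, lambda, pen_idx)
  for (iter in seq_len(100L)) {
    eta <- drop(X %*% w)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, Y - p)) - 2 * lambda * pen_diag * w
    if (max(abs(g)) < 1e-9) break
    wts <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * wts) + diag(2 * lambda * pen_diag, d)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    # step halving keeps the concave objective increasing
    s <- 1
    repeat {
      w_new <- w + s * step
      obj_new <- kernel_logpost(w_new, X, Y, lambda, pen_idx)
      if (obj_new >= obj - 1e-12 || s < 1e-6) break
      s <- s / 2
    }
    if (abs(obj_new - obj) < 1e-12 && max(abs(g)) < 1e-6) {
      w <- w_new
      break
    }
    w <- w_new
    obj <- obj_new
  }

  weights <- unname(w[pen_idx])
  structure(
    list(
      weights = weights,
      bias = unname(w[d]),
      lambda = lambda,
      weights_normalized = normalize_kernel(weights),
      log_posterior = kernel_logpost(w, X, Y, lambda, pen_idx),
      loglik = sum(Y * drop(X %*% w) - log1pexp(drop(X %*% w))),
      n = nrow(X)
    ),
    class = "kernel_fit"
  )
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("Temporal weighting kernel (ridge-penalized logistic MAP)\n")
  cat("  normalized weights:", paste(sprintf("%.3f", x$weights_normalized), collapse = " "), "\n")
  cat(sprintf("  bias %.4f;  lambda %.4g;  n = %d trials\n", x$bias, x$lambda, x$n))
  invisible(x)
}

#' Unit-norm kernel
#'
#' Divides the pulse weights by their Euclidean norm (bias excluded), the
#' scale on which kernels are compared and summarized.
#'
#' @param w A numeric weight vector or a `kernel_fit`.
#' @return Unit-Euclidean-norm weight vector.
#' @export
normalize_kernel <- function(w) {
  if (inherits(w, "kernel_fit")) w <- w$weights
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("cannot normalize an all-zero kernel")
  w / nrm
}

# Laplace-approximated log marginal likelihood at one lambda.
# Prior: pulse weights ~ N(0, 1/(2*lambda)) iid, improper flat prior on bias.
laplace_evidence <- function(fit, X, Y, lambda) {
  d <- ncol(X)
  w <- c(fit$weights, fit$bias)
  eta <- drop(X %*% w)
  p <- stats::plogis(eta)
  wts <- pmax(p * (1 - p), 1e-12)
  pen_diag <- c(rep(1, d - 1L), 0)
  A <- crossprod(X, X * wts) + diag(2 * lambda * pen_diag, d)
  ld <- determinant(A, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  log_prior <- ((d - 1L) / 2) * log(lambda / pi) - lambda * sum(fit$weights^2)
  fit$loglik + log_prior + (d / 2) * log(2 * pi) - 0.5 * as.numeric(ld$modulus)
}

#' Evidence optimization of the ridge hyperparameter
#'
#' Selects `lambda` by maximizing the Laplace-approximated log marginal
#' likelihood (model evidence) over a log-spaced grid: Bernoulli
#' log-likelihood at the MAP, plus the Gaussian log prior, minus half the
#' log determinant of the Hessian of the negative log posterior.
#' Deterministic given the data.
#'
#' @param tm A [trial_matrix()] or trial table.
#' @param grid Candidate `lambda` values (default: 25 points log-spaced over
#'   `[1e-4, 1e4]`).
#' @param zero_mean_only Restrict to zero-mean trials.
#' @return List: `lambda` (the maximizer), `grid`, `evidence` (the curve).
#' @export
estimate_lambda_evidence <- function(tm,
                                     grid = 10^seq(-4, 4, length.out = 25),
                                     zero_mean_only = FALSE) {
  if (!inherits(tm, "trial_matrix")) tm <- trial_matrix(tm)
  X <- tm$X; Y <- tm$Y
  if (zero_mean_only) {
    X <- X[tm$zero_mean_mask, , drop = FALSE]
    Y <- Y[tm$zero_mean_mask]
  }
  ev <- vapply(grid, function(l) {
    fit <- fit_kernel_map(tm, lambda = l, zero_mean_only = zero_mean_only)
    laplace_evidence(fit, X, Y, l)
  }, numeric(1))
  if (all(!is.finite(ev))) stop("evidence is non-finite across the whole lambda grid")
  list(lambda = grid[which.max(ev)], grid = grid, evidence = ev)
}

#' Fit the temporal weighting kernel with evidence-chosen penalty
#'
#' Convenience wrapper: selects `lambda` by [estimate_lambda_evidence()] and
#' returns the MAP kernel at that `lambda`.
#'
#' @inheritParams estimate_lambda_evidence
#' @param lambda Either `"evidence"` (default) or a fixed numeric value.
#' @return A `kernel_fit` (see [fit_kernel_map()]).
#' @export
fit_kernel <- function(tm, lambda = "evidence", zero_mean_only = FALSE,
                       grid = 10^seq(-4, 4, length.out = 25)) {
  if (!inherits(tm, "trial_matrix")) tm <- trial_matrix(tm)
  if (identical(lambda, "evidence")) {
    lambda <- estimate_lambda_evidence(tm, grid = grid,
                                       zero_mean_only = zero_mean_only)$lambda
  }
  fit_kernel_map(tm, lambda = lambda, zero_mean_only = zero_mean_only)
}

#' Whitening check: all trials vs. zero-mean trials
#'
#' Logistic regression whitens the stimulus covariance, so the kernel
#' estimated on all trials (signal trials included, where pulses are
#' correlated through the shared generating mean) should agree with the
#' kernel estimated on zero-mean trials only, the classical
#' reverse-correlation subset. Returns the Pearson correlation between the
#' two normalized weight vectors.
#'
#' @param trials Trial table with choices.
#' @param min_zero_mean Minimum number of zero-mean trials required (100).
#' @return List: `r` (Pearson correlation of the two normalized kernels),
#'   `fit_all`, `fit_zero_mean`.
#' @export
whitening_check <- function(trials, min_zero_mean = 100L) {
  tm <- trial_matrix(trials)
  if (sum(tm$zero_mean_mask) < min_zero_mean) {
    stop("need at least ", min_zero_mean, " zero-mean trials, have ",
         sum(tm$zero_mean_mask))
  }
  fit_all <- fit_kernel(tm)
  fit_zm <- fit_kernel(tm, zero_mean_only = TRUE)
  list(
    r = stats::cor(fit_all$weights_normalized, fit_zm$weights_normalized),
    fit_all = fit_all,
    fit_zero_mean = fit_zm
  )
}
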
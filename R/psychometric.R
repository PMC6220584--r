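#' Three-parameter logistic psychometric function
#'
#' Probability of a rightward choice as a function of signed net motion
#' strength `x`:
#' \deqn{p(x) = \gamma + (1 - 2\gamma) \frac{1}{1 + e^{-\beta (x - \alpha)}}}
#' where `alpha` is the bias (midpoint), `beta` the slope (sensitivity, in
#' log-odds per unit strength) and `gamma` the lapse rate compressing the
#' function symmetrically away from 0 and 1.
#'
#' @param x Net motion strength (typically z-scored per subject).
#' @param alpha,beta,gamma Parameters as above; `gamma` in \[0, 0.5).
#' @return Choice probabilities in \[gamma, 1 - gamma\].
#' @export
psychometric_prob <- function(x, alpha, beta, gamma) {
  gamma + (1 - 2 * gamma) * stats::plogis(beta * (x - alpha))
}

#' Z-score net motion strengths per subject
#'
#' Standardizes net strengths to mean 0, SD 1 within each subject, pooling
#' all of that subject's sessions (population-SD convention, denominator n).
#'
#' @param x Numeric vector of net strengths.
#' @param subject Optional vector of subject identifiers, recycled against
#'   `x`; when `NULL` all values are standardized together.
#' @return Numeric vector of standardized strengths.
#' @examples
#' zscore_strengths(c(-1, 0, 1))
#' @export
zscore_strengths <- function(x, subject = NULL) {
  if (is.null(subject)) subject <- rep(1L, length(x))
  stopifnot(length(subject) == length(x))
  out <- numeric(length(x))
  for (s in unique(subject)) {
    sel <- subject == s
    xs <- x[sel]
    if (length(unique(xs)) < 2L) {
      stop("cannot z-score: constant net strengths for subject ", s)
    }
    sd_pop <- sqrt(mean((xs - mean(xs))^2))
    out[sel] <- (xs - mean(xs)) / sd_pop
  }
  out
}

#' Maximum-likelihood psychometric fit
#'
#' Fits the three-parameter logistic function by maximizing the Bernoulli
#' log-likelihood of the binary choices. The lapse rate is optimized on an
#' unconstrained scale (logit of `2 * gamma`) so that `gamma` stays in
#' \[0, 0.5); three deterministic starting points guard against local
#' optima. Standard errors are the square roots of the diagonal of the
#' inverse Hessian of the negative log-likelihood at the optimum, computed
#' in the natural (alpha, beta, gamma) parameterization.
#'
#' @param x Standardized net motion strengths.
#' @param choices Binary choices (1 = rightward).
#' @param min_n Minimum number of trials required (20).
#' @return An object of class `psychometric_fit`: `alpha`, `beta`, `gamma`,
#'   `se_alpha`, `se_beta`, `se_gamma`, `loglik`, `threshold75`, `n`,
#'   `converged`, and `separation` (`TRUE` when the slope ran away,
#'   indicating separable data).
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' y <- as.integer(runif(500) < psychometric_prob(x, 0, 2, 0.02))
#' fit_psychometric(x, y)
#' @export
fit_psychometric <- function(x, choices, min_n = 20L) {
  stopifnot(length(x) == length(choices))
  choices <- as.integer(choices)
  if (!all(choices %in% c(0L, 1L))) stop("choices must be binary 0/1")
  if (length(x) < min_n) stop("need at least ", min_n, " trials")
  if (length(unique(choices)) < 2L) stop("both choice classes must be present")

  nll <- function(par) {
    alpha <- par[1L]; beta <- par[2L]
    gamma <- 0.5 * stats::plogis(par[3L])
    p <- psychometric_prob(x, alpha, beta, gamma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(choices == 1L, log(p), log1p(-p)))
  }

  starts <- list(c(0, 1, -4), c(stats::median(x), 2, -2), c(0, 0.5, -6))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("psychometric fit failed to converge from all starts")

  alpha <- best$par[1L]
  beta <- best$par[2L]
  gamma <- 0.5 * stats::plogis(best$par[3L])
  separation <- abs(beta) > 50

  # SEs in the natural parameterization; may be unavailable at the gamma
  # boundary or under separation
  ses <- rep(NA_real_, 3L)
  nll_nat <- function(par) {
    p <- psychometric_prob(x, par[1L], par[2L], par[3L])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(choices == 1L, log(p), log1p(-p)))
  }
  H <- tryCatch(pracma::hessian(nll_nat, c(alpha, beta, gamma)),
                error = function(e) NULL)
  if (!is.null(H)) {
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Hi)) {
      d <- diag(Hi)
      ses <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }

  fit <- structure(
    list(
      alpha = alpha, beta = beta, gamma = gamma,
      se_alpha = ses[1L], se_beta = ses[2L], se_gamma = ses[3L],
      loglik = -best$value, n = length(x),
      converged = best$convergence == 0L,
      separation = separation,
      threshold75 = NA_real_
    ),
    class = "psychometric_fit"
  )
  fit$threshold75 <- tryCatch(threshold75(fit), error = function(e) NA_real_)
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit (3-parameter logistic, ML)\n")
  cat(sprintf("  alpha (bias)  %8.4f  (SE %s)\n", x$alpha, format(signif(x$se_alpha, 3))))
  cat(sprintf("  beta  (slope) %8.4f  (SE %s)\n", x$beta, format(signif(x$se_beta, 3))))
  cat(sprintf("  gamma (lapse) %8.4f  (SE %s)\n", x$gamma, format(signif(x$se_gamma, 3))))
  cat(sprintf("  loglik %.3f on %d trials;  75%% threshold %.4f\n",
              x$loglik, x$n, x$threshold75))
  if (x$separation) cat("  warning: slope ran away (separable data)\n")
  invisible(x)
}

#' 75%-correct psychophysical threshold
#'
#' Inverts the fitted psychometric function at p = 0.75:
#' `x = alpha - (1/beta) * log((0.25 - gamma) / (0.75 - gamma))`. The
#' threshold is reported in the units of the fitted `x` (z-scored strength
#' when the fit used z-scored strengths).
#'
#' @param fit A `psychometric_fit`, or the `alpha` value when `beta` and
#'   `gamma` are given explicitly.
#' @param beta,gamma Used when `fit` is a bare `alpha` scalar.
#' @return The motion strength at which the function crosses 0.75.
#' @examples
#' threshold75(0, beta = 1, gamma = 0)  # log(3)
#' @export
threshold75 <- function(fit, beta = NULL, gamma = NULL) {
  if (inherits(fit, "psychometric_fit")) {
    alpha <- fit$alpha; beta <- fit$beta; gamma <- fit$gamma
  } else {
    alpha <- fit
    stopifnot(!is.null(beta), !is.null(gamma))
  }
  if (gamma >= 0.25) stop("threshold undefined: lapse rate >= 0.25 makes 75% unreachable")
  alpha - (1 / beta) * log((0.25 - gamma) / (0.75 - gamma))
}
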
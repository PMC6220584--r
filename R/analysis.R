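#' Slope and intercept of the temporal weighting profile
#'
#' Ordinary least-squares fit of weight against pulse index 1..n. A negative
#' slope indicates early weighting (early pulses weighted more), a positive
#' slope late weighting, and a slope near zero uniform weighting. Computed
#' on normalized weights by convention.
#'
#' @param weights Numeric weight vector (normalized kernel) or a
#'   `kernel_fit` (its normalized weights are used).
#' @return Named vector `c(slope, intercept)`.
#' @examples
#' kernel_slope(c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05))
#' @export
kernel_slope <- function(weights) {
  if (inherits(weights, "kernel_fit")) weights <- weights$weights_normalized
  n <- length(weights)
  stopifnot(n >= 2)
  i <- seq_len(n)
  co <- stats::coef(stats::lm(weights ~ i))
  c(slope = unname(co[2L]), intercept = unname(co[1L]))
}

#' Energy of the temporal weighting profile
#'
#' Sum of squared deviations of the weights from their mean: zero for
#' perfectly uniform weighting, large when weight is concentrated on a few
#' pulses. Computed on normalized weights by convention.
#'
#' @inheritParams kernel_slope
#' @return Non-negative scalar.
#' @examples
#' kernel_energy(c(1, 0, 0, 0, 0, 0, 0))  # 6/7
#' @export
kernel_energy <- function(weights) {
  if (inherits(weights, "kernel_fit")) weights <- weights$weights_normalized
  sum((weights - mean(weights))^2)
}

#' Group statistics on per-session weighting slopes
#'
#' Per condition: an exact two-sided sign test of the slopes against zero
#' (optionally the Wilcoxon signed-rank test), plus mean, median and SD.
#' Across conditions: one-way ANOVA on mean slopes and pairwise Bartlett
#' tests for differences in variance.
#'
#' @param slopes Numeric vector of per-session kernel slopes.
#' @param condition Factor/character of the stimulus condition per session.
#' @param test `"sign"` (exact sign test, default) or `"signed_rank"`.
#' @return List: `per_condition` (data.frame with n, mean, median, sd and
#'   the sign-test p-value vs 0), `anova_p`, `bartlett` (data.frame of
#'   pairwise condition comparisons and p-values).
#' @export
group_statistics <- function(slopes, condition, test = c("sign", "signed_rank")) {
  test <- match.arg(test)
  stopifnot(length(slopes) == length(condition))
  condition <- as.character(condition)
  if (any(!stats::complete.cases(slopes, condition))) stop("missing values in input")
  conds <- unique(condition)
  if (any(table(condition) == 0L)) stop("empty condition group")

  per <- do.call(rbind, lapply(conds, function(cc) {
    s <- slopes[condition == cc]
    p <- if (test == "sign") {
      nz <- s[s != 0]
      if (length(nz) < 6L) NA_real_
      else stats::binom.test(sum(nz > 0), length(nz), p = 0.5)$p.value
    } else {
      if (length(s) < 6L) NA_real_ else stats::wilcox.test(s, mu = 0)$p.value
    }
    data.frame(condition = cc, n = length(s), mean = mean(s),
               median = stats::median(s), sd = stats::sd(s),
               p_vs_zero = p, stringsAsFactors = FALSE)
  }))

  anova_p <- NA_real_
  if (length(conds) >= 2L) {
    fit <- stats::aov(slopes ~ factor(condition))
    anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    if (is.null(anova_p)) anova_p <- NA_real_
  }

  bart <- NULL
  if (length(conds) >= 2L) {
    pairs <- utils::combn(conds, 2L)
    bart <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      sel <- condition %in% c(a, b)
      p <- stats::bartlett.test(slopes[sel], factor(condition[sel]))$p.value
      data.frame(condition_a = a, condition_b = b, p = p,
                 stringsAsFactors = FALSE)
    }))
  }

  list(per_condition = per, anova_p = anova_p, bartlett = bart)
}

#' Correlation between psychometric threshold and weighting summaries
#'
#' Within each condition, Pearson correlations (with two-sided p-values)
#' between the 75% psychophysical threshold and (a) the kernel slope and
#' (b) the kernel energy, across sessions.
#'
#' @param sessions Data frame with columns `condition`, `threshold`,
#'   `slope`, `energy` (one row per session).
#' @param min_sessions Minimum sessions per condition (4).
#' @return Data frame with one row per (condition, summary) pair: `r`, `p`,
#'   `n`.
#' @export
threshold_weighting_correlation <- function(sessions, min_sessions = 4L) {
  need <- c("condition", "threshold", "slope", "energy")
  if (!all(need %in% colnames(sessions))) {
    stop("sessions must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (cc in unique(sessions$condition)) {
    s <- sessions[sessions$condition == cc, ]
    if (nrow(s) < min_sessions) {
      stop("need at least ", min_sessions, " sessions per condition; '",
           cc, "' has ", nrow(s))
    }
    for (v in c("slope", "energy")) {
      if (stats::sd(s$threshold) == 0 || stats::sd(s[[v]]) == 0) {
        stop("correlation undefined: constant ", v, " or threshold in '", cc, "'")
      }
      ct <- stats::cor.test(s$threshold, s[[v]])
      out[[length(out) + 1L]] <- data.frame(
        condition = cc, summary = v, r = unname(ct$estimate),
        p = ct$p.value, n = nrow(s), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# index of the strongest pulse (largest |element count|), earliest on ties
strongest_pulse_index <- function(counts) apply(abs(counts), 1L, which.max)

#' Extrema-detection control analysis
#'
#' Tests whether choices track the single strongest pulse rather than the
#' integrated net motion. Inconsistent trials are those where the sign of
#' the strongest pulse (largest absolute element count; earliest pulse on
#' ties) opposes the sign of the net strength. Each inconsistent trial is
#' matched for difficulty (|net strength|) to an unused consistent trial by
#' greedy nearest-neighbour matching without replacement, with a maximum
#' match distance of half a lattice step; unmatched inconsistent trials are
#' dropped and counted. Accuracy (proportion of choices matching the net
#' direction) and exact Clopper-Pearson 95% binomial CIs are returned for
#' both groups. An integrator passes (equal accuracies); an
#' extrema-detector fails (inconsistent accuracy collapses).
#'
#' @param trials Trial table with choices.
#' @param min_inconsistent Minimum number of inconsistent trials (20).
#' @param max_match_distance Maximum |net strength| difference allowed in a
#'   match, in units of strength; default half a lattice step
#'   (`0.5 / n_elements`).
#' @return List: `inconsistent` and `consistent`, each with `accuracy`,
#'   `ci` (95% Clopper-Pearson), `n`; `matched_pairs` (data.frame of row
#'   indices of each matched inconsistent/consistent pair); `n_unmatched`.
#' @export
consistency_analysis <- function(trials, min_inconsistent = 20L,
                                 max_match_distance = NULL) {
  if (anyNA(trials$choice)) stop("trial table has missing choices")
  n_elements <- attr(trials, "n_elements")
  if (is.null(n_elements)) n_elements <- 19L
  if (is.null(max_match_distance)) max_match_distance <- 0.5 / n_elements

  C <- pulse_counts(trials, n_elements)
  idx <- strongest_pulse_index(C)
  strongest_sign <- sign(C[cbind(seq_len(nrow(C)), idx)])
  net_sign <- sign(trials$net_strength)

  usable <- net_sign != 0 & strongest_sign != 0
  inconsistent <- usable & strongest_sign != net_sign
  consistent_pool <- usable & strongest_sign == net_sign
  if (sum(inconsistent) < min_inconsistent) {
    stop("need at least ", min_inconsistent, " inconsistent trials, have ",
         sum(inconsistent))
  }

  # greedy nearest-neighbour difficulty matching, without replacement
  inc_idx <- which(inconsistent)
  pool_idx <- which(consistent_pool)
  pool_diff <- abs(trials$net_strength[pool_idx])
  used <- logical(length(pool_idx))
  matched_inc <- integer(0)
  matched_con <- integer(0)
  for (i in inc_idx) {
    d <- abs(pool_diff - abs(trials$net_strength[i]))
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1L && is.finite(d[j]) && d[j] <= max_match_distance) {
      used[j] <- TRUE
      matched_inc <- c(matched_inc, i)
      matched_con <- c(matched_con, pool_idx[j])
    }
  }
  n_unmatched <- length(inc_idx) - length(matched_inc)

  acc_ci <- function(rows) {
    correct <- trials$choice[rows] == as.integer(net_sign[rows] > 0)
    k <- sum(correct); n <- length(rows)
    bt <- stats::binom.test(k, n)
    list(accuracy = k / n, ci = unname(bt$conf.int), n = n)
  }
  list(
    inconsistent = acc_ci(matched_inc),
    consistent = acc_ci(matched_con),
    matched_pairs = data.frame(inconsistent = matched_inc,
                               consistent = matched_con),
    n_unmatched = n_unmatched
  )
}

#' Session-level quality control
#'
#' Applies the three inclusion rules: (1) a minimum number of successfully
#' completed trials; (2) minimum accuracy on trials drawn from the
#' strongest-|mean| generating distributions; (3) the psychophysical
#' threshold must lie within `mad_criterion` (unscaled) median absolute
#' deviations of the median threshold, computed per subject across that
#' subject's sessions. Thresholds of all candidate sessions enter the MAD
#' statistics (rule 3 is computed before any exclusion). Subjects with
#' fewer than 3 sessions skip the MAD rule with a warning.
#'
#' @param sessions Data frame with one row per session and columns
#'   `session_id`, `subject_id`, `n_trials`, `strong_accuracy`,
#'   `threshold`.
#' @param min_trials Minimum successfully completed trials (250).
#' @param min_strong_accuracy Minimum accuracy on the strongest motion
#'   values (0.85).
#' @param mad_criterion Allowed deviation in MADs (2).
#' @return The input data frame with added columns `included` (logical) and
#'   `reasons` (comma-separated failure reasons from `too_few_trials`,
#'   `low_strong_accuracy`, `threshold_outlier`; empty when included).
#' @export
session_qc <- function(sessions, min_trials = 250L, min_strong_accuracy = 0.85,
                       mad_criterion = 2) {
  need <- c("session_id", "subject_id", "n_trials", "strong_accuracy", "threshold")
  if (!all(need %in% colnames(sessions))) {
    stop("sessions must have columns: ", paste(need, collapse = ", "))
  }
  reasons <- vector("list", nrow(sessions))
  for (i in seq_len(nrow(sessions))) reasons[[i]] <- character(0)

  few <- sessions$n_trials < min_trials
  weak <- sessions$strong_accuracy < min_strong_accuracy
  for (i in which(few)) reasons[[i]] <- c(reasons[[i]], "too_few_trials")
  for (i in which(weak)) reasons[[i]] <- c(reasons[[i]], "low_strong_accuracy")

  for (s in unique(sessions$subject_id)) {
    sel <- which(sessions$subject_id == s)
    if (length(sel) < 3L) {
      warning("subject ", s, " has fewer than 3 sessions; MAD rule skipped")
      next
    }
    th <- sessions$threshold[sel]
    med <- stats::median(th)
    mad_un <- stats::median(abs(th - med))  # unscaled MAD
    out <- abs(th - med) > mad_criterion * mad_un
    for (i in sel[out]) reasons[[i]] <- c(reasons[[i]], "threshold_outlier")
  }

  sessions$included <- lengths(reasons) == 0L
  sessions$reasons <- vapply(reasons, paste, character(1), collapse = ",")
  sessions
}
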
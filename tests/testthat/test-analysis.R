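test_that("kernel slope is the OLS fit against pulse index", {
  sl <- kernel_slope(rep(0.378, 7))
  expect_equal(sl[["slope"]], 0)

  # exact linear profiles recover their construction slope
  w <- 0.5 - 0.03 * (1:7)
  expect_equal(kernel_slope(w)[["slope"]], -0.03)
  expect_equal(kernel_slope(w)[["intercept"]], 0.5)

  # late-humped profile slopes upward after unit normalization
  w_late <- unit_norm(c(0.1, 0.2, 0.3, 0.45, 0.55, 0.5, 0.35))
  expect_gt(kernel_slope(w_late)[["slope"]], 0)
})

test_that("kernel energy measures squared deviation from uniform weighting", {
  expect_equal(kernel_energy(rep(1 / sqrt(7), 7)), 0)
  expect_equal(kernel_energy(c(1, 0, 0, 0, 0, 0, 0)), 6 / 7)
  # centering invariance
  set.seed(261)
  w <- rnorm(7)
  expect_equal(kernel_energy(w + 5), kernel_energy(w))
  # slope and energy are invariant to positive rescaling once normalized
  expect_equal(kernel_slope(normalize_kernel(w * 13)), kernel_slope(normalize_kernel(w)))
  expect_equal(kernel_energy(normalize_kernel(w * 13)), kernel_energy(normalize_kernel(w)))
})

test_that("group statistics reproduce exact small-sample answers", {
  # all-positive slopes, n = 20: exact two-sided sign test p = 2 * 0.5^20
  set.seed(271)
  slopes <- abs(rnorm(20)) + 0.01
  gs <- group_statistics(slopes, rep("flat", 20))
  expect_equal(gs$per_condition$p_vs_zero, 2 * 0.5^20)

  # three identical groups: ANOVA F = 0, p = 1
  s3 <- rep(c(-1, 0, 1, 2), 3)
  cond <- rep(c("flat", "early", "late"), each = 4)
  gs3 <- group_statistics(s3, cond)
  expect_equal(gs3$anova_p, 1)
  expect_equal(nrow(gs3$bartlett), 3)

  # signed-rank option runs and agrees in direction
  gsw <- group_statistics(slopes, rep("flat", 20), test = "signed_rank")
  expect_lt(gsw$per_condition$p_vs_zero, 0.001)
})

test_that("Bartlett's test detects a doubled SD at n = 80 per group", {
  reject <- vapply(1:20, function(r) {
    set.seed(280 + r)
    s <- c(rnorm(80, 0, 1), rnorm(80, 0, 2))
    cond <- rep(c("flat", "early"), each = 80)
    group_statistics(s, cond)$bartlett$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("threshold correlates with weighting summaries in the built-in directions", {
  # perfectly linear association
  df <- data.frame(condition = "flat", threshold = 1:10,
                   slope = (1:10) / 10, energy = seq(0.2, 2, 0.2))
  res <- threshold_weighting_correlation(df)
  expect_equal(res$r, c(1, 1))

  # permutation null: shuffled pairings center r at zero
  set.seed(291)
  th <- rnorm(40)
  en <- rnorm(40)
  rs <- vapply(1:1000, function(i) cor(th, sample(en)), numeric(1))
  expect_lt(abs(mean(rs)), 0.02)

  expect_error(
    threshold_weighting_correlation(
      data.frame(condition = "flat", threshold = rep(1, 5),
                 slope = rnorm(5), energy = rnorm(5))),
    "constant")
})

test_that("high kernel energy raises thresholds on matched-norm observers", {
  cfg <- stimulus_config()
  run_session <- function(kernel, stim_seed, obs_seed) {
    trials <- linear_cohort(kernel, 800, config = cfg,
                            stim_seed = stim_seed, obs_seed = obs_seed)
    z <- zscore_strengths(trials$net_strength)
    fit <- fit_psychometric(z, trials$choice)
    fit$threshold75
  }
  uniform <- unit_norm(rep(1, 7)) * 8
  spiky <- unit_norm(c(1, 0, 0, 0, 0, 0, 0)) * 8   # same norm, maximal energy
  th_u <- sapply(1:4, function(r) run_session(uniform, 300 + r, 310 + r))
  th_s <- sapply(1:4, function(r) run_session(spiky, 300 + r, 320 + r))
  sessions <- data.frame(
    condition = "flat",
    threshold = c(th_u, th_s),
    slope = seq(-0.01, 0.01, length.out = 8),
    energy = rep(c(kernel_energy(unit_norm(uniform)), kernel_energy(unit_norm(spiky))),
                 each = 4)
  )
  res <- threshold_weighting_correlation(sessions)
  r_energy <- res$r[res$summary == "energy"]
  expect_gt(r_energy, 0)
  expect_gt(mean(th_s), mean(th_u))
})

test_that("consistency analysis separates integrators from extrema detectors", {
  trials <- generate_session(stimulus_config(), 4000, seed = 331)

  # perfect integrator: both accuracies 1 in the noise-free limit
  set.seed(332)
  t_int <- with_choices(trials, accumulator_observer())
  ca_int <- consistency_analysis(t_int)
  expect_equal(ca_int$inconsistent$accuracy, 1)
  expect_equal(ca_int$consistent$accuracy, 1)

  # extrema detector: fails every inconsistent trial, passes every
  # consistent one, by construction of the rule
  set.seed(333)
  t_ext <- with_choices(trials, extrema_observer())
  ca_ext <- consistency_analysis(t_ext)
  expect_equal(ca_ext$inconsistent$accuracy, 0)
  expect_equal(ca_ext$consistent$accuracy, 1)

  # matched sets are disjoint and no consistent trial is reused
  pairs <- ca_int$matched_pairs
  expect_length(intersect(pairs$inconsistent, pairs$consistent), 0)
  expect_false(any(duplicated(pairs$consistent)))

  # a partially integrating observer sits in between, with lower accuracy
  # on inconsistent trials
  set.seed(334)
  t_acc <- with_choices(trials, accumulator_observer(bound = 0.3, noise_sd = 0.1))
  ca_acc <- consistency_analysis(t_acc)
  expect_lt(ca_acc$inconsistent$accuracy, ca_acc$consistent$accuracy)

  expect_error(consistency_analysis(t_int[1:30, ]), "inconsistent trials")
})

test_that("session QC applies the three inclusion rules exactly", {
  qc <- session_qc(qc_fixture())
  expect_equal(sum(qc$included), 6)
  expect_equal(qc$reasons[1], "too_few_trials")
  expect_equal(qc$reasons[2], "too_few_trials")
  expect_equal(qc$reasons[3], "low_strong_accuracy")
  expect_equal(qc$reasons[10], "threshold_outlier")
  expect_true(all(qc$reasons[4:9] == ""))

  # inclusion iff no reasons
  expect_equal(qc$included, qc$reasons == "")

  # a session can fail multiple rules at once
  fx <- qc_fixture()
  fx$strong_accuracy[1] <- 0.5
  qc2 <- session_qc(fx)
  expect_equal(qc2$reasons[1], "too_few_trials,low_strong_accuracy")

  # order independence
  set.seed(341)
  perm <- sample(10)
  qc_perm <- session_qc(qc_fixture()[perm, ])
  expect_equal(qc_perm$included[order(qc_perm$session_id)],
               qc$included[order(qc$session_id)])

  # all-compliant cohort: everything included
  fx_ok <- qc_fixture()
  fx_ok$n_trials <- 600L
  fx_ok$strong_accuracy <- 0.95
  fx_ok$threshold <- fx_ok$threshold[c(1:9, 5)]
  expect_true(all(session_qc(fx_ok)$included))

  # fewer than 3 sessions per subject: MAD rule skipped with a warning
  expect_warning(session_qc(qc_fixture()[1:2, ]), "MAD")
})
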
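test_that("MAP kernel at fixed lambda matches a derivative-free optimizer", {
  trials <- linear_cohort(unit_norm(kernel_shapes()$late_humped) * 8, 200,
                          config = zero_mean_config(),
                          stim_seed = 161, obs_seed = 162)
  tm <- trial_matrix(trials)
  fit <- fit_kernel_map(tm, lambda = 1)

  # independent oracle: Nelder-Mead on the penalized objective
  neg_obj <- function(w) {
    eta <- drop(tm$X %*% w)
    -(sum(tm$Y * eta - log(1 + exp(eta))) - 1 * sum(w[1:7]^2))
  }
  o <- list(par = rep(0, 8))
  for (restart in 1:5) {
    o <- optim(o$par, neg_obj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-15))
  }
  expect_lt(max(abs(c(fit$weights, fit$bias) - o$par)), 1e-4)
})

test_that("a dominant penalty shrinks pulse weights to zero and bias to logit mean choice", {
  trials <- linear_cohort(rep(2, 7), 1000, stim_seed = 171, obs_seed = 172)
  tm <- trial_matrix(trials)
  fit <- fit_kernel_map(tm, lambda = 1e7)
  expect_lt(sqrt(sum(fit$weights^2)), 1e-3)
  expect_equal(fit$bias, qlogis(mean(tm$Y)), tolerance = 1e-3)
})

test_that("weight norm is monotone nonincreasing across the lambda grid", {
  trials <- linear_cohort(unit_norm(kernel_shapes()$flat) * 8, 1500,
                          config = zero_mean_config(),
                          stim_seed = 181, obs_seed = 182)
  tm <- trial_matrix(trials)
  grid <- 10^seq(-4, 4, length.out = 25)
  norms <- vapply(grid, function(l) {
    sqrt(sum(fit_kernel_map(tm, lambda = l)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("kernel normalization is definitional", {
  expect_equal(normalize_kernel(c(2, 0, 0, 0, 0, 0, 0)), c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(normalize_kernel(rep(3, 7)), rep(1 / sqrt(7), 7))
  set.seed(191)
  for (i in 1:10) {
    w <- rnorm(7)
    expect_equal(sum(normalize_kernel(w)^2), 1)
  }
  expect_error(normalize_kernel(rep(0, 7)), "all-zero")
})

test_that("normalized kernels are invariant to positive rescaling of stimulus units", {
  trials <- linear_cohort(unit_norm(kernel_shapes()$linear_up) * 8, 1500,
                          config = zero_mean_config(),
                          stim_seed = 201, obs_seed = 202)
  tm <- trial_matrix(trials)
  tm_scaled <- tm
  tm_scaled$X[, 1:7] <- tm$X[, 1:7] * 10
  # compare at lambda = 0 (maximum likelihood), where invariance is exact
  f1 <- fit_kernel_map(tm, lambda = 0)
  f2 <- fit_kernel_map(tm_scaled, lambda = 0)
  expect_equal(f2$weights_normalized, f1$weights_normalized, tolerance = 1e-5)
})

test_that("evidence optimization selects stronger shrinkage for pure noise", {
  cfg <- zero_mean_config()
  trials <- generate_session(cfg, 2000, seed = 211)
  set.seed(212)
  strong <- with_choices(trials, linear_observer(unit_norm(kernel_shapes()$flat) * 10))
  set.seed(213)
  noise <- trials
  noise$choice <- as.integer(runif(nrow(noise)) < 0.5)
  noise$correct <- as.integer(noise$choice == as.integer(noise$rewarded_direction > 0))

  l_strong <- estimate_lambda_evidence(strong)
  l_noise <- estimate_lambda_evidence(noise)
  expect_gte(l_noise$lambda, l_strong$lambda)

  # evidence curve is unimodal on this well-conditioned fixture
  d <- diff(l_strong$evidence)
  expect_lte(sum(diff(sign(d[d != 0])) != 0), 1)
})

test_that("shrinkage relaxes toward the MLE as the trial count doubles", {
  shrinkage_at <- function(n, seed) {
    trials <- linear_cohort(unit_norm(kernel_shapes()$late_humped) * 8, n,
                            config = zero_mean_config(),
                            stim_seed = seed, obs_seed = seed + 1)
    tm <- trial_matrix(trials)
    lam <- estimate_lambda_evidence(tm)$lambda
    w_map <- fit_kernel_map(tm, lambda = lam)$weights
    w_mle <- fit_kernel_map(tm, lambda = 0)$weights
    sqrt(sum(w_map^2)) / sqrt(sum(w_mle^2))
  }
  s1 <- mean(sapply(1:3, function(r) shrinkage_at(1000, 220 + 2 * r)))
  s2 <- mean(sapply(1:3, function(r) shrinkage_at(4000, 230 + 2 * r)))
  expect_lt(abs(s2 - 1), abs(s1 - 1))
})

test_that("whitening check: identical trial sets and sign flips are exact", {
  trials <- linear_cohort(unit_norm(kernel_shapes()$late_humped) * 8, 1500,
                          config = zero_mean_config(),
                          stim_seed = 241, obs_seed = 242)
  fit <- fit_kernel(trials)
  expect_equal(cor(fit$weights_normalized, fit$weights_normalized), 1)
  expect_equal(cor(fit$weights_normalized, -fit$weights_normalized), -1)

  # every trial zero-mean: the two whitening-check fits see the same data
  wc <- whitening_check(trials)
  expect_equal(wc$r, 1, tolerance = 1e-6)

  few_zm <- linear_cohort(rep(2, 7), 300,
                          config = stimulus_config(
                            trial_type_probabilities = c(0.45, 0.05, 0.0, 0.05, 0.45)),
                          stim_seed = 243, obs_seed = 244)
  expect_error(whitening_check(few_zm), "zero-mean")
})

test_that("estimation requires both choice classes", {
  trials <- generate_session(stimulus_config(), 200, seed = 251)
  trials$choice <- 1L
  trials$correct <- as.integer(trials$rewarded_direction > 0)
  expect_error(fit_kernel_map(trials, lambda = 1), "both choice classes")
})
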
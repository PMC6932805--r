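test_that("the least-squares engine matches closed forms and a pseudoinverse oracle", {
  # intercept-only: mean 2, residual SS 2
  f <- fit_linear_model(y ~ 1, data.frame(y = c(1, 2, 3)))
  expect_equal(unname(f$coefficients), 2)
  expect_equal(f$rss, 2)
  expect_equal(f$aic, -2 * f$loglik + 2 * (f$rank + 1))
  expect_equal(f$bic, -2 * f$loglik + (f$rank + 1) * log(f$n))

  # balanced noise-free two-level factor: exact group means
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(5, 9), each = 3))
  f <- fit_linear_model(y ~ g, d)
  expect_equal(unname(f$coefficients), c(5, 4))
  expect_lt(f$rss, 1e-20)

  # random two-factor designs against the SVD pseudoinverse, incl. rank-deficient
  set.seed(301)
  for (rep in 1:6) {
    n <- 40
    d <- data.frame(a = sample(letters[1:4], n, TRUE),
                    b = sample(LETTERS[1:3], n, TRUE),
                    y = rnorm(n))
    if (rep > 4) d$b[d$a == "a"] <- "A"  # force aliasing
    f <- fit_linear_model(y ~ a + b, d)
    X <- model.matrix(~ a + b, transform(d, a = factor(a), b = factor(b)))
    o <- pinv_lsq_oracle(X, d$y)
    pred <- drop(X[, !is.na(f$coefficients), drop = FALSE] %*%
                   f$coefficients[!is.na(f$coefficients)])
    expect_lt(max(abs(pred - o$fitted)), 1e-8)
    if (!anyNA(f$coefficients)) {
      expect_lt(max(abs(f$coefficients - o$coef)), 1e-8)
    }
  }
})

test_that("the HFA model recovers zero and planted premiums", {
  # noise-free additive data without GxE: home premium exactly zero (the
  # generator's true homes are supplied — without any yield noise the argmax
  # assignment ties everywhere and carries no information)
  sim <- generate_trials(small_params(31, delta = 0, sigma_sy = 0, sigma_e = 0))
  f <- fit_hfa(sim$trials, truth_home_map(sim$truth))
  expect_lt(abs(f$hfa), 1e-8)

  # planted delta = 1.5 with the *true* homes supplied: unbiased recovery
  ests <- vapply(41:52, function(seed) {
    sim <- generate_trials(small_params(seed, delta = 1.5, n_sites = 8L,
                                        n_years = 6L, n_varieties = 40L))
    fit_hfa(sim$trials, truth_home_map(sim$truth))$hfa
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1.5), 3 * mc_se)

  # adding is_home can only reduce residual SS (nesting)
  sim <- generate_trials(small_params(5, delta = 0.8))
  hm <- assign_home(relative_yields(sim$trials))
  expect_lte(fit_hfa(sim$trials, hm)$rss,
             fit_hfa(sim$trials, hm, include_home = FALSE)$rss + 1e-10)

  # estimated homes inflate the premium at delta = 0 (argmax selection bias)
  ests0 <- vapply(61:70, function(seed) {
    sim <- generate_trials(small_params(seed, delta = 0))
    hm <- assign_home(relative_yields(sim$trials))
    fit_hfa(sim$trials, hm)$hfa
  }, numeric(1))
  expect_gt(mean(ests0), 0)

  # no record at home: explicit degenerate-design error
  d <- toy_trials()
  hm <- assign_home(relative_yields(d))
  hm$home$home_site <- "nowhere"
  expect_error(fit_hfa(d, hm), "degenerate")
})

test_that("the overall HFA carries a reproducible case-bootstrap SE", {
  sim <- generate_trials(small_params(55, delta = 1, n_years = 4L,
                                      n_varieties = 24L))
  hm <- assign_home(relative_yields(sim$trials))
  b1 <- hfa_case_bootstrap(sim$trials, hm, n_boot = 30, seed = 9)
  b2 <- hfa_case_bootstrap(sim$trials, hm, n_boot = 30, seed = 9)
  expect_identical(b1$estimates, b2$estimates)
  expect_true(is.finite(b1$se) && b1$se > 0)
  # the bootstrap spread should be on the order of the model SE
  f <- fit_hfa(sim$trials, hm)
  expect_lt(b1$se, 10 * f$hfa_se)
  expect_gt(b1$se, f$hfa_se / 10)
})

test_that("model comparison reports control-minus-full deltas and guards misuse", {
  sim <- generate_trials(small_params(8, delta = 2, sigma_e = 1))
  hm <- assign_home(relative_yields(sim$trials))
  full <- fit_hfa(sim$trials, hm)
  ctrl <- fit_hfa(sim$trials, hm, include_home = FALSE)
  cmp <- compare_models(full, ctrl)
  expect_equal(cmp$delta_aic, ctrl$aic - full$aic)
  expect_equal(cmp$delta_bic, ctrl$bic - full$bic)

  # different n is an error
  ctrl2 <- fit_hfa(sim$trials[-1, ], hm, include_home = FALSE)
  expect_error(compare_models(full, ctrl2), "different numbers")

  # a 'full' fit without an estimated home term must not be compared
  expect_error(compare_models(ctrl, ctrl), "home term")
})

test_that("a real home premium wins the AIC comparison almost always", {
  wins <- vapply(1:60, function(seed) {
    sim <- generate_trials(small_params(seed + 400, delta = 2, sigma_e = 1))
    hm <- assign_home(relative_yields(sim$trials))
    cmp <- compare_models(fit_hfa(sim$trials, hm),
                          fit_hfa(sim$trials, hm, include_home = FALSE))
    cmp$delta_aic > 0
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("Type-II variance shares match a nested-RSS oracle and sum to one", {
  sim <- generate_trials(small_params(12, delta = 0.5))
  d <- sim$trials
  vp <- variance_partition(d)
  expect_equal(sum(vp$share), 1, tolerance = 1e-9)
  expect_true(all(vp$share >= 0 & vp$share <= 1))

  md <- data.frame(yield = d$yield, genotype = factor(d$variety),
                   site = factor(d$site), year = factor(d$year))
  oracle <- type2_nested_oracle(md)
  got <- setNames(vp$sum_sq, vp$term)[names(oracle)]
  expect_equal(unname(got), unname(oracle), tolerance = 1e-8)

  # record order cannot matter
  set.seed(1); d2 <- d[sample(nrow(d)), , drop = FALSE]
  vp2 <- variance_partition(d2)
  expect_equal(vp2$share, vp$share, tolerance = 1e-9)

  # the home term enters the partition when asked
  hm <- assign_home(relative_yields(d))
  vph <- variance_partition(d, hm, include_home = TRUE)
  expect_true("is_home" %in% vph$term)
  md$is_home <- is_home_indicator(d, hm)
  oh <- type2_nested_oracle(md, include_home = TRUE)
  goth <- setNames(vph$sum_sq, vph$term)[names(oh)]
  expect_equal(unname(goth), unname(oh), tolerance = 1e-8)
})

test_that("orthogonal balanced designs make Type II equal Type I", {
  # fully crossed, balanced, no interaction term ambiguity
  d <- expand.grid(variety = paste0("v", 1:3), site = paste0("s", 1:4),
                   year = 2001:2002, KEEP.OUT.ATTRS = FALSE)
  set.seed(5)
  d$yield <- abs(5 + rnorm(nrow(d)))
  vp <- variance_partition(d)
  a1 <- anova(lm(yield ~ genotype + site + year + site:year,
                 data.frame(yield = d$yield, genotype = factor(d$variety),
                            site = factor(d$site), year = factor(d$year))))
  expect_equal(setNames(vp$sum_sq, vp$term)[c("genotype", "site", "year")],
               setNames(a1$`Sum Sq`, rownames(a1))[c("genotype", "site", "year")],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the home term's residual share agrees with its definition", {
  sim <- generate_trials(small_params(9, delta = 1))
  d <- sim$trials
  hm <- assign_home(relative_yields(d))
  hs <- home_share_of_residual(d, hm)
  full <- fit_hfa(d, hm)
  ctrl <- fit_hfa(d, hm, include_home = FALSE)
  expect_equal(hs$share_residual, (ctrl$rss - full$rss) / ctrl$rss,
               tolerance = 1e-10)
  tss <- sum((d$yield - mean(d$yield))^2)
  expect_equal(hs$share_total, (ctrl$rss - full$rss) / tss, tolerance = 1e-10)

  # nothing left to explain in noise-free additive data
  sim0 <- generate_trials(small_params(10, delta = 0, sigma_sy = 0, sigma_e = 0))
  hm0 <- assign_home(relative_yields(sim0$trials))
  hs0 <- home_share_of_residual(sim0$trials, hm0)
  expect_true(hs0$degenerate)
  expect_equal(hs0$share_residual, 0)
})

test_that("yearly HFA estimates recover a planted premium with honest bootstrap SEs", {
  # single-year recovery across seeds
  ests <- vapply(1:15, function(seed) {
    sim <- generate_trials(small_params(seed + 500, delta = 1.2, n_years = 1L,
                                        n_sites = 8L, n_varieties = 8L,
                                        vpc = 4L))
    hm <- assign_home(relative_yields(sim$trials))
    yh <- suppressMessages(yearly_hfa(sim$trials, hm, n_boot = 0))
    if (nrow(yh)) yh$estimate[1] else NA_real_
  }, numeric(1))
  ests <- ests[!is.na(ests)]
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1.2), 3 * mc_se)

  # n_boot = 0 leaves SEs missing; estimates unchanged by asking for them
  sim <- generate_trials(small_params(33, delta = 1))
  hm <- assign_home(relative_yields(sim$trials))
  y0 <- suppressMessages(yearly_hfa(sim$trials, hm, n_boot = 0))
  expect_true(all(is.na(y0$se)))
  y1 <- suppressMessages(yearly_hfa(sim$trials, hm, n_boot = 25, seed = 2))
  expect_equal(y1$estimate, y0$estimate)
  expect_true(all(is.finite(y1$se)))

  # a noise-free year resamples to the same coefficient every time
  sim0 <- generate_trials(small_params(34, delta = 1, sigma_e = 0, sigma_gs = 0,
                                       n_years = 1L, n_sites = 8L,
                                       n_varieties = 8L, vpc = 4L))
  hm0 <- truth_home_map(sim0$truth)
  y <- suppressMessages(yearly_hfa(sim0$trials, hm0, n_boot = 20, seed = 3))
  if (nrow(y)) expect_lt(max(y$se), 1e-8)
})

test_that("trend regression equals the closed-form simple regression", {
  # perfectly linear series
  tf <- trend_regression(data.frame(year = 2001:2006,
                                    value = 2 + 0.3 * (2001:2006)))
  expect_equal(tf$slope, 0.3, tolerance = 1e-10)
  expect_equal(tf$adj_r2, 1, tolerance = 1e-8)

  set.seed(44)
  yr <- 2001:2006; val <- rnorm(6)
  tf <- trend_regression(data.frame(year = yr, value = val))
  o <- simple_reg_oracle(yr, val)
  expect_equal(tf$slope, o$slope, tolerance = 1e-10)
  expect_equal(tf$intercept, o$intercept, tolerance = 1e-10)

  expect_error(trend_regression(data.frame(year = 2001:2002, value = 1:2)),
               "at least 3")
})

test_that("high home advantage goes with less stable yields by construction", {
  # per-variety premium delta_v with residual noise scaled by delta_v: the
  # stability regression must find a positive slope nearly always
  positives <- vapply(1:50, function(seed) {
    set.seed(seed + 700)
    n_var <- 16; n_sites <- 6; n_years <- 3
    delta_v <- setNames(runif(n_var, 0, 2), paste0("v", seq_len(n_var)))
    home_v <- setNames(sample(paste0("s", seq_len(n_sites)), n_var, TRUE),
                       names(delta_v))
    d <- expand.grid(variety = names(delta_v),
                     site = paste0("s", seq_len(n_sites)),
                     year = 2000L + seq_len(n_years),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    at_home <- home_v[d$variety] == d$site
    d$yield <- abs(10 + rnorm(nrow(d), 0, 0.2 + 0.8 * delta_v[d$variety]) +
                     delta_v[d$variety] * at_home)
    hm <- assign_home(relative_yields(d))
    stability_regression(d, hm)$slope > 0
  }, logical(1))
  expect_gte(mean(positives), 0.9)

  # identical z everywhere -> degenerate guard
  d <- expand.grid(variety = c("a", "b", "c"), site = c("x", "y"),
                   year = 2001:2002, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$yield <- c(1, 2, 3)[match(d$variety, c("a", "b", "c"))]  # same ranks per cell
  hm <- assign_home(relative_yields(d))
  expect_error(stability_regression(d, hm), "zero variance|degenerate")
})
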
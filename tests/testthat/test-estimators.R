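test_that("Wald ratio follows the delta method and its symmetries", {
  est <- wald_ratio(list(beta_x = 0.5, se_x = 0.02, beta_y = 0.1,
                         se_y = 0.05))
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(est$ci_low, 0.2 - qnorm(0.975) * 0.1)
  zero <- wald_ratio(list(beta_x = 0.5, se_x = 0.02, beta_y = 0,
                          se_y = 0.05))
  expect_equal(zero$beta, 0)
  neg <- wald_ratio(list(beta_x = -0.5, se_x = 0.02, beta_y = -0.1,
                         se_y = 0.05))
  expect_equal(neg$beta, est$beta)
  expect_equal(neg$se, est$se)
  expect_error(wald_ratio(list(beta_x = 0, se_x = 0.02, beta_y = 0.1,
                               se_y = 0.05)),
               class = "mrkit_degenerate_instruments")
})

test_that("IVW reduces to the Wald ratio for one variant and is exact at zero noise", {
  d1 <- rand_dataset(1, seed = 5)
  ivw1 <- mr_ivw(d1)
  w1 <- wald_ratio(d1)
  expect_equal(ivw1$beta, w1$beta)
  expect_equal(ivw1$se, w1$se)
  expect_match(ivw1$note, "single variant")

  exact <- mr_dataset(paste0("v", 1:5), beta_x = c(0.1, 0.2, 0.05, 0.3, 0.15),
                      se_x = 0.01, beta_y = 0.4 * c(0.1, 0.2, 0.05, 0.3, 0.15),
                      se_y = c(0.01, 0.02, 0.03, 0.01, 0.02))
  re <- mr_ivw(exact, "random")
  fe <- mr_ivw(exact, "fixed")
  expect_equal(re$beta, 0.4)
  expect_equal(re$q, 0, tolerance = 1e-20)
  expect_equal(re$se, fe$se)  # overdispersion floor at 1
})

test_that("IVW and Egger match brute-force weighted least squares", {
  for (seed in c(11, 12, 13)) {
    d <- rand_dataset(10, seed = seed, noise = 0.01)
    w <- 1 / d$se_y^2
    fit0 <- lm(beta_y ~ 0 + beta_x, data = d, weights = w)
    ivw <- mr_ivw(d, "fixed")
    expect_equal(ivw$beta, unname(coef(fit0)), tolerance = 1e-10)
    s0 <- summary(fit0)
    expect_equal(ivw$se, s0$coefficients[1, 2] / s0$sigma, tolerance = 1e-10)

    d$beta_y <- d$beta_y * sign(d$beta_x)
    d$beta_x <- abs(d$beta_x)  # Egger orientation applied to the oracle too
    fit1 <- lm(beta_y ~ beta_x, data = d, weights = w)
    egger <- mr_egger(d)
    expect_equal(egger$beta, unname(coef(fit1)[2]), tolerance = 1e-10)
    expect_equal(egger$intercept, unname(coef(fit1)[1]), tolerance = 1e-10)
    s1 <- summary(fit1)
    scale <- max(1, s1$sigma)
    expect_equal(egger$se, s1$coefficients[2, 2] / s1$sigma * scale,
                 tolerance = 1e-10)
  }
})

test_that("Cochran's Q is zero for identical ratios and exact on a toy pair", {
  same <- mr_dataset(c("a", "b", "c"), beta_x = c(0.1, 0.2, 0.4),
                     se_x = 0.01, beta_y = 0.5 * c(0.1, 0.2, 0.4),
                     se_y = 0.02)
  q0 <- cochran_q(same)
  expect_equal(q0$q, 0, tolerance = 1e-20)
  expect_equal(q0$q_pvalue, 1)
  # two variants, ratios 0 and 1 with unit weights: Q = 0.5 at beta_hat 0.5
  toy <- mr_dataset(c("a", "b"), beta_x = c(1, 1), se_x = 0.01,
                    beta_y = c(0, 1), se_y = c(1, 1))
  expect_equal(cochran_q(toy, beta_hat = 0.5)$q, 0.5)
  # equivalence with the IVW residual form
  d <- rand_dataset(15, seed = 3, noise = 0.02)
  ivw <- mr_ivw(d)
  expect_equal(cochran_q(d, beta_hat = ivw$beta)$q, ivw$q)
})

test_that("Egger interpolates exactly and needs three variants", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  d <- mr_dataset(paste0("v", 1:4), beta_x = bx, se_x = 0.01,
                  beta_y = 0.02 + 0.5 * bx, se_y = 0.02)
  est <- mr_egger(d)
  expect_equal(est$intercept, 0.02)
  expect_equal(est$beta, 0.5)
  expect_error(mr_egger(rand_dataset(2, seed = 1)),
               class = "mrkit_insufficient_instruments")
})

test_that("weighted median interpolates the weighted quantile at one half", {
  d <- mr_dataset(c("a", "b", "c"), beta_x = c(1, 1, 1), se_x = 0.01,
                  beta_y = c(1, 2, 3), se_y = c(1, 1, 1))
  est <- mr_weighted_median(d, n_boot = 100, seed = 1)
  expect_equal(est$beta, 2)
  expect_identical(est$seed, 1)

  # grid-search oracle for the weighted-quantile definition
  set.seed(8)
  for (rep in 1:5) {
    k <- 9
    ratio <- rnorm(k)
    wgt <- runif(k, 0.5, 2)
    d2 <- mr_dataset(paste0("v", 1:k), beta_x = rep(1, k), se_x = 0.01,
                     beta_y = ratio, se_y = 1 / sqrt(wgt))
    est2 <- mr_weighted_median(d2, n_boot = 50, seed = 2)
    ord <- order(ratio)
    r <- ratio[ord]
    p <- (cumsum(wgt[ord]) - wgt[ord] / 2) / sum(wgt)
    j <- max(which(p <= 0.5))
    oracle <- r[j] + (0.5 - p[j]) / (p[j + 1] - p[j]) * (r[j + 1] - r[j])
    expect_equal(est2$beta, oracle)
  }
})

test_that("weighted median resists up to half invalid weight and tracks majorities", {
  # 6 valid instruments (ratio 0.3) carrying ~60% of weight, 4 invalid at 2.0
  bx <- rep(1, 10)
  by <- c(rep(0.3, 6), rep(2.0, 4))
  sy <- c(rep(1, 6), rep(1.1, 4))
  d <- mr_dataset(paste0("v", 1:10), bx, 0.01, by, sy)
  est <- mr_weighted_median(d, n_boot = 100, seed = 3)
  expect_lt(abs(est$beta - 0.3), abs(est$beta - 2.0))
  # a single variant holding > 50% of weight pins the estimate near its ratio
  d2 <- mr_dataset(c("big", "s1", "s2"), beta_x = c(1, 1, 1), se_x = 0.01,
                   beta_y = c(1, 4, 5), se_y = c(0.1, 1, 1))
  est2 <- mr_weighted_median(d2, n_boot = 50, seed = 4)
  expect_lt(est2$beta, 4)
})

test_that("the mode-based estimate finds the dominant ratio cluster", {
  d <- mr_dataset(paste0("v", 1:4), beta_x = rep(1, 4), se_x = 0.01,
                  beta_y = c(1, 1.01, 0.99, 5), se_y = rep(1, 4))
  est <- mr_mode(d, n_boot = 50, seed = 5)
  h <- mad(c(1, 1.01, 0.99, 5))
  expect_lt(abs(est$beta - 1), h)
  same <- mr_dataset(paste0("v", 1:3), beta_x = rep(1, 3), se_x = 0.01,
                     beta_y = rep(0.7, 3), se_y = rep(1, 3))
  expect_equal(mr_mode(same, n_boot = 50, seed = 6)$beta, 0.7)
})

test_that("the mode argmax agrees with an independent fine-grid density scan", {
  d <- rand_dataset(12, seed = 21, noise = 0.03)
  est <- mr_mode(d, n_boot = 50, seed = 7)
  ratio <- d$beta_y / d$beta_x
  wgt <- d$beta_x^2 / d$se_y^2
  wgt <- wgt / sum(wgt)
  h <- mad(ratio)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 2001)
  dens <- vapply(grid, function(x) sum(wgt * dnorm((x - ratio) / h)),
                 numeric(1))
  expect_equal(est$beta, grid[which.max(dens)],
               tolerance = diff(range(grid)) / 2000)
})

test_that("leave-one-out pinpoints an injected outlier and counts refits", {
  d <- rand_dataset(12, seed = 14, noise = 0.002)
  loo_clean <- leave_one_out(d)
  expect_equal(nrow(loo_clean), 12L)
  full <- attr(loo_clean, "full_estimate")
  expect_true(all(abs(loo_clean$beta - full$beta) <= full$se))

  d$beta_y[4] <- d$beta_y[4] + 25 * d$se_y[4]
  loo <- leave_one_out(d)
  expect_equal(which.max(abs(loo$delta)), 4L)
  expect_equal(nrow(leave_one_out(rand_dataset(3, seed = 2))), 3L)
})

test_that("all estimators are equivariant under joint sign flips", {
  d <- rand_dataset(10, seed = 33, noise = 0.02)
  flip <- d
  sgn <- rep(c(-1, 1), 5)
  flip$beta_x <- d$beta_x * sgn
  flip$beta_y <- d$beta_y * sgn
  expect_equal(mr_ivw(d)$beta, mr_ivw(flip)$beta)
  expect_equal(mr_egger(d)$beta, mr_egger(flip)$beta)
  expect_equal(mr_egger(d)$intercept, mr_egger(flip)$intercept)
  expect_equal(mr_weighted_median(d, 100, seed = 9)$beta,
               mr_weighted_median(flip, 100, seed = 9)$beta)
  expect_equal(mr_mode(d, n_boot = 20, seed = 9)$beta,
               mr_mode(flip, n_boot = 20, seed = 9)$beta)
})

test_that("fixed-effect IVW standard errors never exceed random-effects ones", {
  for (seed in 1:8) {
    d <- rand_dataset(8, seed = seed, noise = 0.05)
    expect_lte(mr_ivw(d, "fixed")$se, mr_ivw(d, "random")$se)
  }
})

test_that("estimator confidence intervals bracket the point estimate", {
  d <- rand_dataset(10, seed = 55, noise = 0.02)
  for (est in list(mr_ivw(d), mr_egger(d),
                   mr_weighted_median(d, 50, seed = 1),
                   mr_mode(d, n_boot = 20, seed = 1))) {
    expect_lte(est$ci_low, est$beta)
    expect_gte(est$ci_high, est$beta)
    expect_gt(est$se, 0)
    if (!is.null(est$q)) expect_gte(est$q, 0)
  }
})
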
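test_that("conditional likelihood: null value, discordant-pair closed form, grid oracle", {
  ## perfectly balanced discordance: MLE at 0, loglik = n * ln(1/2)
  d0 <- matrix(c(1, -1, 1, -1), ncol = 1, dimnames = list(NULL, "x"))
  f0 <- clogit_fit(d0)
  expect_equal(unname(f0$beta), 0, tolerance = 1e-10)
  expect_equal(f0$loglik, 4 * log(0.5))

  ## matched-pair OR = ratio of discordant counts
  d <- matrix(c(rep(1, 30), rep(-1, 10)), ncol = 1,
              dimnames = list(NULL, "exposed"))
  f <- clogit_fit(d)
  expect_equal(unname(f$beta), log(3), tolerance = 1e-8)
  expect_true(f$converged)

  ## small toy surface vs a dense grid search
  toy <- rbind(c(1, 0), c(1, 0), c(0, 1), c(-1, -1), c(1, -1), c(-1, 1))
  colnames(toy) <- c("a", "b")
  ft <- clogit_fit(toy)
  grid <- as.matrix(expand.grid(a = seq(-3, 3, 0.01), b = seq(-3, 3, 0.01)))
  ll <- function(b) {
    eta <- toy %*% b
    sum(eta - log1p(exp(eta)))
  }
  vals <- apply(grid, 1, ll)
  best <- grid[which.max(vals), ]
  expect_equal(unname(ft$beta), unname(best), tolerance = 0.011)
  expect_gte(ft$loglik, max(vals) - 1e-10)
  expect_lte(abs(ft$loglik - max(vals)), 1e-4)
})

test_that("concordant pairs change neither estimates nor the LRT", {
  sim <- simulate_matched_pairs(200, beta_g = 0.4, beta_gxe = 0.2, seed = 201)
  d <- sim$diffs[, c("carrier", "mds_q", "carrier_mds_q")]
  full_a <- clogit_fit(d)
  red_a <- clogit_fit(d[, 1:2])
  padded <- rbind(d, matrix(0, 50, 3, dimnames = list(NULL, colnames(d))))
  full_b <- clogit_fit(padded)
  red_b <- clogit_fit(padded[, 1:2])
  expect_equal(full_a$beta, full_b$beta, tolerance = 1e-8)
  expect_equal(lrt_interaction(full_a, red_a)$lr_chi2,
               lrt_interaction(full_b, red_b)$lr_chi2, tolerance = 1e-8)
})

test_that("pair-difference fit equals an intercept-free logistic on differences", {
  sim <- simulate_matched_pairs(400, beta_g = 0.3, beta_e = -0.1,
                                beta_gxe = 0.15, seed = 202)
  d <- sim$diffs[, c("carrier", "mds_q", "carrier_mds_q")]
  a <- clogit_fit(d)
  b <- logit_fit(d, rep(1, nrow(d)), intercept = FALSE)
  expect_equal(unname(a$beta), unname(b$beta), tolerance = 1e-6)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-8)
})

test_that("conditional fit matches the survival package on simulated pairs", {
  skip_if_not_installed("survival")
  sim <- simulate_matched_pairs(500, beta_g = 0.5, beta_e = 0.1,
                                beta_gxe = -0.2, seed = 203)
  d <- sim$diffs[, c("carrier", "mds_q", "carrier_mds_q")]
  ours <- clogit_fit(d)
  long <- data.frame(y = rep(c(1, 0), each = nrow(d)),
                     strat = rep(seq_len(nrow(d)), 2))
  long <- cbind(long, rbind(d, matrix(0, nrow(d), 3,
                                      dimnames = list(NULL, colnames(d)))))
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(long)), y) ~ carrier + mds_q +
      carrier_mds_q + survival::strata(strat),
    data = long, method = "exact")
  expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(ours$cov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
})

test_that("separation and degenerate designs are flagged", {
  d <- matrix(rep(1, 12), ncol = 1, dimnames = list(NULL, "x"))
  expect_warning(f <- clogit_fit(d), "separation")
  expect_false(f$converged)
  dz <- cbind(x = c(1, -1, 0), z = c(0, 0, 0))
  expect_error(clogit_fit(dz), "no discordant")
  expect_error(logit_fit(cbind(a = c(1, 2, 3), b = c(2, 4, 6)), c(0, 1, 0)),
               "rank deficient")
})

test_that("logistic regression: closed forms and agreement with glm", {
  ## intercept-only at prevalence one half
  f <- logit_fit(matrix(numeric(0), nrow = 10, ncol = 0),
                 rep(c(0, 1), 5))
  expect_equal(unname(f$beta), 0, tolerance = 1e-10)

  ## 2x2 table log-OR = ln(ad/bc)
  x <- c(rep(1, 30), rep(0, 30))
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  f2 <- logit_fit(cbind(exposed = x), y)
  expect_equal(f2$beta[["exposed"]], log(20 * 20 / (10 * 10)),
               tolerance = 1e-8)

  withr::local_seed(204)
  xs <- cbind(x1 = rnorm(800), x2 = rbinom(800, 1, 0.4))
  ys <- rbinom(800, 1, plogis(-1 + 0.5 * xs[, 1] - 0.3 * xs[, 2]))
  ours <- logit_fit(xs, ys)
  ref <- glm(ys ~ xs, family = binomial())
  expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(ours$cov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("logistic regression recovers known coefficients within Monte-Carlo error", {
  withr::local_seed(205)
  n <- 5000
  x <- cbind(z = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + 0.5 * x[, 1]))
  f <- logit_fit(x, y)
  se <- sqrt(diag(f$cov))
  expect_lt(abs(f$beta[["(Intercept)"]] - (-1)), 3 * se[1])
  expect_lt(abs(f$beta[["z"]] - 0.5), 3 * se[2])
})

test_that("likelihood-ratio test basics and affine-recoding invariance", {
  sim <- simulate_matched_pairs(300, beta_g = 0.4, seed = 206)
  d <- sim$diffs[, c("carrier", "mds_q", "carrier_mds_q")]
  f <- clogit_fit(d)
  same <- lrt_interaction(f, f, df = 1)
  expect_equal(same$lr_chi2, 0)
  expect_equal(same$p_value, 1)

  r <- clogit_fit(d[, 1:2])
  t1 <- lrt_interaction(f, r)
  ## recode covariates affinely (difference design: scale only)
  d2 <- d %*% diag(c(2, 0.5, 4))
  colnames(d2) <- colnames(d)
  t2 <- lrt_interaction(clogit_fit(d2), clogit_fit(d2[, 1:2]))
  expect_equal(t1$lr_chi2, t2$lr_chi2, tolerance = 1e-6)

  bad_full <- f; bad_full$loglik <- f$loglik - 5
  expect_error(lrt_interaction(bad_full, f, df = 1), "convergence")
})

test_that("interaction LRT gains power with effect size and sample size", {
  pow <- function(b, n) {
    calibrate(beta_gxe = b, n_reps = 60, n_pairs = n, seed = 207)$rate
  }
  p_null <- pow(0, 400)
  p_eff <- pow(0.5, 400)
  p_eff_big <- pow(0.5, 1200)
  expect_gt(p_eff, p_null)
  expect_gte(p_eff_big, p_eff)
})

test_that("trend test: zero slope for flat risk, uniform p under the null", {
  ## identical outcome rates in every quartile: slope estimate near 0
  q <- rep(1:4, each = 40)
  y <- rep(rep(c(1, 0), each = 20), 4)
  score <- quartile_median_score(rep(2 * (1:8), each = 20), assign_quartiles(
    rep(2 * (1:8), each = 20)))
  f <- logit_fit(cbind(trend = score), y)
  expect_lt(abs(f$beta[["trend"]]), 1e-6)
  expect_gt(trend_test(f, "trend")$p_value, 0.99)

  withr::local_seed(208)
  pvals <- replicate(300, {
    n <- 200
    qq <- sample(1:4, n, replace = TRUE)
    yy <- rbinom(n, 1, 0.4)
    trend_test(logit_fit(cbind(trend = qq), yy), "trend")$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("quartile medians enter the trend model as the stated continuous coding", {
  mds <- c(0, 1, 1, 2, 4, 4, 5, 6, 7, 8, 8, 8)
  q <- assign_quartiles(mds)
  sc <- quartile_median_score(mds, q)
  med <- tapply(mds, q, median)
  expect_equal(sc, as.numeric(med[as.character(q)]))
})

test_that("odds-ratio report evaluates Wald intervals exactly", {
  fit <- structure(list(beta = c(a = 0, b = log(2)),
                        cov = diag(c(0.01, 0.04)),
                        loglik = -1, n_obs = 10, converged = TRUE,
                        iterations = 1, model_label = "toy"),
                   class = c("clogit_fit", "gxe_fit"))
  dimnames(fit$cov) <- list(c("a", "b"), c("a", "b"))
  rep_ <- or_report(fit)
  expect_equal(rep_$or, c(1, 2))
  expect_equal(rep_$ci_lo[1], exp(-1.96 * 0.1))
  expect_equal(rep_$ci_hi[1], exp(1.96 * 0.1))
  expect_true(all(rep_$ci_lo < rep_$or & rep_$or < rep_$ci_hi))
})

test_that("descriptive comparisons: identical groups, planted shift, textbook chi-square", {
  base <- data.frame(v = rep(c(1.2, 3.4, 5.6, 7.8), 25),
                     cat = rep(c("x", "y"), 50))
  dat <- rbind(base, base)
  grp <- rep(c("case", "control"), each = 100)
  de <- cohort_descriptives(dat, grp, continuous = "v", categorical = "cat")
  expect_true(all(de$p_value == 1))

  withr::local_seed(209)
  a <- rnorm(200); b <- rnorm(200) + 0.5
  shifted <- data.frame(v = c(a, b))
  ds <- cohort_descriptives(shifted, rep(c("g1", "g2"), each = 200),
                            continuous = "v")
  expect_lt(ds$p_value, 0.05)

  ## chi-square from a printed 2x2 against the textbook formula
  tab <- matrix(c(30, 20, 10, 40), 2)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2_hand <- sum((tab - expected)^2 / expected)
  d2 <- data.frame(cat = rep(rep(c("a", "b"), 2), times = c(30, 20, 10, 40)))
  g2 <- rep(c("g1", "g2"), times = c(50, 50))
  dc <- cohort_descriptives(d2, g2, categorical = "cat")
  expect_equal(unique(dc$p_value),
               pchisq(chi2_hand, df = 1, lower.tail = FALSE),
               tolerance = 1e-10)
})
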
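test_that("Kaplan-Meier matches forced examples and the risk-set oracle", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  km_c <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(survival_at(km_c, c(0, 1, 5)), c(1, 1, 1))

  # 8-subject mixed fixture: frozen values from the independent risk-set
  # oracle (and cross-checked against survival::survfit)
  time <- c(2, 3, 3, 5, 7, 8, 10, 12)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0)
  km8 <- km_estimate(time, event)
  want <- oracle_km(time, event)
  expect_equal(km8$time, want$time)
  expect_equal(km8$surv, want$surv)
  expect_equal(km8$surv, c(0.875, 0.75, 0.6, 0.4, 0.2))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(survival_at(km8, sf$time), sf$surv)

  # monotone, right-continuous step evaluation
  expect_equal(survival_at(km8, 0), 1)
  expect_equal(survival_at(km8, 100), 0.2)
  expect_true(all(diff(km8$surv) <= 0))

  # with no censoring S(t) equals the empirical survivor fraction
  set.seed(17)
  t2 <- rexp(50) + 0.1
  km2 <- km_estimate(t2, rep(1, 50))
  expect_equal(survival_at(km2, km2$time),
               vapply(km2$time, function(tt) mean(t2 > tt), numeric(1)))
})

test_that("log-rank matches survdiff, is symmetric, and handles null input", {
  time <- c(2, 3, 3, 5, 7, 8, 10, 12)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0)
  group <- rep(c("a", "b"), 4)
  lr <- logrank_test(time, event, group)
  sd_ref <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$chi_square, sd_ref$chisq, tolerance = 1e-12)
  expect_equal(unname(lr$observed), unname(sd_ref$obs))
  expect_equal(unname(lr$expected), unname(sd_ref$exp))
  expect_equal(sum(lr$observed), sum(event))

  # identical groups -> zero statistic
  lr0 <- logrank_test(rep(time, 2), rep(event, 2),
                      rep(c("a", "b"), each = 8))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)

  # invariance under relabeling
  lr_sw <- logrank_test(time, event, ifelse(group == "a", "b", "a"))
  expect_equal(lr_sw$chi_square, lr$chi_square)

  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")

  set.seed(18)
  for (i in 1:10) {
    n <- 40
    tt <- round(rexp(n, 0.1), 1) + 0.1   # force ties
    ev <- rbinom(n, 1, 0.7)
    gg <- sample(c("x", "y"), n, replace = TRUE)
    if (sum(ev) == 0 || length(unique(gg)) < 2) next
    lr_i <- logrank_test(tt, ev, gg)
    sd_i <- survival::survdiff(survival::Surv(tt, ev) ~ gg)
    expect_equal(lr_i$chi_square, sd_i$chisq, tolerance = 1e-10)
  }
})

test_that("log-rank p-values are near-uniform under group permutation", {
  set.seed(19)
  n <- 60
  tt <- rexp(n, 0.05)
  ev <- rbinom(n, 1, 0.8)
  gg <- rep(c("a", "b"), each = n / 2)
  ps <- vapply(1:300, function(i) {
    logrank_test(tt, ev, sample(gg))$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Cox fit matches coxph (Efron) and its own invariants", {
  set.seed(20)
  n <- 400
  x <- cbind(expr = rnorm(n), age = rnorm(n))
  tt <- round(rexp(n, 0.05 * exp(0.6 * x[, 1] - 0.3 * x[, 2])), 1) + 0.1
  ev <- rbinom(n, 1, 0.8)
  fit <- cox_fit(tt, ev, x)
  ref <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = "efron")
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  # partial likelihood at the optimum is at least the null value
  expect_gte(fit$loglik["fitted"], fit$loglik["null"])
  # CI contains the HR
  expect_true(all(fit$ci95[, "lower"] <= fit$hr &
                    fit$hr <= fit$ci95[, "upper"]))

  expect_error(cox_fit(tt, ev, rep(1, n)), "constant covariate")

  # null data: the estimate concentrates near zero
  set.seed(21)
  z0 <- rnorm(1000)
  t0 <- rexp(1000, 0.05)
  f0 <- cox_fit(t0, rep(1, 1000), z0)
  expect_lt(abs(f0$beta), 0.1)
})

test_that("Spearman matches cor.test including ties", {
  expect_equal(spearman_rho(1:10, 2 * (1:10))$rho, 1)
  expect_equal(spearman_rho(1:10, 10:1)$rho, -1)
  set.seed(22)
  for (i in 1:10) {
    x <- sample(1:5, 30, replace = TRUE)   # heavy ties
    y <- x + sample(1:4, 30, replace = TRUE)
    s <- spearman_rho(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(s$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(spearman_rho(1:4, 1:5), "length mismatch")
})

test_that("dichotomize implements median/cutoff/youden splits", {
  expect_equal(dichotomize(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(dichotomize(c(5, 9), "cutoff", cutoff = 1),
               c("high", "high"))
  expect_error(dichotomize(c(2, 2, 2)), "identical")

  scores <- c(1, 2, 3, 4, 6, 8)
  outcomes <- c(0, 0, 0, 1, 1, 1)
  g <- dichotomize(scores, "youden", outcomes = outcomes)
  yc <- oracle_youden(scores, outcomes)
  expect_equal(g, ifelse(scores >= yc$cutoff, "high", "low"))
})
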
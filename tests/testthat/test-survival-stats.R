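test_that("inclusion filter applies both rules with reasons", {
  rec <- data.table(id = c("a", "b", "c", "d", "e"),
                    os_months = c(1, 2, 17, 18, NA),
                    event = c(1, 1, 0, 0, 1))
  f <- apply_inclusion_filter(rec)
  expect_setequal(f$included$id, c("b", "d"))   # death at 2 is included
  expect_equal(f$excluded[id == "a"]$reason, "early_death")
  expect_equal(f$excluded[id == "c"]$reason, "short_followup")
  expect_equal(f$excluded[id == "e"]$reason, "missing")
})

test_that("inclusion filter keeps 76 of the 80 reference patients", {
  clin <- load_series1_clinical()
  f <- apply_inclusion_filter(clin)
  expect_equal(nrow(f$included), 76)
  expect_setequal(f$excluded$id, c("G72", "G65", "G14", "G12"))
  expect_true(all(f$excluded$reason == "early_death"))
})

test_that("Kaplan-Meier product limit and median convention", {
  f1 <- km_fit(5, 1)
  expect_equal(km_median(f1), 5)
  f2 <- km_fit(c(1, 2, 3, 4), rep(1, 4))
  expect_equal(f2$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km_median(f2), 2)   # S(2) = 0.5 exactly
  # all censored: valid curve, median not reached
  f3 <- km_fit(c(10, 20), c(0, 0))
  expect_true(is.na(km_median(f3)))
  # no censoring: S equals the empirical survivor function
  set.seed(9)
  t <- sample(1:40, 25, replace = TRUE)
  f4 <- km_fit(t, rep(1, 25))
  for (i in seq_len(nrow(f4)))
    expect_equal(f4$surv[i], mean(t > f4$time[i]))
})

test_that("Kaplan-Meier agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(14)
  t <- rexp(60, 0.1); e <- rbinom(60, 1, 0.7)
  ours <- km_fit(t, e)
  ref <- summary(survival::survfit(survival::Surv(t, e) ~ 1))
  expect_equal(ours$time, ref$time, tolerance = 1e-12)
  expect_equal(ours$surv, ref$surv, tolerance = 1e-12)
})

test_that("log-rank: symmetry, degenerate groups, oracle equivalence", {
  t <- c(3, 5, 7, 9); e <- c(1, 1, 1, 0)
  same <- logrank_test(rep(t, 2), rep(e, 2), rep(c("A", "B"), each = 4))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  set.seed(5)
  tt <- rexp(30); ee <- rbinom(30, 1, 0.8)
  gg <- rep(c("A", "B", "C"), 10)
  a <- logrank_test(tt, ee, gg)
  b <- logrank_test(tt, ee, factor(gg, levels = c("C", "A", "B")))
  expect_equal(a$chisq, b$chisq, tolerance = 1e-10)
  expect_equal(a$df, 2)
  expect_error(logrank_test(tt, ee, factor(gg, levels = c("A", "B", "C",
                                                          "D"))),
               "zero subjects")
  # hand-worked 6-subject instance against the per-event-time 2x2 oracle
  t6 <- c(1, 2, 2, 4, 5, 6); e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- c("A", "B", "A", "B", "A", "B")
  lr <- logrank_test(t6, e6, g6)
  or <- logrank_oracle_2g(t6, e6, g6)
  expect_equal(lr$chisq, or$chisq, tolerance = 1e-12)
})

test_that("log-rank matches survdiff across random instances", {
  skip_if_not_installed("survival")
  set.seed(8)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    t <- round(rexp(n, 0.1)) + 1
    e <- rbinom(n, 1, 0.8)
    g <- sample(c("A", "B", if (i %% 2) "C"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    ours <- logrank_test(t, e, g)
    ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(ours$chisq, ref$chisq, tolerance = 1e-8)
  }
})

test_that("Cox fit matches coxph with Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(21)
  n <- 120
  x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
  t <- round(rexp(n, 0.08 * exp(0.8 * x1 - 0.3 * x2))) + 1
  e <- rbinom(n, 1, 0.85)
  X <- cbind(trt = x1, cov = x2)
  ours <- cox_fit(t, e, X)
  ref <- survival::coxph(survival::Surv(t, e) ~ x1 + x2,
                         ties = "breslow")
  expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(ours$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(ours$loglik, ref$loglik[2], tolerance = 1e-8)
  expect_equal(ours$loglik_null, ref$loglik[1], tolerance = 1e-8)
  # invariants: HR = exp(coef), CI brackets HR
  expect_equal(unname(ours$hr), unname(exp(ours$coef)))
  expect_true(all(ours$ci_lo < ours$hr & ours$hr < ours$ci_hi))
})

test_that("Cox degenerate inputs: no covariates, no events, separation", {
  t <- c(2, 4, 6, 8); e <- c(1, 1, 1, 1)
  f0 <- cox_fit(t, e, matrix(numeric(0), 4, 0))
  expect_equal(f0$loglik, f0$loglik_null)
  expect_error(cox_fit(t, c(0, 0, 0, 0), cbind(x = 1:4)), "1 event")
  # complete separation is flagged, not an uncaught failure
  xs <- c(0, 0, 1, 1); ts <- c(1, 2, 10, 12)
  fs <- cox_fit(ts, c(1, 1, 1, 1), cbind(x = xs))
  expect_true(fs$separation)
})

test_that("Cox recovers a planted hazard ratio and is monotone in it", {
  set.seed(3)
  hrs <- c(1.5, 3, 6)
  est <- vapply(hrs, function(hr) {
    x <- rbinom(400, 1, 0.5)
    t <- rexp(400, 0.1 * hr^x)
    cox_fit(t, rep(1, 400), cbind(x = x))$hr[[1]]
  }, 0)
  expect_true(all(diff(est) > 0))
  expect_lt(abs(log(est[2]) - log(3)), log(1.35))
})

test_that("stepwise selection keeps signal and drops noise", {
  set.seed(17)
  kept_signal <- 0; kept_noise <- 0
  for (r in 1:100) {
    n <- 120
    sig <- rbinom(n, 1, 0.5)
    noise <- sample(c("u", "v"), n, replace = TRUE)
    t <- round(rexp(n, 0.08 * 3^sig) * 10) / 10 + 0.1
    rec <- data.table(os_months = t, event = rep(1L, n),
                      sig = factor(sig), noise = factor(noise))
    sw <- suppressWarnings(stepwise_cox(rec, c("sig", "noise")))
    kept_signal <- kept_signal + ("sig" %in% sw$selected)
    kept_noise <- kept_noise + ("noise" %in% sw$selected)
  }
  expect_gte(kept_signal, 95)
  expect_lte(kept_noise, 10)   # noise excluded in >= 90% of replicates
})

test_that("stepwise edge cases: empty candidate set, gate failure", {
  rec <- data.table(os_months = c(2, 4, 6, 8, 10, 12),
                    event = rep(1L, 6),
                    junk = factor(rep(c("a", "b"), 3)))
  sw0 <- stepwise_cox(rec, character(0))
  expect_equal(sw0$selected, character(0))
  expect_warning(sw1 <- stepwise_cox(rec, "junk"), "null model")
  expect_equal(length(sw1$fit$coef), 0)
})

test_that("reference cohort: stepwise retains chemotherapy and risk group", {
  joined <- join_profiles_clinical(load_series1_profiles(),
                                   load_series1_clinical())
  inc <- apply_inclusion_filter(joined)$included
  sw <- stepwise_cox(inc, c("age_group", "karnofsky_group", "surgery",
                            "chemo_category", "risk"))
  expect_true(all(c("chemo_category", "risk") %in% sw$selected))
  # every candidate is univariately prognostic in this cohort
  expect_true(all(sw$gate < 0.05))
  hr_risk <- sw$fit$hr[grep("risk", names(sw$fit$hr))]
  expect_gt(hr_risk, 1)  # unfavorable group carries the excess hazard
})
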
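test_that("BH adjustment follows the step-up rule and is idempotent", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.04, 0.9, 0.2, 0.012)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone in the order statistics
  expect_true(all(diff(adj[order(p)]) >= 0))
  # hand step-up evaluation: p_adj(i) = min_{j >= i} (m/j) p_(j), capped at 1
  sorted <- sort(p)
  hand <- rev(cummin(rev(length(p) / seq_along(p) * sorted)))
  expect_equal(sort(adj), pmin(hand, 1))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(1.2), "\\(0, 1\\]")
})

test_that("linear association recovers a near-deterministic slope and is order-invariant", {
  set.seed(2)
  n <- 200
  x <- rnorm(n)
  covars <- data.frame(age = rnorm(n, 60, 10),
                       sex = sample(c("female", "male"), n, TRUE),
                       race = sample(c("a", "b", "c"), n, TRUE))
  y <- 2 * x + rnorm(n, sd = 1e-8)
  res <- linear_association(y, x, covars)
  expect_equal(res$coef, 2, tolerance = 1e-6)
  expect_true(res$ci_low <= res$coef && res$coef <= res$ci_high)

  perm <- sample(n)
  res2 <- linear_association(y[perm], x[perm], covars[perm, ])
  expect_equal(res2$coef, res$coef)
  expect_equal(res2$p, res$p)
})

test_that("linear association errors on rank-deficient designs", {
  set.seed(3)
  x <- rnorm(50)
  covars <- data.frame(age = rnorm(50), dup = NA)
  covars$dup <- covars$age  # aliased column
  expect_error(linear_association(rnorm(50), x, covars), "aliased")
})

test_that("logistic association estimates the log-odds slope and flips with labels", {
  set.seed(4)
  n <- 800
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 1 * x))
  res <- logistic_association(y, x)
  se <- (res$ci_high - res$ci_low) / (2 * 1.96)
  expect_lt(abs(res$coef - 1), 2 * se)
  flip <- logistic_association(1 - y, x)
  expect_equal(flip$coef, -res$coef, tolerance = 1e-6)
  expect_error(logistic_association(y, rep(1, n)), "aliased")
  expect_error(logistic_association(rep(1, n), x), "classes")
  # perfect separation is an error, not a divergent fit
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  expect_error(logistic_association(ys, xs), "separation")
})

test_that("KM curves match the product-limit computation on small instances", {
  rec <- clinical_records(paste0("p", 1:2), time = c(1, 2), event = c(1, 1))
  km <- km_curve(rec, rep("g", 2))
  expect_equal(km$surv[km$time == 1], 0.5)
  expect_equal(km$surv[km$time == 2], 0)

  # a group with no events stays flat at 1; zero events overall is an error
  mix <- clinical_records(paste0("p", 1:6), time = c(1, 2, 3, 1, 2, 3),
                          event = c(1, 1, 0, 0, 0, 0))
  kmix <- km_curve(mix, rep(c("a", "b"), each = 3))
  expect_true(all(kmix$surv[kmix$group == "b"] == 1))
  expect_error(km_curve(clinical_records("p", 1, 0), "g"), "no events")

  set.seed(5)
  for (i in 1:5) {
    n <- sample(3:5, 1)
    t <- round(runif(n, 1, 4), 1)
    e <- rbinom(n, 1, 0.7)
    if (!sum(e)) e[1] <- 1L
    rec <- clinical_records(paste0("p", 1:n), t, e)
    km <- km_curve(rec, rep("g", n))
    hand <- oracle_km(t, e)
    for (k in seq_len(nrow(hand)))
      expect_equal(km$surv[km$time == hand$time[k]][1], hand$surv[k])
  }

  # doubling every subject leaves the curve unchanged
  t <- c(1, 2, 3); e <- c(1, 0, 1)
  k1 <- km_curve(clinical_records(paste0("p", 1:3), t, e), rep("g", 3))
  k2 <- km_curve(clinical_records(paste0("p", 1:6), rep(t, 2), rep(e, 2)), rep("g", 6))
  expect_equal(k1$surv, k2$surv)
  expect_equal(k1$time, k2$time)
})

test_that("log-rank test is symmetric in labels and detects separation direction", {
  rec <- clinical_records(paste0("p", 1:40),
                          time = c(rexp(20, 1), rexp(20, 0.2)) + 0.01,
                          event = rep(1, 40))
  g <- rep(c("a", "b"), each = 20)
  lr <- logrank_test(rec, g)
  expect_gt(lr$chisq, 0)
  sw <- logrank_test(rec, ifelse(g == "a", "b", "a"))
  expect_equal(sw$chisq, lr$chisq)
  expect_equal(sw$p, lr$p)
  expect_error(logrank_test(rec, rep("a", 40)), "two groups")
})

test_that("Cox model recovers a planted hazard ratio with Efron ties", {
  set.seed(6)
  score <- rnorm(300)
  rec <- simulate_survival(score, true_loghr = -0.69, censoring_rate = 0.3, seed = 7)
  fit <- cox_ph(rec, data.frame(z = rec$z, age = rec$age, sex = rec$sex))
  zrow <- fit[fit$term == "z", ]
  expect_lt(abs(zrow$coef - (-0.69)), 2 * zrow$se)
  expect_equal(zrow$hr, exp(zrow$coef))

  # time-scale invariance of hazard ratios
  rec2 <- rec; rec2$time <- rec2$time * 365.25
  fit2 <- cox_ph(rec2, data.frame(z = rec$z, age = rec$age, sex = rec$sex))
  expect_equal(fit2[fit2$term == "z", "coef"], zrow$coef, tolerance = 1e-6)

  expect_error(cox_ph(rec, data.frame(z = rec$z, const = 1)), "aliased")
})

test_that("landmark AUC handles perfect ranking, antisymmetry, and filtering", {
  rec <- clinical_records(paste0("p", 1:20),
                          time = c(rep(0.5, 10), rep(5, 10)),
                          event = c(rep(1, 10), rep(0, 10)))
  scores <- c(rnorm(10, 10), rnorm(10, 0))  # cases ranked strictly above controls
  res <- landmark_auc(scores, rec, horizon = 1, n_boot = 100, seed = 1)
  expect_equal(res$auc, 1)
  expect_equal(res$n_case, 10)
  expect_equal(res$n_control, 10)

  neg <- landmark_auc(-scores, rec, horizon = 1, n_boot = 100, seed = 1)
  expect_equal(neg$auc, 1 - res$auc)

  # censored before the horizon are excluded
  rec2 <- rec
  rec2$event[1:10] <- 0  # now no cases at all
  expect_error(landmark_auc(scores, rec2, horizon = 1), "0 cases")

  # null scores give AUC near 1/2 with a covering CI
  set.seed(9)
  recn <- clinical_records(paste0("p", 1:400),
                           time = rexp(400, 0.5) + 1e-6, event = rbinom(400, 1, 0.8))
  null <- landmark_auc(rnorm(400), recn, horizon = 1, n_boot = 500, seed = 2)
  expect_lt(abs(null$auc - 0.5), 0.12)
  expect_true(null$ci_low <= 0.5 && 0.5 <= null$ci_high)
})

test_that("clinical_records validates its invariants", {
  expect_error(clinical_records("a", 0, 1), "positive")
  expect_error(clinical_records("a", 1, 2), "0/1")
  rec <- clinical_records(c("a", "b"), c(1, 2), c(0, 1), sex = c("m", "f"))
  expect_s3_class(rec$sex, "factor")
  expect_equal(levels(rec$sex), c("f", "m"))
})
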
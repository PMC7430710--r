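test_that("Clopper-Pearson interval matches the study incidence and
           handles boundaries", {
  ci <- clopper_pearson(14, 43)
  expect_equal(round(ci$point, 3), 0.326)
  expect_equal(round(ci$lower, 3), 0.191)
  expect_equal(round(ci$upper, 3), 0.485)
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  expect_error(clopper_pearson(11, 10), "require")
  expect_error(clopper_pearson(5, 10, level = 1), "require")
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(71)
  for (p in c(0.1, 0.33, 0.5)) {
    n_rep <- 2000
    x <- stats::rbinom(n_rep, 30, p)
    covered <- vapply(x, function(xi) {
      ci <- clopper_pearson(xi, 30)
      ci$lower <= p && p <= ci$upper
    }, logical(1))
    se <- sqrt(0.95 * 0.05 / n_rep)
    expect_gt(mean(covered), 0.95 - 3 * se)
  }
})

test_that("univariate logistic OR equals the 2x2 cross-product", {
  # exposure MFC vs referent NC; events 3/7 exposed, 4/17 referent
  y <- c(rep(1, 3), rep(0, 4), rep(1, 7), rep(0, 17))
  x <- data.frame(mfc = c(rep(1, 7), rep(0, 24)))
  fit <- fit_logistic(y, x)
  expect_equal(fit$terms$OR[2], (3 * 17) / (7 * 4), tolerance = 1e-6)
  expect_equal(round(fit$terms$OR[2], 2), 1.82)
})

test_that("saturated categorical fit reproduces cell log-odds exactly", {
  cells <- expand.grid(a = 0:1, b = 0:1)
  events <- c(3, 5, 2, 7); totals <- c(10, 12, 9, 14)
  y <- unlist(mapply(function(e, t) c(rep(1, e), rep(0, t - e)),
                     events, totals))
  X <- data.frame(
    a = rep(cells$a, totals), b = rep(cells$b, totals),
    ab = rep(cells$a * cells$b, totals)
  )
  fit <- fit_logistic(y, X)
  beta <- stats::coef(fit$glm)
  for (i in 1:4) {
    eta <- beta[1] + beta[2] * cells$a[i] + beta[3] * cells$b[i] +
      beta[4] * cells$a[i] * cells$b[i]
    expect_equal(unname(eta), log(events[i] / (totals[i] - events[i])),
                 tolerance = 1e-6)
  }
  expect_gte(fit$summary$LR_chi2, 0)
})

test_that("model summary identities hold: AIC, BIC, deviances, pseudo-R2", {
  st <- simulate_study(simulation_config(seed = 37))
  calls <- classify_pairs(st$genotypes, st$pairs)
  fit <- fit_rfm_logistic(calls)
  s <- fit$summary
  expect_equal(s$AIC - s$deviance_model, 2 * s$k)
  expect_equal(s$BIC - s$deviance_model, s$k * log(s$n))
  expect_equal(s$LR_chi2, s$deviance_null - s$deviance_model)
  expect_gte(s$LR_chi2, 0)
  expect_equal(s$df_residual, s$n - s$k)
  expect_true(all(fit$terms$OR > 0))
  expect_true(all(fit$terms$ci_lower <= fit$terms$OR &
                    fit$terms$OR <= fit$terms$ci_upper))
  # intercept-only deviance for 14/43 events has a closed form
  y14 <- c(rep(1, 14), rep(0, 29))
  f0 <- fit_logistic(y14, data.frame(x = c(rep(0:1, 21), 0)))
  expect_equal(f0$summary$deviance_null,
               -2 * (14 * log(14 / 43) + 29 * log(29 / 43)),
               tolerance = 1e-8)
})

test_that("pseudo-R2 arithmetic from reported deviances", {
  r2 <- pseudo_r2_from_deviances(52.70, 50.84, 43)
  expect_equal(round(r2$cox_snell, 2), 0.04)
  expect_equal(round(r2$LR_chi2, 2), 1.86)
  expect_equal(round(r2$mcfadden, 2), 0.04)
  expect_equal(round(r2$nagelkerke, 2), 0.06)
})

test_that("degenerate designs are rejected with explicit errors", {
  expect_error(fit_logistic(rep(0, 20), data.frame(x = rnorm(20))),
               "degenerate outcome")
  y <- rep(c(0, 1), each = 10)
  expect_error(fit_logistic(y, data.frame(x = y)), "separation")
  X <- data.frame(a = rep(0:1, 10), b = rep(0:1, 10) * 2)
  expect_error(fit_logistic(y[sample(20)], X), "collinear")
})

test_that("logistic fit recovers simulated compatibility effects", {
  cfg <- simulation_config(
    n_pairs = 5000,
    rfm_model = list(beta0 = -1.0, beta_mcfc_I = 0.4, beta_mfc_I = 0.9,
                     beta_mcfc_II = 0.2, beta_mfc_II = -0.5),
    seed = 43)
  st <- simulate_study(cfg)
  # fit on the true categories so only estimation error is in play
  calls <- do.call(rbind, lapply(c("I", "II"), function(cl) {
    data.frame(mare_id = st$truth$categories$mare_id,
               foal_id = st$truth$categories$foal_id,
               rfm = st$pairs$rfm, mhc_class = cl,
               category = st$truth$categories[[paste0("cat_", cl)]],
               loci_used = 9L, stringsAsFactors = FALSE)
  }))
  fit <- fit_rfm_logistic(calls)
  truth <- c(-1.0, 0.4, 0.9, 0.2, -0.5)
  for (i in seq_along(truth)) {
    expect_lt(abs(fit$terms$estimate[i] - truth[i]), 3 * fit$terms$se[i])
  }
})

test_that("pooled t-test matches stats::t.test and handles zero variance", {
  a <- c(1.2, 1.9, 2.4, 3.1); b <- c(0.8, 1.1, 2.2)
  got <- students_t_test(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  same <- students_t_test(c(1, 1), c(1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  apart <- students_t_test(c(2, 2), c(1, 1))
  expect_true(is.infinite(apart$t))
  expect_equal(students_t_test(c(0, 0, 1, 1), c(0, 0, 1, 1))$t, 0)
})

test_that("t-test holds its type-I error for equal-mean normal groups", {
  set.seed(83)
  n_rep <- 1000
  rej <- sum(vapply(seq_len(n_rep), function(r) {
    students_t_test(stats::rnorm(12), stats::rnorm(15))$p <= 0.05
  }, logical(1)))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej / n_rep - 0.05), 3 * se)
})

test_that("Mann-Whitney U is min(U_a, U_b) with exact small-sample p
           matching full enumeration", {
  # symmetry: mirror-image rank patterns give U = n^2 / 2
  res <- mann_whitney_u(c(1, 4, 5, 8), c(2, 3, 6, 7))
  expect_equal(res$U, 8)  # U_a = U_b = 16 / 2
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  set.seed(97)
  for (rep in 1:5) {
    a <- sample(100, 5); b <- sample(100, 5) + 0.5  # no ties
    got <- mann_whitney_u(a, b, mode = "exact")
    expect_equal(got$p, oracle_mw_exact(a, b), tolerance = 1e-10)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
  # ties force the corrected normal approximation
  tied <- mann_whitney_u(c(1, 1, 2, 3), c(1, 2, 2, 4))
  expect_equal(tied$method, "normal_approx")
  expect_true(tied$p > 0 && tied$p <= 1)
})
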
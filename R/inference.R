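#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from Beta quantiles: lower bound is the
#' \eqn{\alpha/2} quantile of Beta(x, n - x + 1) (0 when x = 0), upper the
#' \eqn{1 - \alpha/2} quantile of Beta(x + 1, n - x) (1 when x = n).
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @return List with `x`, `n`, `point`, `lower`, `upper`, `level`.
#' @export
#' @examples
#' clopper_pearson(14, 43)  # incidence 0.326 (0.191-0.485)
clopper_pearson <- function(x, n, level = 0.95) {
  if (n < 1 || x < 0 || x > n || level <= 0 || level >= 1) {
    stop("require 0 <= x <= n, n >= 1, 0 < level < 1", call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  list(x = x, n = n, point = x / n, lower = lower, upper = upper,
       level = level)
}

#' Logistic regression of RFM on MHC compatibility
#'
#' Fits, by binomial maximum likelihood, the model used to test whether
#' compatibility predicts retained fetal membranes: an intercept plus, for
#' each MHC class, two indicators — one-way compatibility ("MC + FC",
#' collapsing mare- and foal-compatible) and mutual compatibility ("MFC") —
#' with the incompatible category (NC) as the referent. Reports per-term
#' log-odds estimates, Wald SEs, odds ratios with 95% Wald CIs and p-values,
#' and the usual model summary: null and residual deviance, AIC, BIC,
#' likelihood-ratio chi-square, and McFadden, Cox-Snell, Nagelkerke and Tjur
#' pseudo-R-squared values.
#'
#' @param calls Output of [classify_pairs()] (both MHC classes per pair).
#' @param level Confidence level for the Wald CIs.
#' @return A `logistic_rfm_fit`: list with `terms` (data.frame; a term
#'   whose category is unobserved in the data is kept with `NA` estimates),
#'   `summary` (list), `dropped` (inestimable term labels) and the
#'   underlying `glm` fit.
#' @export
fit_rfm_logistic <- function(calls, level = 0.95) {
  wide <- build_design(calls)
  fit_logistic(wide$rfm, wide[, c("mcfc_I", "mfc_I", "mcfc_II", "mfc_II")],
               level = level,
               labels = c("MHC I MC + FC", "MHC I MFC",
                          "MHC II MC + FC", "MHC II MFC"),
               on_rank_deficiency = "drop")
}

build_design <- function(calls) {
  ids <- unique(calls[, c("mare_id", "foal_id", "rfm")])
  for (cl in c("I", "II")) {
    sub <- calls[calls$mhc_class == cl, ]
    cat <- sub$category[match(paste(ids$mare_id, ids$foal_id),
                              paste(sub$mare_id, sub$foal_id))]
    if (any(is.na(cat))) {
      stop("pair without an MHC ", cl, " classification", call. = FALSE)
    }
    ids[[paste0("mcfc_", cl)]] <- as.integer(cat %in% c("MC", "FC"))
    ids[[paste0("mfc_", cl)]] <- as.integer(cat == "MFC")
  }
  ids
}

#' Logistic fit with pseudo-R-squared summaries
#'
#' Lower-level worker behind [fit_rfm_logistic()]: fits
#' `y ~ 1 + X` by iteratively reweighted least squares (via [stats::glm()])
#' and computes the derived summaries. Pseudo-R-squared definitions:
#' McFadden \eqn{1 - \ell_1/\ell_0}; Cox-Snell
#' \eqn{1 - \exp(-\chi^2_{LR}/n)}; Nagelkerke = Cox-Snell rescaled by its
#' maximum \eqn{1 - \exp(2\ell_0/n)}; Tjur = difference in mean fitted
#' probability between outcome groups.
#'
#' @param y Logical or 0/1 outcome vector.
#' @param X Data.frame or matrix of numeric predictors.
#' @param level Confidence level for Wald CIs.
#' @param labels Optional term labels (excluding the intercept).
#' @param on_rank_deficiency `"error"` rejects a collinear design;
#'   `"drop"` removes aliased columns and reports them with `NA` estimates
#'   (small categorical designs go rank-deficient whenever a referent
#'   category is empty, e.g. no NC pair in one MHC class).
#' @return A `logistic_rfm_fit` list.
#' @export
fit_logistic <- function(y, X, level = 0.95, labels = NULL,
                         on_rank_deficiency = c("error", "drop")) {
  on_rank_deficiency <- match.arg(on_rank_deficiency)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: all observations in one class", call. = FALSE)
  }
  X <- as.data.frame(X)
  if (is.null(labels)) labels <- names(X)
  # a term whose indicator never varies (e.g. an unobserved compatibility
  # category) cannot be estimated; drop it and report it as inestimable
  constant <- vapply(X, function(v) stats::var(v) == 0, logical(1))
  # aliased terms: greedy scan keeping columns that raise the design rank
  kept_mat <- matrix(1, length(y), 1)
  for (j in seq_along(X)) {
    if (constant[j]) next
    cand <- cbind(kept_mat, X[[j]])
    if (qr(cand)$rank == ncol(cand)) {
      kept_mat <- cand
    } else {
      constant[j] <- TRUE  # aliased: treat like an inestimable term
      if (on_rank_deficiency == "error") {
        stop("collinear design: term '", labels[j],
             "' is aliased with earlier columns", call. = FALSE)
      }
    }
  }
  dropped <- labels[constant]
  X_fit <- X[, !constant, drop = FALSE]
  df <- cbind(data.frame(.y = y), X_fit)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  mu <- stats::fitted(fit)
  # complete separation: the model predicts the outcome perfectly and the
  # likelihood has no maximum
  if (all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6)) {
    stop("separation detected: the design predicts the outcome perfectly",
         call. = FALSE)
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # quasi-separation of single terms (a pure design cell): the estimate
  # drifts to +/-infinity with an exploding SE; keep the row but flag it
  qsep <- abs(est) > 10 | se > 50
  if (any(qsep)) {
    warning("quasi-separation: diverging estimate(s) for ",
            paste(c("Intercept", labels[!constant])[qsep], collapse = ", "),
            call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  terms <- data.frame(
    term = c("Intercept", labels[!constant]),
    estimate = as.numeric(est), se = as.numeric(se),
    OR = exp(as.numeric(est)),
    ci_lower = exp(est - z * se), ci_upper = exp(est + z * se),
    p = 2 * stats::pnorm(-abs(est / se)),
    separated = unname(qsep),
    stringsAsFactors = FALSE
  )
  if (length(dropped)) {
    terms <- rbind(terms, data.frame(
      term = dropped, estimate = NA_real_, se = NA_real_, OR = NA_real_,
      ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
      separated = NA, stringsAsFactors = FALSE))
    terms <- terms[match(c("Intercept", labels), terms$term), ]
  }
  rownames(terms) <- NULL
  n <- length(y)
  k <- length(est)
  ll1 <- as.numeric(stats::logLik(fit))
  dev1 <- fit$deviance
  dev0 <- fit$null.deviance
  ll0 <- -dev0 / 2
  lr <- dev0 - dev1
  cox_snell <- 1 - exp(-lr / n)
  summ <- list(
    n = n, k = k,
    deviance_null = dev0, deviance_model = dev1,
    df_null = n - 1, df_residual = n - k,
    AIC = dev1 + 2 * k, BIC = dev1 + k * log(n),
    LR_chi2 = lr, LR_df = k - 1,
    LR_p = stats::pchisq(lr, df = k - 1, lower.tail = FALSE),
    mcfadden = 1 - ll1 / ll0,
    cox_snell = cox_snell,
    nagelkerke = cox_snell / (1 - exp(2 * ll0 / n)),
    tjur = mean(mu[y == 1]) - mean(mu[y == 0])
  )
  structure(list(terms = terms, summary = summ, dropped = dropped,
                 glm = fit),
            class = "logistic_rfm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.logistic_rfm_fit <- function(x, ...) {
  cat("Logistic regression (binomial ML), n =", x$summary$n, "\n")
  t <- x$terms
  num <- vapply(t, is.numeric, logical(1))
  t[num] <- lapply(t[num], round, digits = 3)
  print(t, row.names = FALSE)
  with(x$summary, cat(sprintf(
    "deviance %0.2f (null %0.2f), AIC %0.2f, BIC %0.2f, LR X2 %0.2f (p = %0.3f)\nMcFadden %0.3f  Cox-Snell %0.3f  Nagelkerke %0.3f  Tjur %0.3f\n",
    deviance_model, deviance_null, AIC, BIC, LR_chi2, LR_p,
    mcfadden, cox_snell, nagelkerke, tjur)))
  invisible(x)
}

#' Pseudo-R-squared values from deviances
#'
#' Computes McFadden, Cox-Snell and Nagelkerke R-squared directly from a
#' null and a model deviance and the sample size, e.g. to audit values
#' printed in a publication table.
#'
#' @param deviance_null,deviance_model Deviances (\eqn{-2 \ell}).
#' @param n Sample size.
#' @return List with `LR_chi2`, `mcfadden`, `cox_snell`, `nagelkerke`.
#' @export
pseudo_r2_from_deviances <- function(deviance_null, deviance_model, n) {
  lr <- deviance_null - deviance_model
  cs <- 1 - exp(-lr / n)
  list(LR_chi2 = lr,
       mcfadden = 1 - deviance_model / deviance_null,
       cox_snell = cs,
       nagelkerke = cs / (1 - exp(-deviance_null / n)))
}

#' Two-sided pooled-variance Student's t-test
#'
#' Wrapper around [stats::t.test()] with `var.equal = TRUE` that handles the
#' degenerate zero-variance cases explicitly: equal means give t = 0, p = 1;
#' unequal means with zero pooled variance give an infinite t flagged by
#' `degenerate = TRUE`.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
students_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs >= 2 values", call. = FALSE)
  }
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0,
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}

#' Two-sided Mann-Whitney U test
#'
#' Reports \eqn{U = \min(U_a, U_b)} with the p-value from
#' [stats::wilcox.test()]: exact by enumeration when
#' \eqn{n_a n_b \le 400} and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric samples.
#' @param mode `"auto"` applies the rule above; `"exact"` or
#'   `"normal_approx"` force a method (exact is refused with ties).
#' @return List with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  if (stats::var(c(a, b)) == 0) {
    # every observation tied: no evidence either way
    return(list(U = length(a) * length(b) / 2, p = 1,
                method = "degenerate"))
  }
  ties <- any(duplicated(c(a, b)))
  exact <- switch(mode,
    auto = !ties && length(a) * length(b) <= 400,
    exact = if (ties) stop("exact mode unavailable with ties",
                           call. = FALSE) else TRUE,
    normal_approx = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  u_a <- unname(wt$statistic)            # wilcox.test W = U of sample a
  u_b <- length(a) * length(b) - u_a
  list(U = min(u_a, u_b), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}
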
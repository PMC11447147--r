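# Regression stages: linear endophenotype models in female AD patients with
# CSF biomarkers, and the logistic disease-risk model including the
# same-birthplace consanguinity proxy. Linear models are ordinary least
# squares via stats::lm; the logistic model is fit by our own IRLS so its
# convergence behaviour (monotone deviance, gradient tolerance) is part of
# the contract and testable against stats::glm.

.csf_outcomes <- c(age_of_onset = "age_of_onset", csf_abeta42 = "csf_abeta42",
                   csf_ttau = "csf_ttau", csf_ptau = "csf_ptau")

# Regression covariate frame. Both-parents-affected subjects are RETAINED
# here with both indicators set to 1 (the univariate both-affected exclusion
# applies only to the dyad tables).
.model_frame <- function(cohort) {
  data.frame(
    status = as.integer(cohort$status == "case"),
    female = as.integer(cohort$sex == "female"),
    paternal = as.integer(cohort$paternal_history == "yes"),
    maternal = as.integer(cohort$maternal_history == "yes"),
    same_town = {
      st <- same_town_flag(cohort$father_birthplace, cohort$mother_birthplace)
      ifelse(st == "unknown", NA_integer_, as.integer(st == "same"))
    },
    apoe_e4 = ifelse(is.na(cohort$apoe), NA_integer_,
                     as.integer(grepl("e4", cohort$apoe))),
    age_of_onset = cohort$age_of_onset,
    age_at_assessment = cohort$age_at_assessment,
    age_at_lp = cohort$age_at_lp,
    education = cohort$education,
    year_of_birth = cohort$year_of_birth,
    csf_abeta42 = cohort$csf_abeta42,
    csf_ttau = cohort$csf_ttau,
    csf_ptau = cohort$csf_ptau)
}

#' Endophenotype linear models in female AD patients with CSF biomarkers
#'
#' Four ordinary-least-squares models on the subset of female cases with all
#' CSF measures present, one per outcome: age of onset, CSF amyloid-beta 42,
#' CSF total tau and CSF phosphorylated tau. Each model adjusts for paternal
#' and maternal dementia history, the same-birthplace flag, age at lumbar
#' puncture, education, age of onset (except when it is the outcome), APOE
#' e4 carriership, the other CSF markers (mutual adjustment) and year of
#' birth — ten predictors per model. Complete-case per model, with the
#' per-model n reported.
#'
#' @param cohort A `cohort` object.
#' @param genotype_apoe Use the full 6-level genotype instead of the binary
#'   e4-carrier indicator.
#' @return Named list of four `regression_fit` objects.
#' @export
fit_endophenotype_models <- function(cohort, genotype_apoe = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  sub <- cohort[cohort$sex == "female" & cohort$status == "case" &
                  !is.na(cohort$csf_abeta42) & !is.na(cohort$csf_ttau) &
                  !is.na(cohort$csf_ptau) & !is.na(cohort$age_at_lp), ,
                drop = FALSE]
  mf <- .model_frame(sub)
  if (genotype_apoe) mf$apoe_e4 <- factor(sub$apoe)
  fits <- lapply(names(.csf_outcomes), function(outcome) {
    preds <- c("paternal", "maternal", "same_town", "age_at_lp", "education",
               "apoe_e4",
               setdiff(c("age_of_onset", "csf_abeta42", "csf_ttau",
                         "csf_ptau"), outcome),
               "year_of_birth")
    .fit_linear(mf, outcome, preds)
  })
  names(fits) <- names(.csf_outcomes)
  fits
}

.fit_linear <- function(mf, outcome, predictors) {
  dat <- mf[, c(outcome, predictors)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  p_terms <- length(predictors)
  if (n <= p_terms + 1) {
    stop("subset too small for '", outcome, "': n = ", n, ", need > ",
         p_terms + 1, call. = FALSE)
  }
  form <- stats::as.formula(paste(outcome, "~",
                                  paste(predictors, collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  if (fit$rank < length(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model for '", outcome, "'; collinear term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit)
  terms <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    se = sm$coefficients[, 2],
    ci_lo = ci[, 1], ci_hi = ci[, 2],
    p = sm$coefficients[, 4],
    row.names = NULL, stringsAsFactors = FALSE)
  fstat <- sm$fstatistic
  structure(list(family = "linear", outcome = outcome, terms = terms, n = n,
                 stats = list(r_squared = sm$r.squared,
                              f = unname(fstat[1]),
                              df_model = unname(fstat[2]),
                              df_residual = unname(fstat[3]),
                              sigma = sm$sigma),
                 lm_fit = fit),
            class = "regression_fit")
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Newton/IRLS maximum likelihood for a binary outcome, iterating until the
#' score (gradient) max-norm falls below `tol`. The per-iteration deviance
#' trace is returned; it is non-increasing. Perfect separation is detected
#' (diverging coefficients / fitted probabilities at the boundary) and raised
#' as an error rather than reported with meaningless Wald statistics.
#'
#' @param X Numeric design matrix (including the intercept column).
#' @param y 0/1 response vector.
#' @param tol Convergence tolerance on the score max-norm.
#' @param max_iter Iteration cap.
#' @return List with `coefficients`, `vcov`, `deviance`, `null_deviance`,
#'   `deviance_trace`, `log_lik`, `n`, `iterations`, `converged`.
#' @export
logistic_irls <- function(X, y, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design matrix in logistic fit", call. = FALSE)
  }
  n <- length(y)
  beta <- numeric(ncol(X))
  dev_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    dev_trace <- c(dev_trace, -2 * sum(y * log(mu) + (1 - y) * log1p(-mu)))
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    w <- mu * (1 - mu)
    if (any(abs(beta) > 30) || all(w < 1e-10)) {
      stop("perfect separation detected: coefficients diverging; ",
           "Wald statistics are not reported", call. = FALSE)
    }
    xtwx <- crossprod(X * w, X)
    beta <- beta + solve(xtwx, score)
  }
  if (!converged) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    if (any(abs(beta) > 30)) {
      stop("perfect separation detected: coefficients diverging; ",
           "Wald statistics are not reported", call. = FALSE)
    }
    warning("IRLS did not reach tolerance ", tol, " in ", max_iter,
            " iterations")
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  vcov <- solve(crossprod(X * w, X))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  p_bar <- mean(y)
  null_dev <- -2 * (sum(y) * log(p_bar) + (n - sum(y)) * log(1 - p_bar))
  list(coefficients = beta, vcov = vcov,
       deviance = dev_trace[length(dev_trace)], null_deviance = null_dev,
       deviance_trace = dev_trace,
       log_lik = -dev_trace[length(dev_trace)] / 2, n = n,
       iterations = length(dev_trace), converged = converged)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R2 rescaled by its maximum attainable value so the index spans
#' `[0, 1]`.
#'
#' @param deviance,null_deviance Model and intercept-only deviances.
#' @param n Number of observations.
#' @return Numeric scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(deviance, null_deviance, n) {
  r2_cs <- 1 - exp((deviance - null_deviance) / n)
  r2_max <- 1 - exp(-null_deviance / n)
  max(0, min(1, r2_cs / r2_max))
}

#' Logistic model for AD risk
#'
#' Maximum-likelihood logistic regression of case status on sex (female = 1),
#' age, education, APOE e4 carriership and the same-birthplace flag,
#' complete-case. Because controls have no disease onset, the age variable is
#' age of onset for cases and age at assessment for controls (a documented
#' modelling assumption). Reports per-term odds ratios with Wald 95% CIs and
#' p-values, -2 log-likelihood and Nagelkerke R-squared.
#'
#' @param cohort A `cohort` object.
#' @param tol,max_iter Passed to [logistic_irls()].
#' @return A `regression_fit`.
#' @export
fit_ad_logistic <- function(cohort, tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(cohort, "cohort"))
  mf <- .model_frame(cohort)
  mf$age <- ifelse(cohort$status == "case", cohort$age_of_onset,
                   cohort$age_at_assessment)
  dat <- mf[, c("status", "female", "age", "education", "apoe_e4",
                "same_town")]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$status)) < 2) {
    stop("outcome has a single class after complete-case filtering",
         call. = FALSE)
  }
  X <- cbind("(Intercept)" = 1, female = dat$female, age = dat$age,
             education = dat$education, apoe_e4 = dat$apoe_e4,
             same_town = dat$same_town)
  fit <- logistic_irls(X, dat$status, tol = tol, max_iter = max_iter)
  se <- sqrt(diag(fit$vcov))
  z <- fit$coefficients / se
  ci_lo <- fit$coefficients - stats::qnorm(0.975) * se
  ci_hi <- fit$coefficients + stats::qnorm(0.975) * se
  terms <- data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients), se = unname(se),
    or = exp(unname(fit$coefficients)),
    or_lo = exp(unname(ci_lo)), or_hi = exp(unname(ci_hi)),
    p = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE)
  structure(list(family = "logistic", outcome = "status", terms = terms,
                 n = fit$n,
                 stats = list(
                   minus2_loglik = fit$deviance,
                   null_deviance = fit$null_deviance,
                   nagelkerke_r2 = nagelkerke_r2(fit$deviance,
                                                 fit$null_deviance, fit$n),
                   chi_squared = fit$null_deviance - fit$deviance,
                   iterations = fit$iterations),
                 irls_fit = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<regression_fit> %s model for %s (n = %d)\n", x$family,
              x$outcome, x$n))
  tt <- x$terms
  num <- vapply(tt, is.numeric, TRUE)
  tt[num] <- lapply(tt[num], function(v) signif(v, digits))
  print(tt, row.names = FALSE)
  if (x$family == "linear") {
    cat(sprintf("F(%d, %d) = %.3f, R2 = %.3f\n", x$stats$df_model,
                x$stats$df_residual, x$stats$f, x$stats$r_squared))
  } else {
    cat(sprintf("-2LL = %.3f, Nagelkerke R2 = %.3f\n",
                x$stats$minus2_loglik, x$stats$nagelkerke_r2))
  }
  invisible(x)
}
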
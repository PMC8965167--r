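#' Adjusted logistic regression with robust variance
#'
#' Fits the adjusted logistic models used throughout: a binary outcome on
#' ALE class indicators (reference class 1) plus sex, age, a quadratic age
#' term, smoking (reference never) and education (reference low), optionally
#' with a log follow-up offset (coefficient fixed at 1) for hospitalization
#' outcomes. Estimation is maximum likelihood via iteratively reweighted
#' least squares; inference uses an HC0 sandwich (robust) covariance by
#' default, with the model-based covariance retained alongside.
#'
#' Fits that fail to converge, are rank deficient, or show signs of
#' separation raise an error rather than returning unstable estimates.
#'
#' @param formula Model formula, e.g.
#'   `hosp ~ ale_class + age + I(age^2) + sex + education + smoking`.
#' @param data Data frame (see [prepare_cohort()] for the expected factor
#'   coding).
#' @param offset Optional numeric vector added to the linear predictor with
#'   coefficient 1 — for hospitalization models, `log(followup_years)`.
#' @param robust Use the sandwich covariance for inference (default TRUE).
#' @param tol,max_iter IRLS convergence tolerance and iteration cap.
#' @return Object of class `ale_logit`: `coefficients`, `vcov_model`,
#'   `vcov_robust`, `n_used`, `converged`, `log_likelihood`, the underlying
#'   `glm`, and the model data/offset for marginal prediction.
#' @seealso [odds_ratio_table()], [marginal_predictions()]
#' @export
ale_logit <- function(formula, data, offset = NULL, robust = TRUE,
                      tol = 1e-8, max_iter = 50) {
  data <- as.data.frame(data)
  if (!is.null(offset)) {
    if (length(offset) != nrow(data) || any(!is.finite(offset)))
      stop("invalid offset: must be finite, one value per row")
    data$.alehosp_offset <- offset
    formula <- stats::update(formula, . ~ . + offset(.alehosp_offset))
  }
  fit <- stats::glm(formula, family = stats::binomial(), data = data,
                    control = stats::glm.control(epsilon = tol,
                                                 maxit = max_iter))
  if (!fit$converged)
    stop("non-convergence: IRLS did not converge in ", max_iter,
         " iterations")
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("design error: rank-deficient design (collinear columns: ",
         paste(names(beta)[is.na(beta)], collapse = ", "), ")")
  if (any(abs(beta) > 15))
    stop("non-convergence: diverging coefficient(s) suggest separation: ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "))
  structure(list(coefficients = beta,
                 vcov_model = stats::vcov(fit),
                 vcov_robust = sandwich::vcovHC(fit, type = "HC0"),
                 robust = robust,
                 n_used = stats::nobs(fit),
                 converged = TRUE,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 glm = fit,
                 formula = formula,
                 data = fit$model,
                 offset_values = if (is.null(fit$offset)) rep(0, stats::nobs(fit))
                                 else fit$offset),
            class = "ale_logit")
}

#' @export
coef.ale_logit <- function(object, ...) object$coefficients

#' Covariance matrix of an `ale_logit` fit
#'
#' @param object An [ale_logit()] fit.
#' @param robust Sandwich (default: the fit's `robust` setting) or
#'   model-based covariance.
#' @param ... Unused.
#' @export
vcov.ale_logit <- function(object, robust = object$robust, ...) {
  if (robust) object$vcov_robust else object$vcov_model
}

#' @export
logLik.ale_logit <- function(object, ...) {
  stats::logLik(object$glm)
}

#' @export
predict.ale_logit <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(stats::predict(object$glm, type = type))
  if (!is.null(object$glm$offset) &&
      is.null(newdata$.alehosp_offset))
    newdata$.alehosp_offset <- 0
  stats::predict(object$glm, newdata = newdata, type = type)
}

#' @export
residuals.ale_logit <- function(object,
                                type = c("deviance", "pearson",
                                         "response"), ...) {
  stats::residuals(object$glm, type = match.arg(type))
}

#' Simulate outcomes from a fitted model
#'
#' Parametric simulation: Bernoulli draws at the fitted probabilities
#' (observed covariates and offsets), one column per replicate.
#'
#' @param object An [ale_logit()] fit.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @export
simulate.ale_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::fitted(object$glm)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.ale_logit <- function(x, ...) {
  cat("Logistic model (", if (x$robust) "robust" else "model-based",
      " variance), n = ", x$n_used, "\n", sep = "")
  print(odds_ratio_table(x))
  invisible(x)
}

#' @export
summary.ale_logit <- function(object, ...) {
  v <- vcov(object)
  se <- sqrt(diag(v))
  z <- object$coefficients / se
  out <- data.frame(term = names(object$coefficients),
                    estimate = unname(object$coefficients),
                    se = unname(se), z = unname(z),
                    p = unname(2 * stats::pnorm(-abs(z))))
  structure(list(table = out, n_used = object$n_used,
                 robust = object$robust,
                 log_likelihood = object$log_likelihood),
            class = "summary.ale_logit")
}

#' @export
print.summary.ale_logit <- function(x, ...) {
  cat("n =", x$n_used, "; log-likelihood =",
      format(x$log_likelihood, digits = 6), ";",
      if (x$robust) "robust (HC0)" else "model-based", "SEs\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Odds ratios with confidence intervals
#'
#' `OR = exp(beta)`, `CI = exp(beta +/- z * SE)` with the normal quantile
#' (1.959964 for 95%), using the fit's chosen (robust or model-based)
#' standard errors.
#'
#' @param fit An [ale_logit()] fit.
#' @param level Confidence level.
#' @return Data frame `term`, `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_table <- function(fit, level = 0.95) {
  se <- sqrt(diag(vcov(fit)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  data.frame(term = names(b), or = exp(unname(b)),
             ci_low = exp(unname(b - z * se)),
             ci_high = exp(unname(b + z * se)))
}

#' Average adjusted predictions with delta-method intervals
#'
#' For each exposure level `c`, sets every observation's exposure to `c`
#' (covariates and offsets as observed), averages the predicted
#' probabilities, and propagates the coefficient covariance to the average
#' by the delta method: with counterfactual design `X_c` and fitted
#' probabilities `p_i`, the gradient is `g = mean_i p_i (1 - p_i) x_i` and
#' `Var = g' V g` with `V` the fit's (robust) covariance. 95% intervals use
#' the normal quantile.
#'
#' @param fit An [ale_logit()] fit.
#' @param exposure Name of the exposure factor in the model (default
#'   `"ale_class"`).
#' @param levels Exposure levels to predict at (default: all factor levels
#'   present in the model data).
#' @param data Data frame over which to average (default: the model frame).
#' @param level Confidence level.
#' @return Data frame of class `ale_margins`: `level` (exposure class),
#'   `predicted`, `se`, `ci_low`, `ci_high`.
#' @export
marginal_predictions <- function(fit, exposure = "ale_class", levels = NULL,
                                 data = NULL, level = 0.95) {
  if (is.null(data)) data <- fit$data
  tt <- stats::delete.response(stats::terms(fit$glm))
  # an exposure absent from the model (e.g. intercept-only fit) leaves the
  # counterfactual design unchanged: every level predicts the same average
  has_exposure <- exposure %in% all.vars(tt) && !is.null(data[[exposure]])
  if (has_exposure) {
    lv_all <- levels(factor(data[[exposure]]))
    if (is.null(levels)) levels <- lv_all
    if (!all(as.character(levels) %in% lv_all))
      stop("config error: exposure level(s) ",
           paste(setdiff(as.character(levels), lv_all), collapse = ", "),
           " absent from the design coding")
  } else if (is.null(levels)) levels <- "(all)"
  beta <- fit$coefficients
  V <- vcov(fit)
  off <- fit$offset_values
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(levels, function(lv) {
    d2 <- data
    if (has_exposure)
      d2[[exposure]] <- factor(lv, levels = levels(factor(data[[exposure]])))
    X <- stats::model.matrix(tt, d2, xlev = fit$glm$xlevels)
    eta <- drop(X %*% beta) + off
    p <- stats::plogis(eta)
    g <- colMeans(p * (1 - p) * X)
    se <- sqrt(drop(t(g) %*% V %*% g))
    data.frame(level = lv, predicted = mean(p), se = se,
               ci_low = mean(p) - z * se, ci_high = mean(p) + z * se)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ale_margins", "data.frame")
  out
}

#' @export
print.ale_margins <- function(x, ...) {
  cat("Average adjusted predicted probabilities (delta-method CIs)\n")
  d <- data.frame(level = x$level,
                  predicted = sprintf("%.2f (%.2f, %.2f)", x$predicted,
                                      x$ci_low, x$ci_high))
  print(d, row.names = FALSE)
  invisible(x)
}
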
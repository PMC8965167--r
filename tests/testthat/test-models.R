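test_that("saturated 2x2 fit equals the closed-form cross-product ratio", {
  # exposure x outcome counts (a, b, c, d) = (10, 40, 20, 30)
  d <- data.frame(x = rep(c(1, 1, 0, 0), c(10, 40, 20, 30)),
                  y = rep(c(1, 0, 1, 0), c(10, 40, 20, 30)))
  fit <- ale_logit(y ~ x, d)
  expect_equal(unname(coef(fit)["x"]), log((10 * 30) / (40 * 20)),
               tolerance = 1e-8)
  # intercept-only: logit of the prevalence
  fit0 <- ale_logit(y ~ 1, d)
  expect_equal(unname(coef(fit0)), qlogis(mean(d$y)), tolerance = 1e-8)
})

test_that("a zero offset reproduces the no-offset fit exactly", {
  d <- sim_model_cohort(800)
  d$y <- as.integer(d$y)
  f <- y ~ ale_class + age + age_sq + sex + education + smoking
  f1 <- ale_logit(f, d)
  f2 <- ale_logit(f, d, offset = rep(0, nrow(d)))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
})

test_that("IRLS matches direct likelihood maximization", {
  d <- sim_model_cohort(300)
  X <- model.matrix(~ ale_class + age, d)
  y <- as.integer(d$y)
  nll <- function(b) -sum(y * (X %*% b) - log1p(exp(X %*% b)))
  gr <- function(b) -drop(t(X) %*% (y - plogis(drop(X %*% b))))
  opt <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  fit <- ale_logit(y ~ ale_class + age, d)
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-6)
})

test_that("failure modes raise errors instead of silent estimates", {
  d <- data.frame(y = c(0, 0, 1, 1), x = c(0, 1, 2, 3))
  expect_error(suppressWarnings(ale_logit(y ~ x, d)),
               "separation|non-convergence")
  d2 <- sim_model_cohort(100)
  d2$dup <- d2$age
  expect_error(ale_logit(y ~ age + dup, d2), "rank.deficient")
})

test_that("sandwich variance scales and agrees with hand summation", {
  d <- sim_model_cohort(500)
  fit <- ale_logit(y ~ age + sex, d)
  # hand-computed HC0: bread = (X'WX)^-1, meat = sum (y-p)^2 x x'
  X <- model.matrix(~ age + sex, d)
  p <- plogis(drop(X %*% coef(fit)))
  y <- as.integer(d$y)
  bread <- solve(t(X) %*% (p * (1 - p) * X))
  meat <- t(X) %*% ((y - p)^2 * X)
  expect_equal(unname(vcov(fit, robust = TRUE)),
               unname(bread %*% meat %*% bread), tolerance = 1e-6)

  # duplicating the data halves the robust covariance exactly
  d2 <- rbind(d, d)
  fit2 <- ale_logit(y ~ age + sex, d2)
  expect_equal(unname(vcov(fit2, robust = TRUE)),
               unname(vcov(fit, robust = TRUE)) / 2, tolerance = 1e-6)
})

test_that("robust and model-based SEs agree under correct specification", {
  d <- sim_model_cohort(20000)
  fit <- ale_logit(y ~ ale_class + age + age_sq + sex + education + smoking,
                   d)
  se_r <- sqrt(diag(vcov(fit, robust = TRUE)))
  se_m <- sqrt(diag(vcov(fit, robust = FALSE)))
  expect_true(all(abs(se_r / se_m - 1) < 0.10))
})

test_that("odds-ratio tables exponentiate with normal-quantile intervals", {
  d <- sim_model_cohort(800)
  fit <- ale_logit(y ~ ale_class + age, d)
  tab <- odds_ratio_table(fit)
  se <- sqrt(diag(vcov(fit)))
  expect_equal(tab$or, exp(unname(coef(fit))))
  expect_equal(tab$ci_low, exp(unname(coef(fit) - 1.959964 * se)),
               tolerance = 1e-6)
  expect_true(all(tab$ci_low <= tab$or & tab$or <= tab$ci_high))
})

test_that("intercept-only margins equal the sample prevalence exactly", {
  d <- sim_model_cohort(500)
  fit <- ale_logit(y ~ 1, d)
  m <- marginal_predictions(fit, exposure = "ale_class", levels = 1:5,
                            data = d)
  expect_equal(m$predicted, rep(mean(d$y), 5))
})

test_that("margins averaged over observed exposure give the prevalence", {
  d <- sim_model_cohort(3000)
  fit <- ale_logit(y ~ ale_class + age + sex, d)
  # ML with an intercept balances fitted values exactly
  expect_equal(mean(predict(fit)), mean(d$y), tolerance = 1e-10)
  # class-share-weighted counterfactual margins agree closely
  m <- marginal_predictions(fit)
  w <- table(d$ale_class) / nrow(d)
  expect_equal(sum(m$predicted * as.numeric(w)), mean(d$y),
               tolerance = 1e-3)
  expect_true(all(m$ci_low <= m$predicted & m$predicted <= m$ci_high))
  expect_error(marginal_predictions(fit, levels = "9"), "config error")
})

test_that("delta-method CI width shrinks like one over root n", {
  d <- sim_model_cohort(8000, seed = 3)
  widths <- vapply(c(2000, 8000), function(nn) {
    fit <- ale_logit(y ~ ale_class + age + sex, d[seq_len(nn), ])
    m <- marginal_predictions(fit, levels = "1")
    m$ci_high - m$ci_low
  }, numeric(1))
  expect_gt(widths[1] / widths[2], 1.6)
  expect_lt(widths[1] / widths[2], 2.6)
})
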
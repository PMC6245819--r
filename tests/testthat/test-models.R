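# Univariate screening, stepwise selection, prediction and R^2.

make_features <- function(n, k, seed = 1) {
  set.seed(seed)
  dt <- data.table::as.data.table(
    matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k))))
  dt
}

test_that("univariate screen recovers exact and null relationships", {
  n <- 1000L
  ft <- make_features(n, 3, seed = 21)
  # exact linear relation: standardized beta 1, r2 1
  y <- 2 * ft$x1
  sc <- suppressWarnings(univariate_screen(ft, y, c("x1", "x2")))
  expect_equal(sc$predictor[1], "x1")  # sorted by |t|
  expect_equal(sc[predictor == "x1", beta], 1)
  expect_equal(sc[predictor == "x1", r2], 1)
  # independent outcome: small beta, non-tiny p
  y2 <- rnorm(n)
  sc2 <- univariate_screen(ft, y2, c("x1", "x2", "x3"))
  expect_true(all(abs(sc2$beta) < 0.15))
  # t grows monotonically as noise shrinks
  ts <- vapply(c(1, 0.3, 0.1, 0.03), function(s) {
    set.seed(77)
    yy <- ft$x1 + rnorm(n, sd = s)
    univariate_screen(ft, yy, "x1")$t
  }, numeric(1))
  expect_true(all(diff(ts) > 0))
  expect_warning(univariate_screen(cbind(ft, cst = 1), y2,
                                   c("x1", "cst")), "constant")
})

test_that("stepwise selection recovers true predictors and drops noise", {
  n <- 2000L
  ft <- make_features(n, 10, seed = 31)
  set.seed(32)
  truth <- c(x2 = 3, x5 = -2, x9 = 1.5)
  y <- 1 + as.matrix(ft[, .(x2, x5, x9)]) %*% truth + rnorm(n)
  fit <- stepwise_fit(ft, as.vector(y), names(ft))
  expect_true(all(names(truth) %in% fit$selected_predictors))
  # estimates within 3 standard errors of truth
  for (nm in names(truth)) {
    se <- abs(fit$coefficients[[nm]] / fit$table[predictor == nm, t])
    expect_lt(abs(fit$coefficients[[nm]] - truth[[nm]]), 3 * se)
  }
  expect_gt(fit$r2, 0.9)
  # single strongly-associated candidate equals its univariate fit
  fit1 <- stepwise_fit(ft, as.vector(y), "x2")
  uni <- univariate_screen(ft, as.vector(y), "x2")
  expect_equal(fit1$coefficients[["x2"]],
               lm(as.vector(y) ~ ft$x2)$coefficients[[2]])
  expect_equal(fit1$table$beta, uni$beta)
})

test_that("stepwise on pure noise returns intercept-only in most replicates", {
  n <- 2000L
  hits <- 0L
  for (s in 1:40) {
    ft <- make_features(n, 8, seed = 100 + s)
    set.seed(200 + s)
    y <- rnorm(n)
    fit <- suppressWarnings(
      stepwise_fit(ft, y, names(ft), p_enter = 0.001, p_remove = 0.002))
    if (length(fit$selected_predictors) == 0L) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("stepwise is idempotent and handles aliased candidates", {
  n <- 800L
  ft <- make_features(n, 5, seed = 41)
  set.seed(42)
  y <- 2 * ft$x1 - ft$x3 + rnorm(n, sd = 0.5)
  fit <- stepwise_fit(ft, y, names(ft))
  refit <- stepwise_fit(ft, y, fit$selected_predictors)
  expect_equal(sort(refit$selected_predictors),
               sort(fit$selected_predictors))
  expect_equal(refit$coefficients[sort(names(refit$coefficients))],
               fit$coefficients[sort(names(fit$coefficients))])
  # perfectly collinear copy never yields NA coefficients
  ft[, x1copy := x1]
  fit2 <- stepwise_fit(ft, y, names(ft))
  expect_false(anyNA(fit2$coefficients))
})

test_that("standardized betas are invariant under affine predictor rescaling", {
  n <- 1000L
  ft <- make_features(n, 3, seed = 51)
  set.seed(52)
  y <- ft$x1 + 0.5 * ft$x2 + rnorm(n)
  f1 <- stepwise_fit(ft, y, c("x1", "x2"))
  ft2 <- data.table::copy(ft)
  ft2[, x1 := 1000 * x1 + 7]
  f2 <- stepwise_fit(ft2, y, c("x1", "x2"))
  expect_equal(f1$table[predictor == "x1", beta],
               f2$table[predictor == "x1", beta], tolerance = 1e-10)
})

test_that("predictions follow the linear model and residuals center at zero", {
  n <- 500L
  ft <- make_features(n, 4, seed = 61)
  ft[, gene_id := paste0("g", 1:n)]
  set.seed(62)
  y <- 3 + ft$x1 - 2 * ft$x4 + rnorm(n)
  fit <- stepwise_fit(ft, y, paste0("x", 1:4))
  pred <- predict_expected(fit, ft)
  # matrix-multiply oracle
  X <- cbind(1, as.matrix(ft[, fit$selected_predictors, with = FALSE]))
  oracle <- as.vector(X %*% fit$coefficients[c("(Intercept)",
                                               fit$selected_predictors)])
  expect_equal(unname(pred), oracle)
  expect_lt(abs(sum(y - pred)), 1e-8 * n)
  expect_equal(names(pred), ft$gene_id)
  expect_error(predict_expected(fit, ft[, .(gene_id)]), "lacks predictor")
  # intercept-only model predicts a constant
  fit0 <- suppressWarnings(stepwise_fit(ft, rnorm(n), "x2",
                                        p_enter = 1e-12, p_remove = 1e-11))
  if (length(fit0$selected_predictors) == 0L)
    expect_equal(unname(unique(predict_expected(fit0, ft))),
                 unname(fit0$coefficients[["(Intercept)"]]))
})

test_that("model_r2 matches its definition", {
  obs <- c(1, 3, 5, 7, 11)
  expect_equal(model_r2(obs, obs), 1)
  expect_equal(model_r2(obs, rep(mean(obs), 5)), 0)
  expect_error(model_r2(rep(2, 4), 1:4), "constant")
})

test_that("stepwise coefficient intervals cover truth at about 95%", {
  # strong effects so selection never misses; coverage of the 95% CI built
  # from the reported t statistic should be binomially close to 0.95
  n <- 300L
  truth <- c(x1 = 2, x3 = -1.5)
  trials <- 200L
  covered <- 0L
  for (s in seq_len(trials)) {
    ft <- make_features(n, 4, seed = 3000 + s)
    set.seed(4000 + s)
    y <- 1 + 2 * ft$x1 - 1.5 * ft$x3 + rnorm(n)
    fit <- stepwise_fit(ft, y, names(ft))
    for (nm in names(truth)) {
      est <- fit$coefficients[[nm]]
      se <- abs(est / fit$table[predictor == nm, t])
      if (abs(est - truth[[nm]]) <= qnorm(0.975) * se)
        covered <- covered + 1L
    }
  }
  rate <- covered / (trials * length(truth))
  expect_gt(rate, 0.91)
  expect_lt(rate, 0.99)
})
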
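test_that("growth rates follow the difference and log-difference definitions", {
  expect_equal(unname(absolute_growth_rate(c(10, 16), interval = 3)), 2)
  expect_equal(unname(absolute_growth_rate(rep(7, 9))), rep(0, 8))
  lin <- 5 + 1.7 * (0:8)
  expect_equal(unname(absolute_growth_rate(lin, interval = 1)), rep(1.7, 8))
  expect_equal(names(absolute_growth_rate(1:9, trait = "TTA")),
               paste0("AGRTTA", 2:9))
  expect_equal(names(absolute_growth_rate(1:9, trait = "TPA",
                                          index_origin = 1)),
               paste0("AGRTPA", 1:8))

  expect_equal(unname(relative_growth_rate(c(100, 200), interval = 3)),
               log(2) / 3) # 0.2310 per day
  ex <- 3 * exp(0.21 * seq(0, 24, by = 3))
  expect_equal(unname(relative_growth_rate(ex, interval = 3)), rep(0.21, 8))
  expect_equal(unname(relative_growth_rate(rep(4, 5))), rep(0, 4))
  expect_warning(r <- relative_growth_rate(c(2, 0, 3)), "non-positive")
  expect_true(all(is.na(r)))
  expect_error(absolute_growth_rate(5), "two time points")
})

test_that("MAPE and RMSE reproduce the worked examples", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(11, 10), 10)
  expect_equal(mape(c(9, 11), c(10, 10)), 10)
  expect_error(mape(1, 0), "zero")
  expect_error(mape(1:2, 1:3), "lengths")

  expect_equal(rmse(c(4, 4), c(4, 4)), 0)
  expect_equal(rmse(11, 10), 1)
  expect_equal(rmse(c(13, 10), c(10, 14)), sqrt((9 + 16) / 2))
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  # both are zero iff the vectors coincide
  set.seed(2)
  a <- runif(6, 1, 2); b <- a; b[4] <- b[4] + 1e-6
  expect_gt(mape(b, a), 0)
  expect_gt(rmse(b, a), 0)
  expect_equal(sd_ape(c(9, 11), c(10, 10)), 0) # equal APEs
})

test_that("noiseless logistic data are recovered within 1%", {
  t <- 1:9
  y <- 100 / (1 + 20 * exp(-0.4 * t))
  fit <- fit_growth_model(t, y, "logistic")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(100, 20, 0.4), tolerance = 0.01)
  expect_gte(fit$r_squared, 0.999)
  expect_lt(fit$mape, 0.1)
  expect_equal(predict(fit, newdata = t), fitted(fit))
})

test_that("each family reproduces its own noiseless data", {
  t <- 1:9
  cases <- list(
    linear = list(y = 2 + 3 * t, co = c(2, 3)),
    power = list(y = 1.5 * t^0.7, co = c(1.5, 0.7)),
    exponential = list(y = 2 * exp(0.3 * t), co = c(2, 0.3)),
    logarithmic = list(y = 1 + 4 * log(t), co = c(1, 4)),
    quadratic = list(y = 1 + 2 * t + 0.5 * t^2, co = c(1, 2, 0.5)))
  for (fam in names(cases)) {
    fit <- fit_growth_model(t, cases[[fam]]$y, fam)
    expect_equal(unname(coef(fit)), cases[[fam]]$co, tolerance = 1e-4)
    expect_equal(fit$r_squared, 1, tolerance = 1e-6)
    expect_lt(fit$mape, 1e-3)
  }
  # exactly linear data: R^2 = 1, MAPE = 0
  fl <- fit_growth_model(t, 2 + 3 * t, "linear")
  expect_equal(fl$mape, 0, tolerance = 1e-10)
})

test_that("model ranking selects logistic on logistic-generated data", {
  t <- seq(3, 27, by = 3) # nine time points, days
  y <- 80 / (1 + 15 * exp(-0.35 * t / 3))
  cmp <- compare_growth_models(t, y)
  expect_equal(cmp$family[1], "logistic")
  expect_equal(nrow(cmp), 6)
  expect_true(all(cmp$mape[-1] > cmp$mape[1]))
})

test_that("growth fit validates inputs and degenerate cases", {
  expect_error(fit_growth_model(1:2, c(1, 2), "logistic"), "at least 3")
  expect_error(fit_growth_model(0:4, 1 + (0:4), "power"), "positive time")
  expect_error(fit_growth_model(1:5, c(-1, 1, 2, 3, 4), "exponential"),
               "positive trait")
})

test_that("tiller senescence follows its defining ratio", {
  expect_equal(tiller_senescence(10, 10)$senescence, 0)
  expect_equal(tiller_senescence(10, 8)$senescence, 0.2)
  expect_equal(tiller_senescence(10, 0)$senescence, 1)
  expect_error(tiller_senescence(0, 0), "positive")
  expect_warning(s <- tiller_senescence(5, 7), "negative")
  expect_equal(s$senescence, -0.4)
})

test_that("stepwise regression recovers a planted two-trait model", {
  set.seed(17)
  n <- 200
  X <- as.data.frame(matrix(rnorm(n * 12), n,
                            dimnames = list(NULL, paste0("t", 1:12))))
  y <- 2 * X$t1 - X$t2 + rnorm(n, sd = 0.1)
  fit <- stepwise_yield_model(X, y)
  expect_setequal(fit$selected[1:2], c("t1", "t2"))
  expect_true(all(c("t1", "t2") %in% fit$selected))
  expect_gt(fit$r, 0.99)
  # response equal to one candidate: selected first with R = 1 (the perfect
  # fit makes summary.lm grumble during the removal phase)
  fit2 <- suppressWarnings(stepwise_yield_model(X, X$t3))
  expect_equal(fit2$selected[1], "t3")
  expect_equal(fit2$r, 1, tolerance = 1e-7)
})

test_that("stepwise controls type-I error on pure noise", {
  hits <- 0
  for (i in 1:100) {
    set.seed(3000 + i)
    X <- data.frame(t1 = rnorm(30))
    y <- rnorm(30)
    if (length(stepwise_yield_model(X, y)$selected) > 0) hits <- hits + 1
  }
  expect_lte(hits, 10) # >= 90% of runs select nothing at alpha = 0.05
})

test_that("a redundant predictor never decreases stepwise R^2", {
  set.seed(23)
  X <- data.frame(a = rnorm(80), b = rnorm(80))
  y <- X$a + 0.5 * X$b + rnorm(80, sd = 0.2)
  base <- stepwise_yield_model(X, y)
  X2 <- X
  X2$c <- X$a + X$b # exactly redundant given a and b
  more <- suppressWarnings(stepwise_yield_model(X2, y))
  expect_gte(more$r_squared + 1e-12, base$r_squared)
  expect_error(stepwise_yield_model(data.frame(k = rep(1, 30)), rnorm(30)),
               "constant")
})
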
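mk_predictors <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(condition = rep(c("tacs", "sham"), length.out = n),
             precision_spat = runif(n, -0.1, 0.6),
             precision_freq = rnorm(n, 0, 0.7),
             strength = runif(n, 0.08, 0.36),
             strength_skin = runif(n, 1, 4),
             strength_eye = runif(n, 0.01, 0.2))
}

test_that("design matrices have 2^m columns and reproduce the printed df shapes", {
  tab <- mk_predictors(40)
  X4 <- build_design(tab, c("condition", "precision_spat", "precision_freq",
                            "strength"))
  expect_equal(ncol(X4), 16)
  expect_equal(colnames(X4)[1], "(Intercept)")
  f4 <- fit_ols(X4, rnorm(40))
  expect_equal(c(f4$df1, f4$df2), c(15, 24))
  X3 <- build_design(tab[1:20, ], c("precision_spat", "precision_freq",
                                    "strength"))
  expect_equal(ncol(X3), 8)
  f3 <- fit_ols(X3, rnorm(20))
  expect_equal(c(f3$df1, f3$df2), c(7, 12))
  f3b <- fit_ols(build_design(tab[1:19, ], c("precision_spat",
                                             "precision_freq", "strength")),
                 rnorm(19))
  expect_equal(c(f3b$df1, f3b$df2), c(7, 11))
  X0 <- build_design(tab, character(0))
  expect_equal(ncol(X0), 1)
  # condition coded 0/1
  expect_setequal(unique(X4[, "condition"]), c(0, 1))
  # collinear design rejected with the offending terms named
  tab$dup <- tab$strength
  expect_error(build_design(tab, c("strength", "dup")), "collinear")
})

test_that("OLS matches exact data and the normal-equations oracle", {
  x <- 1:10
  f <- fit_ols(cbind("(Intercept)" = 1, x = x), 2 * x)
  expect_equal(f$coefficients$beta, c(0, 2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  set.seed(15)
  X <- cbind(1, matrix(rnorm(40 * 5), 40, 5))
  colnames(X) <- c("(Intercept)", paste0("x", 1:5))
  y <- rnorm(40)
  f2 <- fit_ols(X, y)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)[, 1]
  expect_equal(f2$coefficients$beta, unname(beta_oracle), tolerance = 1e-8)
  # R^2 / F identity
  expect_equal(f2$f, (f2$r_squared / f2$df1) / ((1 - f2$r_squared) / f2$df2))
  expect_error(fit_ols(X[1:4, ], y[1:4]), "more observations")
})

test_that("null R^2 concentrates near df1/(n-1) under pure noise", {
  set.seed(16)
  r2 <- replicate(300, {
    X <- build_design(mk_predictors(20, seed = sample.int(1e6, 1)),
                      c("precision_spat", "precision_freq", "strength"))
    fit_ols(X, rnorm(20))$r_squared
  })
  expect_equal(mean(r2), 7 / 19, tolerance = 0.04)
})

test_that("AIC follows the Gaussian formula with RSS guard", {
  set.seed(17)
  X <- cbind(1, rnorm(30))
  y <- rnorm(30)
  f <- fit_ols(X, y)
  expect_equal(f$aic, 30 * log(f$rss / 30) + 2 * (2 + 1))
  # equal RSS, k differing by one -> delta AIC = 2
  f_art <- f
  f_art$k <- f$k + 1
  expect_equal(aic(f_art) - aic(f), 2)
  f0 <- f
  f0$rss <- 0
  expect_error(aic(f0), "RSS = 0")
})

test_that("all-subsets selection spans 2^m models and ranks by AIC", {
  tab <- mk_predictors(30)
  set.seed(18)
  rk <- all_subsets_selection(tab, c("precision_spat", "precision_freq",
                                     "strength"), rnorm(30))
  expect_equal(nrow(rk$table), 8)
  expect_true(all(diff(rk$table$aic) >= 0))
  expect_equal(rk$table$delta_aic[1], 0)
  expect_true("(intercept)" %in% rk$table$model)
  # nested R^2 monotonicity: intercept <= 1-factor <= full
  r2 <- rk$table$r_squared[match(c("(intercept)", "strength",
                                   "precision_spat+precision_freq+strength"),
                                 rk$table$model)]
  expect_true(r2[1] <= r2[2] && r2[2] <= r2[3])
})

test_that("selection recovers the generating model at high SNR and prefers the intercept under noise", {
  pool <- c("precision_spat", "precision_freq", "strength")
  full_first <- 0
  set.seed(19)
  for (i in 1:100) {
    tab <- mk_predictors(20, seed = i)
    X <- build_design(tab, pool)
    beta <- c(0.1, 1, 0.8, -0.6, 1.2, 0.9, -1.1, 1.5)
    y <- as.vector(X %*% beta) + rnorm(20, 0, 0.02)
    rk <- all_subsets_selection(tab, pool, y)
    full_first <- full_first + (rk$table$n_factors[1] == 3)
  }
  expect_gte(full_first / 100, 0.9)
  winners <- character(100)
  for (i in 1:100) {
    tab <- mk_predictors(20, seed = 1000 + i)
    rk <- all_subsets_selection(tab, pool, rnorm(20))
    winners[i] <- rk$table$model[1]
  }
  tt <- sort(table(winners), decreasing = TRUE)
  expect_equal(names(tt)[1], "(intercept)")
})

test_that("AIC ranking is invariant to positive response scaling", {
  tab <- mk_predictors(25)
  set.seed(20)
  y <- rnorm(25)
  rk1 <- all_subsets_selection(tab, c("precision_spat", "strength"), y)
  rk2 <- all_subsets_selection(tab, c("precision_spat", "strength"), 10 * y)
  expect_equal(rk1$table$model, rk2$table$model)
  expect_equal(rk2$table$aic - rk1$table$aic,
               rep(25 * log(100), 4), tolerance = 1e-9)
})

test_that("LOOCV refits equal the hat-matrix PRESS shortcut", {
  set.seed(21)
  X <- cbind(1, matrix(rnorm(25 * 3), 25, 3))
  y <- rnorm(25)
  cv <- loocv(X, y, definition = "press")
  H <- X %*% solve(crossprod(X)) %*% t(X)
  e <- y - X %*% solve(crossprod(X), crossprod(X, y))
  pred_oracle <- y - e / (1 - diag(H))
  expect_equal(cv$predictions, as.vector(pred_oracle), tolerance = 1e-10)
  expect_equal(cv$press, sum((y - pred_oracle)^2), tolerance = 1e-10)
  # exact linear data -> both definitions give 1
  y2 <- as.vector(X %*% c(1, 2, -1, 0.5))
  expect_equal(loocv(X, y2, "corr2")$r_squared_cv, 1, tolerance = 1e-9)
  expect_equal(loocv(X, y2, "press")$r_squared_cv, 1, tolerance = 1e-9)
  expect_error(loocv(X[1:5, ], y[1:5]), "n > columns")
})

test_that("null-response LOOCV: PRESS R^2 is typically non-positive, corr^2 small", {
  set.seed(22)
  press_r2 <- numeric(60); corr_r2 <- numeric(60)
  for (i in 1:60) {
    X <- cbind(1, matrix(rnorm(20 * 3), 20, 3))
    y <- rnorm(20)
    press_r2[i] <- loocv(X, y, "press")$r_squared_cv
    corr_r2[i] <- loocv(X, y, "corr2")$r_squared_cv
  }
  expect_gt(mean(press_r2 <= 0), 0.6)
  expect_lt(stats::median(corr_r2), 0.2)
})

test_that("sham-controlled response is the session difference with sign symmetry", {
  t1 <- c(1, 2, 3); s1 <- c(0.5, 1, 4)
  expect_equal(sham_controlled_response(t1, s1), t1 - s1)
  expect_equal(sham_controlled_response(t1, t1), rep(0, 3))
  expect_equal(sham_controlled_response(t1, rep(0, 3)), t1)
  expect_equal(sham_controlled_response(s1, t1), -(t1 - s1))
  expect_error(sham_controlled_response(t1, s1[1:2]), "both sessions")
  expect_error(sham_controlled_response(t1, c(1, NA, 2)), "missing")
})

test_that("peripheral comparison discriminates brain-driven from skin-driven responses", {
  set.seed(23)
  brain_wins <- 0; skin_wins <- 0
  for (i in 1:20) {
    tab <- mk_predictors(20, seed = 300 + i)
    y_brain <- 2 * tab$precision_spat * tab$strength +
      0.5 * tab$strength + rnorm(20, 0, 0.03)
    pm <- peripheral_model(tab, y_brain)
    brain_wins <- brain_wins + pm$brain_wins
    y_skin <- 0.4 * tab$strength_skin + rnorm(20, 0, 0.03)
    pm2 <- peripheral_model(tab, y_skin)
    skin_wins <- skin_wins + !pm2$brain_wins
  }
  expect_gte(brain_wins / 20, 0.9)
  expect_gte(skin_wins / 20, 0.9)
  # identical skin and brain strengths -> the shared-structure models tie
  tab <- mk_predictors(20, seed = 999)
  tab$strength_skin <- tab$strength
  y <- 0.5 * tab$strength + rnorm(20, 0, 0.05)
  pm3 <- peripheral_model(tab, y,
                          brain_pool = "strength",
                          peripheral_pool = "strength_skin")
  expect_equal(pm3$best_aic_peripheral, pm3$best_aic_brain, tolerance = 1e-8)
})
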
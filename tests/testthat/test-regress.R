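test_that("VIF screen spares orthogonal designs and drops collinear copies", {
  set.seed(2)
  # orthonormal columns, each also orthogonal to the intercept
  X <- qr.Q(qr(cbind(1, matrix(rnorm(100), 20, 5))))[, -1]
  colnames(X) <- paste0("x", 1:5)
  scr <- vif_screen(X, 5)
  expect_equal(scr$retained, colnames(X))
  expect_true(all(abs(scr$vif - 1) < 1e-8))

  X2 <- cbind(X[, 1:3], dup = X[, 1])
  colnames(X2)[1:3] <- paste0("x", 1:3)
  scr2 <- vif_screen(X2, 5)
  expect_equal(sort(setdiff(colnames(X2), scr2$retained)),
               sort(scr2$excluded$predictor))
  expect_equal(nrow(scr2$excluded), 1)
  expect_true(scr2$excluded$predictor %in% c("x1", "dup"))
  expect_equal(scr2$excluded$vif, Inf)
})

test_that("VIFs match the auxiliary-regression oracle on correlated designs", {
  set.seed(17)
  z <- rnorm(40)
  X <- cbind(a = z + rnorm(40, 0, 0.5), b = z + rnorm(40, 0, 0.5),
             c = rnorm(40))
  scr <- vif_screen(X, threshold = 1e6)  # high threshold: report only
  for (j in colnames(X)) {
    r2 <- summary(lm(X[, j] ~ X[, setdiff(colnames(X), j)]))$r.squared
    expect_equal(unname(scr$vif[j]), 1 / (1 - r2))
  }
})

test_that("OLS fit is exact on noiseless data and matches normal equations", {
  d <- data.frame(x1 = 1:10, x2 = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  d$y <- 3 + 2 * d$x1 - 0.5 * d$x2
  # noiseless fit: summary.lm warns about the essentially perfect fit
  fit <- suppressWarnings(fit_mlr("y", c("x1", "x2"), d, screen = FALSE))
  expect_equal(fit$coefficients$estimate, c(3, 2, -0.5), tolerance = 1e-10)
  expect_equal(fit$diagnostics$sigma, 0, tolerance = 1e-10)

  mean_only <- fit_mlr("y", character(), d)
  expect_equal(mean_only$coefficients$estimate, mean(d$y))

  set.seed(3)
  d$y <- d$y + rnorm(10)
  fit <- fit_mlr("y", c("x1", "x2"), d, screen = FALSE)
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-10)
  expect_true(all(fit$coefficients$lower <= fit$coefficients$estimate))
  expect_true(all(fit$coefficients$upper >= fit$coefficients$estimate))
})

test_that("Huber M-estimation matches OLS on clean data, resists outliers", {
  set.seed(5)
  n <- 40
  d <- data.frame(x = rnorm(n))
  d$y <- 1 + 2 * d$x + rnorm(n, 0, 0.3)
  ols <- fit_mlr("y", "x", d, screen = FALSE)
  rob <- fit_m_estimation("y", "x", d, screen = FALSE)
  expect_equal(rob$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 0.02)
  expect_true(rob$diagnostics$converged)
  expect_gte(rob$diagnostics$iterations, 1)

  set.seed(6)
  d2 <- data.frame(x = rnorm(20))
  d2$y <- 1 + 2 * d2$x + rnorm(20, 0, 0.2)
  d2$y[1] <- d2$y[1] + 50  # gross outlier
  ols2 <- fit_mlr("y", "x", d2, screen = FALSE)
  rob2 <- fit_m_estimation("y", "x", d2, screen = FALSE)
  slope_err <- function(f) abs(f$coefficients$estimate[2] - 2)
  expect_lt(slope_err(rob2), slope_err(ols2))
})

test_that("converged IRLS weights reproduce the fit under weighted least squares", {
  set.seed(7)
  d <- data.frame(x = rnorm(25))
  d$y <- 0.5 - 1.5 * d$x + rt(25, 2)
  rob <- fit_m_estimation("y", "x", d, screen = FALSE)
  w <- rob$model$w
  wls <- lm(y ~ x, data = d, weights = w)
  expect_equal(rob$coefficients$estimate, unname(coef(wls)),
               tolerance = 1e-5)
})

test_that("Bayesian posterior tracks OLS when the likelihood dominates", {
  set.seed(11)
  n <- 2000
  d <- data.frame(x = rnorm(n))
  d$y <- 0.2 + 0.8 * d$x + rnorm(n, 0, 0.5)
  bay <- fit_bayes("y", "x", d, chains = 2, draws = 1000, warmup = 500,
                   seed = 4, screen = FALSE)
  ols <- fit_mlr("y", "x", d, screen = FALSE)
  post_sd <- apply(bay$draws[, c("(Intercept)", "x")], 2, sd)
  gap <- abs(bay$coefficients$estimate[1:2] - ols$coefficients$estimate)
  expect_true(all(gap < 2 * post_sd))
})

test_that("fixed-sigma posterior matches the conjugate closed form", {
  set.seed(12)
  n <- 8
  x <- rnorm(n)
  y <- 0.3 + 0.5 * x + rnorm(n, 0, 0.4)
  d <- data.frame(y = y, x = x)
  bay <- fit_bayes("y", "x", d, chains = 4, draws = 4000, warmup = 500,
                   seed = 9, screen = FALSE, sigma_fixed = 0.4)
  ys <- (y - mean(y)) / sd(y)
  xs <- (x - mean(x)) / sd(x)
  s <- 0.4 / sd(y)
  Xm <- cbind(1, xs)
  post <- solve(crossprod(Xm) / s^2 + diag(2) / 0.5^2,
                crossprod(Xm, ys) / s^2)
  oracle_slope_raw <- post[2] * sd(y) / sd(x)
  expect_equal(bay$coefficients$estimate[2], oracle_slope_raw,
               tolerance = 0.02)
})

test_that("identical seed and data give identical draws", {
  set.seed(14)
  d <- data.frame(x = rnorm(30))
  d$y <- 1 + d$x + rnorm(30)
  # deliberately short chains: suppress the low-ESS convergence warning
  b1 <- suppressWarnings(fit_bayes("y", "x", d, chains = 2, draws = 300,
                                   warmup = 200, seed = 123, screen = FALSE))
  b2 <- suppressWarnings(fit_bayes("y", "x", d, chains = 2, draws = 300,
                                   warmup = 200, seed = 123, screen = FALSE))
  expect_identical(b1$draws, b2$draws)
  b3 <- suppressWarnings(fit_bayes("y", "x", d, chains = 2, draws = 300,
                                   warmup = 200, seed = 124, screen = FALSE))
  expect_false(identical(b1$draws, b3$draws))
})

test_that("the cascade picks the branch the data demand", {
  set.seed(20)
  n <- 60
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- 1 + 2 * d$x + rnorm(n)
  g <- auto_cascade("y", c("x", "z"), d)
  expect_equal(g$family_used, "mlr")
  expect_equal(g$diagnostics$cascade$branch, "mlr")

  d$y <- 1 + 2 * d$x + rt(n, 1)  # Cauchy residuals
  h <- auto_cascade("y", c("x", "z"), d)
  expect_equal(h$family_used, "m_estimation")
  expect_lt(h$diagnostics$cascade$shapiro_p, 0.05)

  small <- d[1:5, ]  # n = 5 <= p + 3 with p = 2: gate tests untrusted
  b <- suppressWarnings(auto_cascade("y", c("x", "z"), small, chains = 2,
                                     draws = 300, warmup = 200, seed = 2))
  expect_equal(b$family_used, "bayes")
  expect_match(b$diagnostics$cascade$reason, "too small")

  tiny <- d[1:3, ]  # n <= p + 1: no fit is possible
  expect_error(auto_cascade("y", c("x", "z"), tiny), "too few observations")
})

test_that("Spearman matrix handles monotone, antitone, tied and constant cases", {
  X <- data.frame(up = 1:8, flat = rep(1, 8))
  Y <- data.frame(mono = (1:8)^3, anti = -(1:8))
  out <- spearman_matrix(X, Y)
  get <- function(cv, oc) out[out$covariate == cv & out$outcome == oc, ]
  expect_equal(get("up", "mono")$rho, 1)
  expect_equal(get("up", "anti")$rho, -1)
  expect_true(is.na(get("flat", "mono")$rho))

  adj <- spearman_matrix(X["up"], Y, adjust = "BH")
  expect_equal(adj$q, p.adjust(adj$p, "BH"))
  expect_error(spearman_matrix(data.frame(a = 1:2), data.frame(b = 1:2)),
               ">= 3")
})

test_that("exact Spearman p equals full permutation enumeration at n = 8", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.9, 0.5)
  out <- spearman_matrix(data.frame(x = x), data.frame(y = y))
  rx <- rank(x)
  ry <- rank(y)
  obs <- cor(rx, ry)
  perms <- combinat_perms(8)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  p_exact <- mean(abs(rhos) >= abs(obs) - 1e-12)
  expect_equal(out$p, p_exact, tolerance = 1e-10)
})

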
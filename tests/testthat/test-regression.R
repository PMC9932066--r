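test_that("orthogonal predictors all have VIF 1 and none are dropped", {
  X <- data.frame(a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4),
                  c = rep(c(-1, 1), each = 8))
  out <- vifScreen(X)
  expect_equal(unname(out$vif), rep(1, 3), tolerance = 1e-12)
  expect_length(out$dropped, 0)
})

test_that("a correlated pair has the closed-form VIF 1/(1-r^2)", {
  set.seed(10)
  a <- rnorm(200)
  b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(200)
  r <- cor(a, b)
  out <- vifScreen(data.frame(a = a, b = b), cutoff = 100)
  expect_equal(unname(out$vif), rep(1 / (1 - r^2), 2), tolerance = 1e-9)
})

test_that("perfect collinearity is dropped first with a warning", {
  set.seed(11)
  a <- rnorm(50); c <- rnorm(50)
  w <- capture_warnings(out <- vifScreen(data.frame(a = a, b = 2 * a, c = c)))
  expect_true(any(grepl("perfect collinearity", w)))
  expect_length(out$retained, 2)
  expect_true("c" %in% out$retained)
})

test_that("the generator's bare-soil/impervious collinearity trips the screen", {
  cfg <- syntheticConfig(nSites = 50)
  st <- generateStudy(cfg, seed = 29)
  X <- st$siteData[c("imperv_100", "bare_soil", "veg_height",
                     "flowering_plant_richness")]
  out <- vifScreen(X, cutoff = 3)
  expect_true("imperv_100" %in% out$dropped || "bare_soil" %in% out$dropped)
  expect_true(all(out$vif <= 3))
})

test_that("Poisson slopes are recovered and equidispersion keeps the Poisson branch", {
  set.seed(12)
  x <- rnorm(500)
  y <- rpois(500, exp(1 + 0.5 * x))
  fit <- fitCountModel(y, data.frame(x = x))
  expect_identical(fit$family, "poisson")
  expect_lt(abs(fit$coefficients["x", "Estimate"] - 0.5),
            2 * fit$coefficients["x", "Std. Error"])
  expect_true(is.finite(fit$aic))
  expect_gte(fit$r2, 0)
})

test_that("overdispersed counts trigger the negative-binomial refit", {
  set.seed(13)
  x <- rnorm(400)
  y <- rnbinom(400, mu = exp(1 + 0.4 * x), size = 1.5)
  fit <- fitCountModel(y, data.frame(x = x))
  expect_identical(fit$family, "nbinom")
  expect_lt(abs(fit$coefficients["x", "Estimate"] - 0.4),
            2.5 * fit$coefficients["x", "Std. Error"])
})

test_that("NB estimates converge to Poisson when overdispersion vanishes", {
  set.seed(14)
  x <- rnorm(800)
  y <- rpois(800, exp(0.8 + 0.3 * x))
  po <- fitCountModel(y, data.frame(x = x), family = "poisson")
  nb <- fitCountModel(y, data.frame(x = x), family = "nbinom")
  expect_lt(max(abs(po$coefficients[, "Estimate"] -
                      nb$coefficients[, "Estimate"])), 1e-3)
})

test_that("continuous responses take the Gaussian branch with ordinary R2", {
  set.seed(15)
  x <- rnorm(60); y <- 1 + 0.7 * x + rnorm(60, sd = 0.5)
  fit <- fitCountModel(y, data.frame(x = x))
  expect_identical(fit$family, "gaussian")
  expect_equal(fit$r2, summary(lm(y ~ x))$r.squared)
})

test_that("degenerate inputs to the ladder are rejected", {
  expect_error(fitCountModel(c(1.5, 2.2, 3.1), data.frame(x = 1:3),
                             family = "poisson"), "integer")
  expect_error(fitCountModel(rpois(10, 4), data.frame(z = rep(2, 10))),
               "zero-variance")
})

test_that("all-subsets AIC search fits the documented number of models", {
  set.seed(16)
  X <- as.data.frame(matrix(rnorm(50 * 6), 50))
  names(X) <- paste0("p", 1:6)
  y <- rnorm(50)
  sel <- subsetSelectAic(y, X, maxTerms = 3)
  expect_equal(nrow(sel$ranking), 1 + 6 + 15 + 20)   # 42 subsets
  expect_lte(length(sel$bestTerms), 3)
  expect_equal(sel$ranking$aic, sort(sel$ranking$aic))
  only0 <- subsetSelectAic(y, X, maxTerms = 0)
  expect_length(only0$bestTerms, 0)
  expect_equal(nrow(only0$ranking), 1)
})

test_that("a strong true predictor is selected over noise", {
  set.seed(17)
  X <- as.data.frame(matrix(rnorm(300 * 6), 300))
  names(X) <- c("true", paste0("noise", 1:5))
  y <- 2 + 1.5 * X$true + rnorm(300)
  sel <- subsetSelectAic(y, X, maxTerms = 3)
  expect_true("true" %in% sel$bestTerms)
})

test_that("adding a pure-noise predictor raises AIC in expectation", {
  set.seed(18)
  diffs <- vapply(1:200, function(i) {
    x <- rnorm(30); y <- 1 + x + rnorm(30)
    AIC(lm(y ~ x + rnorm(30))) - AIC(lm(y ~ x))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("Moran's I flags a spatial gradient and has the exact null mean", {
  set.seed(19)
  coords <- cbind(runif(20, 0, 10), runif(20, 0, 10))
  grad <- coords[, 1] + 0.2 * rnorm(20)
  mi <- moransI(grad - mean(grad), coords)
  expect_gt(mi$observed, 0)
  expect_lt(mi$p, 0.05)
  expect_true(mi$gls_recommended)
  expect_equal(mi$expected, -1 / 19)
  noise <- rnorm(20)
  expect_equal(moransI(noise, coords)$expected, -1 / 19)
})

test_that("the normal-approximation p is close to the permutation p at n = 8", {
  set.seed(20)
  coords <- cbind(c(0, 1, 2, 0, 1, 2, 0, 1), c(0, 0, 0, 1, 1, 1, 2, 2))
  z <- rnorm(8)
  mi <- moransI(z, coords)
  # Monte-Carlo permutation reference with the same weights
  d <- as.matrix(dist(coords)); w <- 1 / d; diag(w) <- 0; w <- w / rowSums(w)
  iStat <- function(v) {
    vc <- v - mean(v)
    (8 / sum(w)) * sum(w * outer(vc, vc)) / sum(vc^2)
  }
  perm <- vapply(1:4000, function(i) iStat(sample(z)), numeric(1))
  pPerm <- mean(abs(perm - mean(perm)) >= abs(mi$observed - mean(perm)))
  expect_lt(abs(mi$p - pPerm), 0.02)
  expect_error(moransI(z, coords[c(1, 1, 2:7), ]), "coincident")
})

test_that("delta meta-statistics behave at their degenerate limits", {
  expect_error(deltaMeta(rep(0.3, 5)), "zero variance")
  expect_error(deltaMeta(c(0.1, 0.2)), "at least 3")
  set.seed(21)
  d <- rnorm(11, 0.3, 0.1)
  out <- deltaMeta(d)
  expect_equal(out$t, unname(t.test(d, mu = 0)$statistic))
  x <- rnorm(8)
  rc <- resolutionCompare(x, x)
  expect_equal(rc$r, 1)
  expect_equal(rc$t, 0)
  expect_equal(rc$t_p, 1)
  expect_error(resolutionCompare(x, x + 1), "constant non-zero")
})

test_that("the one-sample t-test attains its simulated power", {
  set.seed(22)
  nRep <- 400
  rejections <- vapply(seq_len(nRep), function(i) {
    deltaMeta(rnorm(11, 0.3, 0.1))$p < 0.05
  }, logical(1))
  # at delta = 3 sd and n = 11 the test is essentially always significant
  expect_gte(mean(rejections), 0.99)
})
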
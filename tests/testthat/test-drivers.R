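test_that("stratified sampling counts and reproducibility", {
  w <- small_world()
  lu <- w$lw$t0
  n1 <- sum(lu$values == 1)
  n0 <- sum(lu$values != 1)
  s <- sample_points(lu, 1, 0.05, seed = 3)
  expect_equal(sum(s$label == 1), floor(0.05 * n1))
  expect_equal(sum(s$label == 0), floor(0.05 * n0))
  # sampled coordinates really carry the right class
  idx <- cbind(s$row, s$col)
  expect_true(all((lu$values[idx] == 1) == (s$label == 1)))
  # same seed -> identical; fraction 1 -> census
  expect_identical(s, sample_points(lu, 1, 0.05, seed = 3))
  all_ <- sample_points(lu, 1, 1, seed = 3)
  expect_equal(nrow(all_), n1 + n0)
  expect_error(sample_points(lu, 1, 1e-6, seed = 1), "empty")
})

test_that("VIF and tolerance match the least-squares definition", {
  set.seed(4)
  n <- 300
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  x3 <- 0.8 * x1 + 0.6 * x2 + stats::rnorm(n, 0, 0.5)
  d <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  v <- collinearity(d)
  # independent oracle: direct 1/(1 - R^2) per factor
  for (j in 1:3) {
    r2 <- summary(stats::lm(d[[j]] ~ ., data = d[-j]))$r.squared
    expect_equal(v$vif[j], 1 / (1 - r2))
    expect_equal(v$vif[j] * v$tol[j], 1)
  }
  expect_false(any(v$flag))
  # independent factors sit near VIF 1
  ortho <- collinearity(data.frame(a = stats::rnorm(200),
                                   b = stats::rnorm(200)))
  expect_true(all(ortho$vif < 1.2))
  # a duplicated factor is flagged singular
  d$x4 <- d$x1
  v2 <- collinearity(d)
  expect_true(any(v2$flag))
  expect_true(any(!is.finite(v2$vif) | v2$vif > 100))
})

test_that("logistic fit recovers known slopes on synthetic data", {
  set.seed(12)
  n <- 5000
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  eta <- -0.5 + 1.0 * x1 - 0.7 * x2
  y <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- fit_blr(data.frame(label = y, x1 = x1, x2 = x2))
  expect_false(fit$separation)
  # factors are z-scored with sd ~ 1, so slopes are comparable to truth
  expect_equal(unname(fit$coef["x1"]), 1.0, tolerance = 0.1)
  expect_equal(unname(fit$coef["x2"]), -0.7, tolerance = 0.1)
  expect_lt(fit$p["x1"], 1e-10)
})

test_that("a null factor is rarely significant", {
  set.seed(21)
  n <- 2000
  d <- data.frame(label = stats::rbinom(n, 1, 0.4),
                  x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  fit <- fit_blr(d)
  expect_true(all(fit$p > 1e-4))   # no spurious certainty under the null
})

test_that("perfect separation falls back to a flagged ridge fit", {
  d <- data.frame(label = rep(c(0, 1), each = 30),
                  x1 = rep(c(-1, 1), each = 30) + stats::rnorm(60, 0, 1e-3),
                  x2 = stats::rnorm(60))
  fit <- fit_blr(d)
  expect_true(fit$separation)
  expect_true(is.finite(fit$coef["x1"]))
  expect_gt(fit$coef["x1"], 0)
})

test_that("signed weights normalize the significant coefficients", {
  w <- derive_weights(c(a = 2, b = -1, c = 0.4),
                      p = c(a = 1e-4, b = 1e-3, c = 0.5))
  expect_equal(w$weight, c(2 / 3, 1 / 3))
  expect_equal(w$sign, c(1L, -1L))
  expect_equal(sum(w$weight), 1)

  # single significant factor takes weight 1 with its sign
  w1 <- derive_weights(c(a = -3, b = 1), p = c(a = 0.001, b = 0.9))
  expect_equal(w1$weight, 1)
  expect_equal(w1$sign, -1L)

  # symmetric magnitudes split 50/50 regardless of sign
  w2 <- derive_weights(c(a = 1.4, b = -1.4), p = c(a = 0.01, b = 0.01))
  expect_equal(w2$weight, c(0.5, 0.5))

  # scale invariance
  co <- c(a = 0.3, b = -1.2, c = 0.8)
  p <- c(a = 0.01, b = 0.02, c = 0.001)
  expect_equal(derive_weights(co, p = p)$weight,
               derive_weights(co * 7, p = p)$weight)
  expect_error(derive_weights(c(a = 1), p = c(a = 0.9)), "no significant")
})

test_that("per-class driver fits produce unit-sum weight rows", {
  w <- small_world()
  dw <- fit_drivers(w$lw$t1, w$drv, fraction = 0.1, seed = 5,
                    classes = c(1, 2, 5))
  for (k in names(dw$per_class))
    expect_equal(sum(dw$per_class[[k]]$weights$weight), 1, tolerance = 1e-9)
  expect_true(all(c("class", "factor", "weight", "sign", "vif") %in%
                    names(dw$table)))
})
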
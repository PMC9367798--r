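test_that("standardization handles positive and negative attributes", {
  tab <- indicator_table(cbind(p = c(2, 4, 6), n = c(2, 4, 6)),
                         c(p = "positive", n = "negative"))
  tab <- standardize_indicators(tab)
  expect_equal(unname(tab$H[, "p"]), c(0, 0.5, 1))   # max -> 1
  expect_equal(unname(tab$H[, "n"]), c(1, 0.5, 0))   # max -> 0
  expect_true(all(tab$H >= 0 & tab$H <= 1))
  expect_error(standardize_indicators(
    indicator_table(cbind(k = c(1, 1, 1)), "positive")), "constant")
})

test_that("entropy weights match the hand-computed formula", {
  # frozen from an independent spreadsheet-style evaluation of
  # p_ij = H_ij / sum_i H_ij, e_j = -(1/ln m) sum p ln p, w = (1-e)/sum(1-e)
  tab <- indicator_table(cbind(a = c(0.2, 0.4, 0.6, 0.8),
                               b = c(1, 0, 1, 0),
                               c = c(0.1, 0.1, 0.1, 0.7)), "positive")
  tab$H <- tab$x   # values already in [0,1]; treat as standardized
  w <- entropy_weights(tab)
  expect_equal(unname(w), c(0.08546431, 0.55655085, 0.35798483),
               tolerance = 1e-7)
  expect_equal(sum(w), 1)
})

test_that("zero-information and duplicate indicators weight sensibly", {
  tab <- indicator_table(cbind(v = c(0, 1, 0.5), k = c(0.5, 0.5, 0.5)),
                         "positive")
  tab$H <- tab$x
  w <- entropy_weights(tab)
  expect_equal(unname(w), c(1, 0))   # constant column carries no weight

  tab2 <- indicator_table(cbind(a = c(0, 1, 0.5), b = c(0, 1, 0.5)),
                          "positive")
  tab2$H <- tab2$x
  expect_equal(unname(entropy_weights(tab2)), c(0.5, 0.5))
})

test_that("entropy weights are permutation-equivariant in units", {
  set.seed(3)
  X <- matrix(stats::runif(40), 8, 5,
              dimnames = list(NULL, paste0("i", 1:5)))
  t1 <- standardize_indicators(indicator_table(X, "positive"))
  t2 <- standardize_indicators(indicator_table(X[sample(8), ], "positive"))
  expect_equal(entropy_weights(t1), entropy_weights(t2))
})

test_that("children are ranked by importance with stable ties", {
  h <- cpm_hierarchy(list(name = "r", children = list("D1", "D2")))
  # reference weights: per-farmland pesticide outweighs fertilizer
  w <- with(psr_indicators(), stats::setNames(weight, indicator))
  rk <- rank_children(h, w)
  expect_equal(vapply(rk$root$children, `[[`, "", "name"), c("D2", "D1"))

  # equal weights keep declaration order
  rk2 <- rank_children(h, c(D1 = 0.5, D2 = 0.5))
  expect_equal(vapply(rk2$root$children, `[[`, "", "name"), c("D1", "D2"))
})

test_that("criteria blocks rank state > response > pressure under the
           reference weights", {
  meta <- psr_indicators()
  w <- stats::setNames(meta$weight, meta$indicator)
  expect_equal(sum(w[meta$criteria == "pressure"]), 0.175)
  expect_equal(sum(w[meta$criteria == "state"]), 0.495)
  expect_equal(sum(w[meta$criteria == "response"]), 0.330)
  rk <- rank_children(psr_hierarchy(), w)
  expect_equal(vapply(rk$root$children, `[[`, "", "name"),
               c("state", "response", "pressure"))
})

test_that("catastrophe aggregation reproduces hand-evaluated values", {
  cusp <- rank_children(cpm_hierarchy(list(name = "r",
                                           children = list("a", "b"))),
                        c(a = 0.6, b = 0.4))
  # mean(sqrt(0.25), cbrt(0.027)) = mean(0.5, 0.3)
  expect_equal(cpm_aggregate(cusp, c(a = 0.25, b = 0.027)), 0.4)
  expect_equal(cpm_aggregate(cusp, c(a = 1, b = 1)), 1)
  expect_equal(cpm_aggregate(cusp, c(a = 0, b = 0)), 0)

  # depth-1 fold model is exactly sqrt
  fold <- rank_children(cpm_hierarchy(list(name = "r",
                                           children = list("x"))),
                        c(x = 1))
  expect_equal(cpm_aggregate(fold, c(x = 0.49)), 0.7)

  # non-complementary takes the minimum of the normalized controls
  ncusp <- cpm_hierarchy(list(name = "r", children = list("a", "b"),
                              principle = "non-complementary"))
  ncusp <- rank_children(ncusp, c(a = 0.6, b = 0.4))
  expect_equal(cpm_aggregate(ncusp, c(a = 0.25, b = 0.027)), 0.3)

  expect_error(cpm_hierarchy(list(name = "r",
                                  children = as.list(paste0("x", 1:5)))),
               "1-4 children")
  expect_error(cpm_aggregate(cusp, c(a = 1.2, b = 0)), "outside")
})

test_that("reference levels anchor at 0 and 1 and increase strictly", {
  cusp <- rank_children(cpm_hierarchy(list(name = "r",
                                           children = list("a", "b"))),
                        c(a = 0.6, b = 0.4))
  lv <- reference_levels(cusp)
  expect_equal(lv[1], 0)
  expect_equal(lv[11], 1)
  expect_equal(lv[6], 0.7504037, tolerance = 1e-6)  # mean(sqrt, cbrt)(0.5)
  expect_true(all(diff(lv) > 0))
})

test_that("index adjustment is piecewise-linear on the affiliation scale", {
  # worked decile: n_7 = 0.85, n_8 = 0.95, L = 0.90
  lv2 <- c(0, 0.25, 0.45, 0.55, 0.65, 0.72, 0.80, 0.85, 0.95, 0.99, 1)
  expect_equal(adjust_index(0.90, lv2, "verbatim"), 0.05)
  expect_equal(adjust_index(0.90, lv2, "monotone"), 0.75)
  # interval endpoints
  expect_equal(adjust_index(lv2[4], lv2, "monotone"), 0.3)
  expect_equal(adjust_index(lv2[4], lv2, "verbatim"), 0)
  expect_equal(adjust_index(1, lv2, "verbatim"), 0.1)
  expect_equal(adjust_index(0, lv2, "monotone"), 0)
})

test_that("monotone adjustment preserves ordering; verbatim within deciles", {
  h <- rank_children(cpm_hierarchy(list(name = "r",
                                        children = list("a", "b", "c"))),
                     c(a = 0.5, b = 0.3, c = 0.2))
  lv <- reference_levels(h)
  set.seed(11)
  L <- sort(stats::runif(50))
  adj <- adjust_index(L, lv, "monotone")
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= 0 & adj <= 1))
  verb <- adjust_index(L, lv, "verbatim")
  expect_true(all(verb >= 0 & verb <= 0.1 + 1e-12))
})

test_that("aggregation is monotone in every leaf and bounded", {
  for (s in 1:30) {
    nl <- sample(2:10, 1)
    h <- random_hierarchy(nl, seed = 1000 + s)
    w <- stats::runif(nl); names(w) <- h$leaves
    h <- rank_children(h, w / sum(w))
    x <- stats::runif(nl); names(x) <- h$leaves
    base <- cpm_aggregate(h, x)
    expect_gte(base, 0); expect_lte(base, 1)
    leaf <- sample(h$leaves, 1)
    x2 <- x
    x2[leaf] <- min(1, x2[leaf] + stats::runif(1, 0, 1 - x2[leaf]))
    expect_gte(cpm_aggregate(h, x2), base - 1e-12)
  }
})

test_that("complementary principle dominates non-complementary", {
  mk <- function(pr) {
    h <- cpm_hierarchy(list(name = "r", principle = pr,
                            children = list("a", "b", "c")))
    rank_children(h, c(a = 0.5, b = 0.3, c = 0.2))
  }
  for (s in 1:20) {
    set.seed(s)
    x <- stats::runif(3); names(x) <- c("a", "b", "c")
    expect_gte(cpm_aggregate(mk("complementary"), x),
               cpm_aggregate(mk("non-complementary"), x))
  }
})

test_that("hierarchies load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: r", "children:",
               "  - name: u", "    children: [a, b]",
               "  - c"), path)
  h <- cpm_hierarchy(path)
  expect_equal(sort(h$leaves), c("a", "b", "c"))
  expect_equal(h$root$model, "cusp")
})

test_that("the one-call evaluation returns a coherent object", {
  set.seed(5)
  X <- matrix(stats::runif(19 * 30), 30, 19,
              dimnames = list(NULL, psr_indicators()$indicator))
  tab <- indicator_table(X, stats::setNames(psr_indicators()$attribute,
                                            psr_indicators()$indicator))
  fit <- lesi(tab)
  expect_s3_class(fit, "lesi")
  expect_length(fit$raw, 30)
  expect_true(all(fit$raw >= 0 & fit$raw <= 1))
  # monotone adjustment preserves unit ordering
  expect_equal(order(fit$raw), order(fit$adjusted))
  expect_output(print(summary(fit)), "units: 30")
})
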
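test_that("transition matrix counts conversions per base class", {
  lu <- toy_map()
  # identical maps give the identity matrix
  tm <- transition_matrix(lu, lu)
  expect_equal(unname(tm$P), diag(6))

  # one of four farmland cells becomes woodland
  v2 <- lu$values; v2[1, 1] <- 2
  tm2 <- transition_matrix(lu, les_landuse(v2))
  expect_equal(unname(tm2$P[1, 1:2]), c(0.75, 0.25))
  expect_equal(rowSums(tm2$P), rep(1, 6), ignore_attr = TRUE)

  # random map pairs always have unit row sums; absent classes identity
  set.seed(14)
  a <- les_landuse(matrix(sample(1:5, 100, TRUE), 10, 10))
  b <- les_landuse(matrix(sample(1:5, 100, TRUE), 10, 10))
  tm3 <- transition_matrix(a, b)
  expect_equal(rowSums(tm3$P), rep(1, 6), ignore_attr = TRUE)
  expect_equal(unname(tm3$P[6, ]), c(0, 0, 0, 0, 0, 1))
})

test_that("demand projection conserves cells with integer targets", {
  P <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(1:2, 1:2))
  d <- project_demand(P, c(`1` = 100, `2` = 0))
  expect_equal(unname(d$targets), c(90, 10))

  # identity matrix returns the base counts
  I <- diag(2); dimnames(I) <- list(1:2, 1:2)
  expect_equal(unname(project_demand(I, c(`1` = 37, `2` = 5))$targets),
               c(37, 5))

  # conservation for arbitrary stochastic matrices
  set.seed(3)
  for (i in 1:10) {
    M <- matrix(stats::rexp(36), 6, 6)
    M <- M / rowSums(M)
    dimnames(M) <- list(1:6, 1:6)
    base <- stats::setNames(sample(0:500, 6), 1:6)
    dd <- project_demand(M, base)
    expect_equal(sum(dd$targets), sum(base))
    expect_equal(rowSums(dd$flow), base, ignore_attr = TRUE)
  }
})

test_that("neighborhood factor is the windowed class fraction", {
  uni <- matrix(2L, 9, 9)
  expect_equal(neighborhood_factor(uni, 2), matrix(1, 9, 9))
  expect_equal(neighborhood_factor(uni, 5), matrix(0, 9, 9))  # absent class

  # isolated cell: 1 of 25 at the interior cell itself
  iso <- matrix(1L, 11, 11); iso[6, 6] <- 5L
  h <- neighborhood_factor(iso, 5, 5)
  expect_equal(h[6, 6], 1 / 25)
  expect_equal(h[6, 8], 1 / 25)
  expect_equal(h[6, 9], 0)

  # edge truncation: corner windows are 3x3
  iso2 <- matrix(1L, 7, 7); iso2[1, 1] <- 5L
  expect_equal(neighborhood_factor(iso2, 5, 5)[1, 1], 1 / 9)
})

test_that("zero demand leaves the state untouched", {
  lu <- toy_map()
  demand <- matrix(0L, 6, 6, dimnames = list(1:6, 1:6))
  atl <- structure(list(maps = list(`5` = matrix(0.5, 4, 4)),
                        scenario = "ND"), class = "suitability_atlas")
  step <- allocate_cycle(lu$values, atl, demand, demand, 1, 10)
  expect_identical(step$state, lu$values)
})

test_that("a strictly dominant candidate wins a single-cell demand", {
  st <- matrix(1L, 6, 6)
  Q <- matrix(0.1, 6, 6); Q[3, 4] <- 0.9
  demand <- matrix(0L, 6, 6, dimnames = list(1:6, 1:6))
  demand[1, 5] <- 1L
  atl <- structure(list(maps = list(`5` = Q)), class = "suitability_atlas")
  step <- allocate_cycle(st, atl, demand, demand * 0L, cycle = 1, cycles = 1)
  expect_equal(step$state[3, 4], 5L)
  expect_equal(sum(step$state == 5L), 1)
})

test_that("cycle allocation matches the greedy brute-force oracle", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(5:8, 1)
    st <- matrix(sample(c(1L, 2L), n * n, TRUE, prob = c(0.7, 0.3)), n, n)
    if (!any(st == 1L)) st[1, 1] <- 1L
    Q <- matrix(round(stats::runif(n * n), 3), n, n)  # ties likely
    demand <- matrix(0L, 6, 6, dimnames = list(1:6, 1:6))
    demand[1, 5] <- sample(1:6, 1)
    atl <- structure(list(maps = list(`5` = Q)),
                     class = "suitability_atlas")
    got <- allocate_cycle(st, atl, demand, demand * 0L, 1, 1)$state
    want <- brute_allocate(st, Q, 1L, 5L, demand[1, 5])
    expect_identical(got, want, label = paste("seed", s))
  }
})

test_that("frozen cells and restricted cells never change", {
  st <- matrix(1L, 5, 5)
  Q <- matrix(1, 5, 5); Q[1, ] <- 0          # restricted row
  frozen <- matrix(FALSE, 5, 5); frozen[2, ] <- TRUE
  demand <- matrix(0L, 6, 6, dimnames = list(1:6, 1:6))
  demand[1, 5] <- 25L
  atl <- structure(list(maps = list(`5` = Q)), class = "suitability_atlas")
  step <- allocate_cycle(st, atl, demand, demand * 0L, 1, 1, frozen = frozen)
  expect_true(all(step$state[1, ] == 1L))
  expect_true(all(step$state[2, ] == 1L))
  expect_true(all(step$state[3:5, ] == 5L))
  expect_equal(step$shortfall$unmet, 10)     # 25 wanted, 15 eligible
})

test_that("simulation under an identity matrix returns the base map", {
  w <- small_world()
  tmI <- transition_matrix(w$lw$t0, w$lw$t0)
  atl <- structure(list(maps = list(), scenario = "ND"),
                   class = "suitability_atlas")
  sim <- ca_simulate(w$lw$t0, tmI, atl, cycles = 3)
  expect_identical(sim$map$values, w$lw$t0$values)
})

test_that("demand satisfaction is monotone and conserved across cycles", {
  w <- small_world()
  mod <- lucc(w$lw$t0, w$lw$t1)
  dw <- fit_drivers(w$lw$t1, w$drv, fraction = 0.1, seed = 5,
                    classes = c(1, 2, 5))
  atl <- suitability_atlas(dw, w$drv, w$lw$t1, scenario = "ND")
  demand <- project_demand(mod$P)$change
  state <- w$lw$t1$values
  frozen <- state == 4L | state == 5L
  allocated <- matrix(0L, 6, 6, dimnames = dimnames(demand))
  n_by_class_prev <- tabulate(state, 6)
  prev_alloc <- allocated
  for (t in 1:5) {
    step <- allocate_cycle(state, atl, demand, allocated, t, 5, frozen)
    state <- step$state; allocated <- step$allocated
    expect_equal(sum(tabulate(state, 6)), sum(n_by_class_prev)) # conserved
    expect_true(all(allocated >= prev_alloc))                   # monotone
    prev_alloc <- allocated
  }
  # the only unmet demand can come from frozen/restricted sources
  met <- allocated[demand > 0]
  expect_true(all(met <= demand[demand > 0]))
})
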
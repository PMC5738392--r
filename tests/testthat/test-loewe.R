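# Independent classical-Loewe oracle: solve the readout-form concentration
# additivity equation sum_j (c_j/i_j) ((m-b)/(r-b) - 1)^(1/h_j) = 1 for r
# directly by bracketed root-finding (valid when all compounds share m).
classical_loewe_readout <- function(curves, doses) {
  b <- curves[[1]]$b; m <- curves[[1]]$m
  f <- function(r) {
    sum(vapply(seq_along(curves), function(j) {
      cv <- curves[[j]]
      (doses[j] / cv$ec50) * ((m - b) / (r - b) - 1)^(1 / cv$hill)
    }, numeric(1))) - 1
  }
  span <- abs(m - b)
  bounds <- sort(c(b, m))  # handles inverse-direction curves (m < b)
  stats::uniroot(f, lower = bounds[1] + 1e-12 * span,
                 upper = bounds[2] - 1e-12 * span, tol = 1e-14)$root
}

test_that("occupancy solver matches the closed form for unit Hill slopes", {
  set.seed(31)
  for (i in 1:20) {
    b <- runif(1, -0.2, 0.4)
    curves <- list(marginal_curve(b, b + 1, 10^runif(1, -1, 1), 1),
                   marginal_curve(b, b + 0.5, 10^runif(1, -1, 1), 1))
    doses <- 10^runif(2, -2, 2)
    S <- doses[1] / curves[[1]]$ec50 + doses[2] / curves[[2]]$ec50
    expect_equal(solve_occupancy(curves, doses), S / (1 + S),
                 tolerance = 1e-10)
  }
  # two compounds each at their EC50: S = 2, o = 2/3
  curves <- list(marginal_curve(0, 1, 3, 1), marginal_curve(0, 1, 5, 1))
  expect_equal(solve_occupancy(curves, c(3, 5)), 2 / 3, tolerance = 1e-10)
})

test_that("single compounds and zero doses reduce to the marginal Hill", {
  set.seed(32)
  for (i in 1:10) {
    crv <- random_curve()
    expect_equal(solve_occupancy(list(crv), crv$ec50), 0.5,
                 tolerance = 1e-10)
    # partner at dose zero contributes nothing
    other <- random_curve(crv$b)
    cc <- 10^runif(1, -2, 2)
    expect_equal(solve_occupancy(list(crv, other), c(cc, 0)),
                 occupancy(crv, cc), tolerance = 1e-10)
  }
  expect_equal(solve_occupancy(random_curve_pair(), c(0, 0)), 0)
  expect_error(solve_occupancy(random_curve_pair(), c(-1, 1)),
               "non-negative")
})

test_that("sham self-combinations are additive by construction", {
  set.seed(33)
  for (i in 1:20) {
    crv <- random_curve()
    curves <- list(crv, crv)
    c1 <- 10^runif(1, -2, 2); c2 <- 10^runif(1, -2, 2)
    expect_equal(solve_occupancy(curves, c(c1, c2)),
                 occupancy(crv, c1 + c2), tolerance = 1e-8)
    expect_equal(predict_readout(curves, c(c1, c2))$readout,
                 readout(crv, c1 + c2), tolerance = 1e-8)
  }
})

test_that("equal maximal effects reduce to classical Loewe", {
  set.seed(34)
  for (i in 1:20) {
    b <- runif(1, -0.2, 0.4)
    m <- b + sample(c(-1, 1), 1) * runif(1, 0.3, 1.2)
    curves <- list(marginal_curve(b, m, 10^runif(1, -1, 1), runif(1, 0.5, 3)),
                   marginal_curve(b, m, 10^runif(1, -1, 1), runif(1, 0.5, 3)))
    doses <- 10^runif(2, -1.5, 1.5)
    pr <- predict_readout(curves, doses)
    # closed-form reduction b + o (m - b) ...
    expect_equal(pr$readout, b + pr$occupancy * (m - b), tolerance = 1e-10)
    # ... agrees with the independent readout-form root-finding oracle
    expect_equal(pr$readout, classical_loewe_readout(curves, doses),
                 tolerance = 1e-8)
  }
})

test_that("partial and neutral agonists blend by occupancy weights", {
  # hand-derived case: agonist + neutral antagonist, both at their EC50
  curves <- list(marginal_curve(0, 1, 1, 1), marginal_curve(0, 0, 1, 1))
  pr <- predict_readout(curves, c(1, 1))
  expect_equal(pr$occupancy, 2 / 3, tolerance = 1e-10)
  expect_equal(unname(pr$weights), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(pr$readout, 1 / 3, tolerance = 1e-10)

  # weights always sum to one over the compounds present
  set.seed(35)
  for (i in 1:15) {
    curves <- random_curve_pair()
    pr <- predict_readout(curves, 10^runif(2, -2, 2))
    expect_equal(sum(pr$weights), 1, tolerance = 1e-8)
  }

  # untreated point returns the baseline with no weights
  pr0 <- predict_readout(curves, c(0, 0))
  expect_equal(pr0$readout, curves[[1]]$b)
  expect_true(all(is.na(pr0$weights)))
})

test_that("occupancy is monotone in every dose", {
  set.seed(36)
  for (i in 1:10) {
    curves <- random_curve_pair()
    base <- 10^runif(2, -1, 1)
    for (j in 1:2) {
      doses <- matrix(rep(base, each = 8), ncol = 2)
      doses[, j] <- base[j] * 2^(0:7)
      o <- solve_occupancy(curves, doses)
      expect_true(all(diff(o) > -1e-12))
    }
  }
})

test_that("three or more compounds are handled by the same equations", {
  b <- 0.1
  curves <- list(marginal_curve(b, 1, 1, 1), marginal_curve(b, 0.7, 2, 1),
                 marginal_curve(b, 0.4, 4, 1))
  doses <- c(0.5, 1, 2)
  S <- sum(doses / c(1, 2, 4))
  expect_equal(solve_occupancy(curves, doses), S / (1 + S),
               tolerance = 1e-10)
  pr <- predict_readout(curves, doses)
  expect_equal(sum(pr$weights), 1, tolerance = 1e-8)
})

test_that("surfaces vectorize predictions in grid order", {
  curves <- list(marginal_curve(0.1, 1, 1, 1), marginal_curve(0.1, 0.6, 10, 2))
  grid <- expand.grid(d1 = 2^(-3:3), d2 = 10 * 2^(-3:3))
  surf <- predict_surface(curves, grid)
  expect_identical(nrow(surf), 49L)
  i <- 17
  pr <- predict_readout(curves, unlist(grid[i, ]))
  expect_equal(surf$predicted[i], pr$readout)
  expect_equal(surf$occupancy[i], pr$occupancy)
  # empty grid -> empty surface
  empty <- predict_surface(curves, grid[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("mismatched baselines are rejected", {
  curves <- list(marginal_curve(0, 1, 1, 1), marginal_curve(0.2, 1, 1, 1))
  expect_error(predict_readout(curves, c(1, 1)), "baseline")
  expect_error(predict_surface(curves, data.frame(d1 = 1, d2 = 1)),
               "baseline")
})
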
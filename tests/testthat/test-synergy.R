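# A small reference analysis reused across blocks: default true curves,
# noiseless mono rows, off-axis readouts exactly on the fitted null surface
# unless shifted.
reference_setup <- function(off_shift = 0, off_points = NULL) {
  curves <- list(marginal_curve(0.1, 1.0, 1, 1),
                 marginal_curve(0.1, 0.6, 10, 2))
  mono <- noiseless_board(curves)
  fit <- fit_marginals(mono)
  if (is.null(off_points))
    off_points <- expand.grid(d1 = 2^(-2:2), d2 = 10 * 2^(-2:2))
  surface <- predict_surface(fit$curves, off_points)
  off <- data.frame(off_points, effect = surface$predicted + off_shift)
  board <- checkerboard(rbind(mono, off[, c("d1", "d2", "effect")]))
  list(board = board, fit = fit, surface = surface)
}

test_that("deviations are replicate means minus predictions", {
  rs <- reference_setup()
  dev <- compute_deviations(rs$board, rs$surface, rs$fit)
  expect_equal(dev$d, rep(0, dev$k))
  expect_identical(dev$n_reps, rep(1L, dev$k))
  expect_identical(dev$k, 25L)
  expect_identical(dev$df, rs$fit$df)

  # two replicates at a single point against a fabricated prediction
  mono <- noiseless_board(list(marginal_curve(0.1, 1.0, 1, 1),
                               marginal_curve(0.1, 0.6, 10, 2)))
  board <- checkerboard(rbind(mono,
    data.frame(d1 = c(1, 1), d2 = c(10, 10), effect = c(0.4, 0.6))))
  surface <- data.frame(d1 = 1, d2 = 10, predicted = 0.3)
  dev2 <- compute_deviations(board, surface, fit_marginals(mono))
  expect_equal(dev2$d, 0.2)
  expect_identical(dev2$n_reps, 2L)

  # missing predictions are an error
  expect_error(compute_deviations(rs$board, rs$surface[-1, ], rs$fit),
               "missing predictions")
})

test_that("Cp bootstrap quantifies prediction uncertainty", {
  spec <- simulation_spec(seed = 41)
  board <- generate_board(spec)
  fit <- fit_marginals(board)
  off <- board_view(board, "off_axis")[, c("d1", "d2")]

  cp <- estimate_cp(fit, off, n_boot = 100, seed = 7)
  expect_identical(dim(unclass(cp)), c(49L, 49L))
  expect_true(all(diag(cp) >= 0))
  expect_equal(as.matrix(cp), t(as.matrix(cp)))
  ev <- eigen(cp, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-10 * max(ev))

  # deterministic given the seed
  cp_again <- estimate_cp(fit, off, n_boot = 100, seed = 7)
  expect_identical(as.matrix(cp), as.matrix(cp_again))

  # Monte-Carlo self-consistency against a larger reference run
  cp_big <- estimate_cp(fit, off, n_boot = 600, seed = 8)
  expect_lt(max(abs(cp - cp_big)), 0.4 * max(diag(cp_big)))
  expect_lt(abs(sum(diag(cp)) / sum(diag(cp_big)) - 1), 0.35)

  # zero residual variance leaves no estimation uncertainty
  rs <- reference_setup()
  cp0 <- estimate_cp(rs$fit, off, n_boot = 20, seed = 1)
  expect_lt(max(abs(cp0)), 1e-12)
})

test_that("MeanR is zero with p = 1 on perfectly additive data", {
  rs <- reference_setup()
  dev <- compute_deviations(rs$board, rs$surface, rs$fit)
  cp <- matrix(0, dev$k, dev$k)
  for (nm in c("parametric", "bootstrap")) {
    mr <- meanR_test(dev, cp, null_method = nm, n_boot_null = 50, seed = 1)
    expect_equal(mr$statistic, 0)
    expect_equal(mr$p_value, 1)
    expect_false(mr$reject)
  }
})

test_that("parametric MeanR p-values decrease in the statistic", {
  spec <- simulation_spec(seed = 42)
  board <- generate_board(spec)
  fit <- fit_marginals(board)
  off <- board_view(board, "off_axis")[, c("d1", "d2")]
  surface <- predict_surface(fit$curves, off)
  dev <- compute_deviations(board, surface, fit)
  cp <- estimate_cp(fit, off, n_boot = 50, seed = 2)
  ps <- vapply(c(1, 2, 4), function(sc) {
    d2 <- dev
    d2$d <- dev$d * sc
    meanR_test(d2, cp, null_method = "parametric")$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("MaxR localizes a single spiked deviation with direction", {
  rs <- reference_setup()
  board <- rs$board
  idx <- which(board$d1 == 1 & board$d2 == 10)
  board$effect[idx] <- board$effect[idx] - 0.3  # stronger-than-predicted
  fit <- rs$fit
  # noiseless mono fit has sigma2 ~ 0; emulate a realistically noisy fit
  fit$sigma2 <- 0.045^2
  dev <- compute_deviations(board, rs$surface, fit)
  cp <- estimate_cp(fit, rs$surface[, c("d1", "d2")], n_boot = 50, seed = 3)
  mx <- maxR_test(dev, cp, null_method = "parametric", seed = 4,
                  decreasing_effect = TRUE)
  flagged <- mx$calls[mx$calls$call != "additive", ]
  expect_identical(nrow(flagged), 1L)
  expect_equal(c(flagged$d1, flagged$d2), c(1, 10))
  expect_identical(flagged$call, "synergy")
  expect_true(mx$reject)
  # internal consistency: calls are exactly the threshold exceedances
  expect_identical(mx$calls$call != "additive", abs(mx$t) > mx$crit)
  # reversing the direction convention flips the label
  mx2 <- maxR_test(dev, cp, null_method = "parametric", seed = 4,
                   decreasing_effect = FALSE)
  expect_identical(mx2$calls$call[mx2$calls$call != "additive"],
                   "antagonism")
})

test_that("bootstrap p-values are reproducible and agree with parametric", {
  spec <- simulation_spec(n_reps = 3, seed = 43)
  board <- generate_board(spec)
  r1 <- run_synergy_analysis(board, null_method = "bootstrap",
                             n_boot_null = 300, n_boot_cp = 50, seed = 99)
  r2 <- run_synergy_analysis(board, null_method = "bootstrap",
                             n_boot_null = 300, n_boot_cp = 50, seed = 99)
  expect_identical(r1$meanR$p_value, r2$meanR$p_value)
  expect_identical(r1$maxR$p_value, r2$maxR$p_value)

  rp <- run_synergy_analysis(board, null_method = "parametric",
                             n_boot_cp = 50, seed = 99)
  expect_lt(abs(rp$meanR$p_value - r1$meanR$p_value), 0.15)
})

test_that("the pipeline orchestrates fit, filter, surface and tests", {
  # sham board without noise is called additive
  crv <- marginal_curve(0.1, 1, 1, 1)
  sham <- generate_board(simulation_spec(curves = list(crv, crv),
                                         noise_sd = 0, seed = 5))
  res <- run_synergy_analysis(sham, null_method = "bootstrap",
                              n_boot_null = 50, n_boot_cp = 20, seed = 5)
  expect_identical(res$status, "ok")
  expect_identical(res$overall_call, "additive")
  expect_equal(res$meanR$statistic, 0)

  # automatic null choice: bootstrap without replicates, parametric with
  b1 <- generate_board(simulation_spec(seed = 6))
  r1 <- run_synergy_analysis(b1, n_boot_null = 50, n_boot_cp = 20, seed = 6)
  expect_identical(r1$null_method, "bootstrap")
  b3 <- generate_board(simulation_spec(n_reps = 2, seed = 6))
  r3 <- run_synergy_analysis(b3, n_boot_cp = 20, seed = 6)
  expect_identical(r3$null_method, "parametric")

  # a noisy flat board (unidentified EC50s) is invalidated, not tested
  flat <- data.frame(
    d1 = c(0, 1, 2, 4, 8, 16, rep(0, 5), 1, 2),
    d2 = c(rep(0, 6), 1, 2, 4, 8, 16, 1, 2),
    effect = 0.3 + 0.05 * rep(c(1, -1), length.out = 13))
  inv <- run_synergy_analysis(flat)
  expect_identical(inv$status, "invalidated")
  expect_false(inv$qc$pass)
  expect_null(inv$meanR)

  # injected strong excess effect on a replicated board yields synergy
  syn <- generate_board(simulation_spec(n_reps = 3, deviation = -0.2,
                                        seed = 7))
  rs <- run_synergy_analysis(syn, n_boot_cp = 50, seed = 7)
  expect_identical(rs$overall_call, "synergy")
  expect_true(rs$meanR$reject)
})
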
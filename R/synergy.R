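#' Observed-minus-predicted deviations at the off-axis points
#'
#' Aggregates the off-axis (both-doses-positive) wells of a checkerboard by
#' dose combination, averages replicates, and subtracts the null-surface
#' prediction at each combination. The result carries the residual variance
#' and degrees of freedom of the marginal fit, which calibrate the synergy
#' tests.
#'
#' @param board A [checkerboard()].
#' @param surface A [predict_surface()] result covering every off-axis
#'   dose combination of the board.
#' @param fit The [fit_marginals()] result the surface was built from.
#' @return A list of class `offaxis_dev`: `points` (data.frame `d1`, `d2`),
#'   `observed`, `predicted`, `d` (deviation vector), `n_reps`, `k`,
#'   `sigma2`, `df`, and the originating `fit`.
#' @export
compute_deviations <- function(board, surface, fit) {
  board <- checkerboard(board)
  if (!inherits(fit, "marginal_fit")) stop_invalid("fit must be a marginal_fit")
  off <- board_view(board, "off_axis")
  if (!nrow(off)) stop_invalid("board has no off-axis points")
  key <- paste(sprintf("%.17g", off$d1), sprintf("%.17g", off$d2))
  first <- !duplicated(key)
  pts <- off[first, c("d1", "d2")]
  ukey <- key[first]
  observed <- as.numeric(tapply(off$effect, factor(key, levels = ukey), mean))
  n_reps <- as.integer(tapply(off$effect, factor(key, levels = ukey), length))
  skey <- paste(sprintf("%.17g", surface$d1), sprintf("%.17g", surface$d2))
  idx <- match(ukey, skey)
  if (anyNA(idx))
    stop_invalid("surface is missing predictions for ", sum(is.na(idx)),
                 " off-axis dose combination(s)")
  predicted <- surface$predicted[idx]
  structure(list(
    points = `rownames<-`(pts, NULL), observed = observed,
    predicted = predicted, d = observed - predicted, n_reps = n_reps,
    k = nrow(pts), sigma2 = fit$sigma2, df = fit$df, fit = fit),
    class = "offaxis_dev")
}

#' Bootstrap covariance of the predicted null surface
#'
#' The predicted off-axis readouts inherit uncertainty from the estimated
#' marginal parameters. This is quantified by a parametric residual
#' bootstrap: mono-therapy readouts are resampled as fitted values plus
#' centered Gaussian noise with the fitted residual variance, the
#' shared-baseline model is refitted, and the null surface recomputed; the
#' empirical covariance of the predicted vectors across resamples is the
#' Cp matrix entering the test variance `V = sigma2 * diag(1/n) + Cp`.
#'
#' @param fit A converged [fit_marginals()] result (carries the
#'   mono-therapy design and data).
#' @param grid Data.frame of off-axis dose combinations (`d1`, `d2`).
#' @param n_boot Number of bootstrap refits (>= 2).
#' @param seed Optional seed; given the same seed the matrix is
#'   reproduced exactly.
#' @param max_fail_frac Maximum tolerated fraction of failed refits.
#' @return A `k x k` matrix of class `cp_matrix` with attributes `n_boot`
#'   (successful resamples) and `n_failed`.
#' @export
estimate_cp <- function(fit, grid, n_boot = 100, seed = NULL,
                        max_fail_frac = 0.1) {
  if (!inherits(fit, "marginal_fit")) stop_invalid("fit must be a marginal_fit")
  if (!is.numeric(n_boot) || n_boot < 2) stop_invalid("n_boot must be >= 2")
  D <- as_dose_matrix(grid, length(fit$curves))
  n <- length(fit$fitted)
  sd_res <- sqrt(fit$sigma2)
  with_seed(seed, {
    preds <- matrix(NA_real_, n_boot, nrow(D))
    failed <- 0L
    for (b in seq_len(n_boot)) {
      ystar <- fit$fitted + stats::rnorm(n, 0, sd_res)
      rf <- refit_marginals(fit, ystar)
      if (is.null(rf)) { failed <- failed + 1L; next }
      preds[b, ] <- predict_surface(rf$curves, D)$predicted
    }
    if (failed / n_boot > max_fail_frac)
      stop_fit_failure(sprintf(
        "Cp bootstrap: %d of %d refits failed (tolerance %.0f%%)",
        failed, n_boot, 100 * max_fail_frac))
    ok <- !is.na(preds[, 1])
    cp <- stats::cov(preds[ok, , drop = FALSE])
    structure(cp, class = c("cp_matrix", class(cp)),
              n_boot = sum(ok), n_failed = failed)
  })
}

# V = sigma2 diag(1/n_reps) + Cp, with a small diagonal ridge escalated
# until the Cholesky factorization succeeds (a rank-deficient bootstrap Cp
# at small n_boot can leave V numerically semi-definite).
build_test_variance <- function(dev, cp) {
  k <- dev$k
  cp <- as.matrix(cp)
  if (!all(dim(cp) == c(k, k)))
    stop_invalid("Cp matrix dimension (", nrow(cp), ") does not match the ",
                 k, " off-axis points")
  cp <- (cp + t(cp)) / 2
  V <- dev$sigma2 * diag(1 / dev$n_reps, k) + cp
  ridge <- max(1e-10 * sum(diag(V)) / k, 1e-30)
  for (attempt in 0:3) {
    ch <- tryCatch(chol(V + diag(ridge * (attempt > 0) * 100^attempt, k)),
                   error = function(e) NULL)
    if (!is.null(ch))
      return(list(V = V, chol = ch, Vinv = chol2inv(ch)))
  }
  stop_numerical("test variance matrix is singular even after regularization")
}

# A board fitted essentially exactly (residual sd and every deviation below
# double-precision resolution of the readout scale) carries no evidence
# against additivity: the computed deviations are rounding noise, not data.
# Both tests then report a zero statistic with p = 1 instead of comparing
# machine noise against machine noise.
degenerate_null <- function(dev) {
  tol <- 1e-8 * max(1, abs(dev$observed), abs(dev$predicted))
  sqrt(dev$sigma2) < tol && max(abs(dev$d)) < tol
}

#' Shared bootstrap null distribution for the MeanR and MaxR statistics
#'
#' Generates synthetic additive experiments under the fitted null: each run
#' resamples the mono-therapy readouts (fitted values plus centered
#' Gaussian noise with the fitted residual variance), refits the marginals
#' and re-predicts the surface, and samples off-axis readout errors from
#' the same centered Gaussian. Both test statistics are recomputed per run
#' with the test variance rescaled by the resampled residual variance, so
#' the null draws carry every estimation-noise source the observed
#' statistic does. One set of draws serves both tests.
#'
#' @param dev A [compute_deviations()] result.
#' @param cp A [estimate_cp()] matrix.
#' @param n_boot Number of null experiments.
#' @param seed Optional seed for exact reproducibility.
#' @param max_fail_frac Maximum tolerated fraction of failed refits.
#' @return A list of class `boot_null` with `mean_stats`, `max_stats`,
#'   `n_boot` (successful runs) and `n_failed`.
#' @export
bootstrap_null_stats <- function(dev, cp, n_boot = 1000, seed = NULL,
                                 max_fail_frac = 0.1) {
  if (!inherits(dev, "offaxis_dev"))
    stop_invalid("dev must come from compute_deviations()")
  if (degenerate_null(dev))
    return(structure(list(mean_stats = rep(0, n_boot),
                          max_stats = rep(0, n_boot),
                          n_boot = n_boot, n_failed = 0L),
                     class = "boot_null"))
  vv <- build_test_variance(dev, cp)
  fit <- dev$fit
  k <- dev$k
  n <- length(fit$fitted)
  sd_res <- sqrt(dev$sigma2)
  sd_off <- sqrt(dev$sigma2 / dev$n_reps)
  diagV <- diag(vv$V)
  D <- as.matrix(dev$points)
  with_seed(seed, {
    mean_stats <- max_stats <- rep(NA_real_, n_boot)
    failed <- 0L
    for (b in seq_len(n_boot)) {
      ystar <- fit$fitted + stats::rnorm(n, 0, sd_res)
      rf <- refit_marginals(fit, ystar)
      if (is.null(rf)) { failed <- failed + 1L; next }
      pred_star <- predict_surface(rf$curves, D)$predicted
      dstar <- dev$predicted + stats::rnorm(k, 0, sd_off) - pred_star
      s <- rf$sigma2 / dev$sigma2
      mean_stats[b] <- drop(crossprod(dstar, vv$Vinv %*% dstar)) / (k * s)
      max_stats[b] <- max(abs(dstar) / sqrt(s * diagV))
    }
    if (failed / n_boot > max_fail_frac)
      stop_fit_failure(sprintf(
        "null bootstrap: %d of %d refits failed (tolerance %.0f%%)",
        failed, n_boot, 100 * max_fail_frac))
    ok <- !is.na(mean_stats)
    structure(list(mean_stats = mean_stats[ok], max_stats = max_stats[ok],
                   n_boot = sum(ok), n_failed = failed),
              class = "boot_null")
  })
}

#' MeanR test: average deviation from the null surface
#'
#' Tests whether the off-axis readouts deviate from the generalized-Loewe
#' prediction on average, via the quadratic-form statistic
#' \deqn{M = d^\top V^{-1} d / k, \qquad V = \hat\sigma^2\,
#'   \mathrm{diag}(1/n_i) + C_p,}
#' where `d` is the vector of mean observed minus predicted readouts over
#' the `k` off-axis combinations. Under the null and normally distributed
#' residuals, `M` is referred to an `F(k, df)` distribution (`df` being
#' the residual degrees of freedom of the marginal fit); alternatively the
#' null is approximated by the full-pipeline bootstrap of
#' [bootstrap_null_stats()], with the `(r + 1)/(B + 1)` p-value estimator.
#'
#' @param dev A [compute_deviations()] result.
#' @param cp A [estimate_cp()] matrix.
#' @param alpha Significance level.
#' @param null_method `"parametric"` or `"bootstrap"`.
#' @param n_boot_null Bootstrap runs for the null (bootstrap method only).
#' @param seed Optional seed (bootstrap method only).
#' @param boot_stats Optional precomputed [bootstrap_null_stats()] draws,
#'   shared with [maxR_test()].
#' @return A list of class `meanR_test` with `statistic`, `p_value`,
#'   `reject`, `k`, `df`, `alpha` and `null_method`.
#' @export
meanR_test <- function(dev, cp, alpha = 0.05,
                       null_method = c("parametric", "bootstrap"),
                       n_boot_null = 1000, seed = NULL, boot_stats = NULL) {
  null_method <- match.arg(null_method)
  check_number(alpha, "alpha", min = 0, strict = TRUE)
  if (degenerate_null(dev)) {
    return(structure(list(statistic = 0, p_value = 1, reject = FALSE,
                          k = dev$k, df = dev$df, alpha = alpha,
                          null_method = null_method, n_boot = NA_integer_),
                     class = "meanR_test"))
  }
  vv <- build_test_variance(dev, cp)
  stat <- drop(crossprod(dev$d, vv$Vinv %*% dev$d)) / dev$k
  if (null_method == "parametric") {
    p <- stats::pf(stat, dev$k, dev$df, lower.tail = FALSE)
    B <- NA_integer_
  } else {
    if (is.null(boot_stats))
      boot_stats <- bootstrap_null_stats(dev, cp, n_boot_null, seed)
    B <- boot_stats$n_boot
    p <- (sum(boot_stats$mean_stats >= stat) + 1) / (B + 1)
  }
  structure(list(statistic = stat, p_value = p, reject = p <= alpha,
                 k = dev$k, df = dev$df, alpha = alpha,
                 null_method = null_method, n_boot = B),
            class = "meanR_test")
}

#' MaxR test: largest standardized deviation, with per-point calls
#'
#' Tests the largest absolute standardized deviation
#' \deqn{T = \max_i |t_i|, \qquad t_i = d_i / \sqrt{V_{ii}},}
#' and localizes synergy/antagonism: point `i` is called non-additive when
#' `|t_i|` exceeds the `(1 - alpha)` quantile of the null distribution of
#' the maximum — a built-in familywise multiplicity control across the
#' grid. The parametric null samples multivariate normal vectors with the
#' correlation structure of `V`, each draw scaled by
#' `sqrt(df / chi-squared_df)` to account for the few residual degrees of
#' freedom behind `sigma2` (`V` scales with the residual variance); the
#' bootstrap null reuses the [bootstrap_null_stats()] draws.
#'
#' Call direction follows the configured effect direction: with
#' `decreasing_effect = TRUE` (growth/viability readouts, lower readout =
#' stronger effect) an observed readout below the prediction is synergy.
#'
#' @inheritParams meanR_test
#' @param decreasing_effect Does a stronger effect lower the readout?
#' @param n_param_draws Monte-Carlo draws for the parametric max-null.
#' @return A list of class `maxR_test` with `statistic`, `p_value`,
#'   `reject`, `crit` (per-point call threshold), `t` (standardized
#'   deviations) and `calls` (data.frame `d1`, `d2`, `observed`,
#'   `predicted`, `t`, `call`).
#' @export
maxR_test <- function(dev, cp, alpha = 0.05,
                      null_method = c("parametric", "bootstrap"),
                      n_boot_null = 1000, seed = NULL,
                      decreasing_effect = TRUE, boot_stats = NULL,
                      n_param_draws = 2000) {
  null_method <- match.arg(null_method)
  check_number(alpha, "alpha", min = 0, strict = TRUE)
  if (degenerate_null(dev)) {
    calls <- data.frame(dev$points, observed = dev$observed,
                        predicted = dev$predicted, t = rep(0, dev$k),
                        call = rep("additive", dev$k),
                        stringsAsFactors = FALSE)
    return(structure(list(statistic = 0, p_value = 1, reject = FALSE,
                          crit = Inf, t = rep(0, dev$k), calls = calls,
                          k = dev$k, df = dev$df, alpha = alpha,
                          null_method = null_method, n_draws = NA_integer_,
                          decreasing_effect = decreasing_effect),
                     class = "maxR_test"))
  }
  vv <- build_test_variance(dev, cp)
  t_i <- dev$d / sqrt(diag(vv$V))
  stat <- max(abs(t_i))
  if (null_method == "parametric") {
    R <- stats::cov2cor(vv$V)
    chR <- tryCatch(chol(R), error = function(e)
      chol(R + diag(1e-8, dev$k)))
    draws <- with_seed(seed, {
      Z <- matrix(stats::rnorm(n_param_draws * dev$k), n_param_draws) %*% chR
      scale <- sqrt(dev$df / stats::rchisq(n_param_draws, dev$df))
      apply(abs(Z), 1, max) * scale
    })
  } else {
    if (is.null(boot_stats))
      boot_stats <- bootstrap_null_stats(dev, cp, n_boot_null, seed)
    draws <- boot_stats$max_stats
  }
  B <- length(draws)
  p <- (sum(draws >= stat) + 1) / (B + 1)
  crit <- sort(draws)[ceiling((1 - alpha) * B)]
  synergy_sign <- if (decreasing_effect) -1 else 1
  call <- ifelse(abs(t_i) <= crit, "additive",
                 ifelse(sign(dev$d) == synergy_sign, "synergy",
                        "antagonism"))
  calls <- data.frame(dev$points, observed = dev$observed,
                      predicted = dev$predicted, t = t_i, call = call,
                      stringsAsFactors = FALSE)
  structure(list(statistic = stat, p_value = p, reject = p <= alpha,
                 crit = crit, t = t_i, calls = calls, k = dev$k,
                 df = dev$df, alpha = alpha, null_method = null_method,
                 n_draws = B, decreasing_effect = decreasing_effect),
            class = "maxR_test")
}

#' Full synergy analysis of a checkerboard experiment
#'
#' Runs the whole pipeline: shared-baseline marginal fit, log(EC50)
#' quality filter (analysis is aborted with status `"invalidated"` on
#' failure), generalized-Loewe null surface at every off-axis combination,
#' Cp bootstrap, and the MeanR and MaxR tests at level `alpha`. With
#' `null_method = "auto"` the parametric null is used when any off-axis
#' point has replicates and the bootstrap null otherwise (replication is
#' what makes the normal-theory reference trustworthy at small boards).
#' The overall call is driven by MeanR (the omnibus test); MaxR localizes
#' the responsible dose combinations.
#'
#' @param board A [checkerboard()] (or coercible data.frame).
#' @param alpha Significance level (default 0.05).
#' @param null_method `"auto"`, `"parametric"` or `"bootstrap"`.
#' @param n_boot_null Bootstrap runs for the test null distributions.
#' @param n_boot_cp Bootstrap runs for the Cp matrix.
#' @param seed Optional seed; the same seed gives byte-identical results.
#' @param log_transform Apply [growth_transform()] to all readouts first.
#' @param qc_threshold [quality_filter()] threshold on sd(log EC50).
#' @param decreasing_effect Effect-direction convention, see [maxR_test()].
#' @return A list of class `synergy_result` with `status` (`"ok"` or
#'   `"invalidated"`), `fit`, `qc`, `surface`, `deviations`, `cp`,
#'   `meanR`, `maxR`, `calls`, `overall_call`, resolved `null_method`,
#'   `alpha`, `seed` and a `config` echo.
#' @export
run_synergy_analysis <- function(board, alpha = 0.05,
                                 null_method = c("auto", "parametric",
                                                 "bootstrap"),
                                 n_boot_null = 1000, n_boot_cp = 100,
                                 seed = NULL, log_transform = FALSE,
                                 qc_threshold = 10,
                                 decreasing_effect = TRUE) {
  null_method <- match.arg(null_method)
  board <- checkerboard(board)
  if (log_transform) board$effect <- growth_transform(board$effect)
  config <- list(alpha = alpha, null_method = null_method,
                 n_boot_null = n_boot_null, n_boot_cp = n_boot_cp,
                 log_transform = log_transform, qc_threshold = qc_threshold,
                 decreasing_effect = decreasing_effect)

  fit <- fit_marginals(board)
  qc <- quality_filter(fit, qc_threshold)
  base <- list(fit = fit, qc = qc, alpha = alpha, seed = seed,
               config = config)
  if (!qc$pass) {
    return(structure(c(list(status = "invalidated", overall_call = NA_character_,
                            null_method = NA_character_),
                       base),
                     class = "synergy_result"))
  }

  off <- board_view(board, "off_axis")
  key <- paste(sprintf("%.17g", off$d1), sprintf("%.17g", off$d2))
  grid <- off[!duplicated(key), c("d1", "d2")]
  surface <- predict_surface(fit$curves, grid)
  dev <- compute_deviations(board, surface, fit)
  cp <- estimate_cp(fit, grid, n_boot = n_boot_cp,
                    seed = derive_seed(seed, 1L))

  resolved <- null_method
  if (resolved == "auto")
    resolved <- if (any(dev$n_reps >= 2)) "parametric" else "bootstrap"
  boot_stats <- NULL
  if (resolved == "bootstrap" && !degenerate_null(dev))
    boot_stats <- bootstrap_null_stats(dev, cp, n_boot_null,
                                       seed = derive_seed(seed, 2L))
  meanR <- meanR_test(dev, cp, alpha, resolved, n_boot_null,
                      seed = derive_seed(seed, 2L), boot_stats = boot_stats)
  maxR <- maxR_test(dev, cp, alpha, resolved, n_boot_null,
                    seed = derive_seed(seed, 3L),
                    decreasing_effect = decreasing_effect,
                    boot_stats = boot_stats)

  overall <- "additive"
  if (meanR$reject) {
    synergy_sign <- if (decreasing_effect) -1 else 1
    overall <- if (sign(sum(maxR$t)) == synergy_sign) "synergy"
               else "antagonism"
  }
  structure(c(list(status = "ok", surface = surface, deviations = dev,
                   cp = cp, meanR = meanR, maxR = maxR,
                   calls = maxR$calls, overall_call = overall,
                   null_method = resolved),
              base),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("Generalized-Loewe synergy analysis\n")
  if (x$status == "invalidated") {
    cat("  status: INVALIDATED by the quality filter\n")
    for (r in x$qc$reasons) cat("   ", r, "\n")
    return(invisible(x))
  }
  cat(sprintf("  null distribution: %s; alpha = %g\n", x$null_method,
              x$alpha))
  cat(sprintf("  MeanR: statistic = %.4g, p = %.4g\n",
              x$meanR$statistic, x$meanR$p_value))
  cat(sprintf("  MaxR : statistic = %.4g, p = %.4g (call threshold %.3g)\n",
              x$maxR$statistic, x$maxR$p_value, x$maxR$crit))
  ncalls <- sum(x$calls$call != "additive")
  cat(sprintf("  off-axis points called non-additive: %d of %d\n",
              ncalls, nrow(x$calls)))
  cat(sprintf("  overall call: %s\n", x$overall_call))
  invisible(x)
}
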
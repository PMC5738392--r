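#' Specification of a synthetic checkerboard experiment
#'
#' Describes the ground truth from which [generate_board()] simulates a
#' two-compound checkerboard: the true marginal curves (shared baseline),
#' the dose grid, the replicate count, the homoscedastic Gaussian noise
#' level, and an optional additive deviation injected at the off-axis
#' points (zero = additive truth, negative values push the readout in the
#' synergy direction under the decreasing-effect convention... direction
#' depends on the convention chosen at analysis time).
#'
#' Defaults mirror a typical growth-inhibition checkerboard: an 8 x 8
#' design (seven 2-fold dilutions per compound centered on the EC50, plus
#' dose zero), a full agonist paired with a partial agonist
#' (`b = 0.1`, `m = (1.0, 0.6)`, `ec50 = (1, 10)`, `hill = (1, 2)`),
#' a single replicate, and noise with standard deviation 0.045 — 5% of
#' the full agonist's dynamic range.
#'
#' @param curves List of two [marginal_curve()]s sharing a baseline.
#' @param dose_grid List of two numeric vectors of doses (including 0) or
#'   `NULL` for the default EC50-centered 2-fold series.
#' @param n_reps Replicates per well.
#' @param noise_sd Readout noise standard deviation (readout units).
#' @param deviation Scalar additive shift applied to every off-axis
#'   readout, or a data.frame `d1`, `d2`, `delta` shifting specific
#'   points.
#' @param seed Optional seed making the generated board reproducible.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(curves = NULL, dose_grid = NULL, n_reps = 1,
                            noise_sd = 0.045, deviation = 0, seed = NULL) {
  if (is.null(curves))
    curves <- list(marginal_curve(0.1, 1.0, 1, 1),
                   marginal_curve(0.1, 0.6, 10, 2))
  curves <- check_curve_list(curves)
  if (length(curves) != 2L)
    stop_invalid("simulation_spec supports two-compound boards")
  shared_baseline(curves)
  if (is.null(dose_grid))
    dose_grid <- lapply(curves, function(cv) c(0, cv$ec50 * 2^(-3:3)))
  if (!is.list(dose_grid) || length(dose_grid) != 2L)
    stop_invalid("dose_grid must be a list of two dose vectors")
  for (j in 1:2) {
    dj <- dose_grid[[j]]
    if (anyNA(dj) || any(dj < 0))
      stop_invalid("dose grid for compound ", j, " must be non-negative")
    if (length(unique(dj[dj > 0])) < 4)
      stop_invalid("dose grid for compound ", j,
                   " needs at least 4 distinct nonzero doses")
    dose_grid[[j]] <- sort(unique(dj))
  }
  check_number(noise_sd, "noise_sd", min = 0)
  if (!is.numeric(n_reps) || n_reps < 1) stop_invalid("n_reps must be >= 1")
  if (is.data.frame(deviation)) {
    if (!all(c("d1", "d2", "delta") %in% names(deviation)))
      stop_invalid("deviation data.frame needs columns d1, d2, delta")
    if (anyNA(deviation$delta) || any(!is.finite(deviation$delta)))
      stop_invalid("deviation must be finite")
  } else check_number(deviation, "deviation")
  structure(list(curves = curves, dose_grid = dose_grid,
                 n_reps = as.integer(n_reps), noise_sd = noise_sd,
                 deviation = deviation, seed = seed),
            class = "simulation_spec")
}

#' Simulate a checkerboard experiment from known ground truth
#'
#' Mono-therapy and untreated readouts are the true 4PLL values; off-axis
#' readouts are the generalized-Loewe prediction from the true curves plus
#' the injected deviation. Homoscedastic Gaussian noise is added to every
#' well. Identical spec and seed give an identical board; the noiseless
#' true values are attached as attribute `"truth"`.
#'
#' @param spec A [simulation_spec()].
#' @return A [checkerboard()] with a `replicate` column.
#' @export
generate_board <- function(spec) {
  if (!inherits(spec, "simulation_spec"))
    stop_invalid("spec must be a simulation_spec")
  grid <- expand.grid(d1 = spec$dose_grid[[1]], d2 = spec$dose_grid[[2]],
                      KEEP.OUT.ATTRS = FALSE)
  truth <- numeric(nrow(grid))
  b <- spec$curves[[1]]$b
  m1 <- grid$d1 > 0 & grid$d2 == 0
  m2 <- grid$d2 > 0 & grid$d1 == 0
  off <- grid$d1 > 0 & grid$d2 > 0
  truth[grid$d1 == 0 & grid$d2 == 0] <- b
  truth[m1] <- readout(spec$curves[[1]], grid$d1[m1])
  truth[m2] <- readout(spec$curves[[2]], grid$d2[m2])
  truth[off] <- predict_surface(spec$curves,
                                grid[off, , drop = FALSE])$predicted
  if (is.data.frame(spec$deviation)) {
    key <- paste(sprintf("%.17g", grid$d1), sprintf("%.17g", grid$d2))
    dkey <- paste(sprintf("%.17g", spec$deviation$d1),
                  sprintf("%.17g", spec$deviation$d2))
    idx <- match(dkey, key)
    if (anyNA(idx))
      stop_invalid("deviation names dose combinations absent from the grid")
    if (any(!off[idx]))
      stop_invalid("deviation may only be injected at off-axis points")
    truth[idx] <- truth[idx] + spec$deviation$delta
  } else if (spec$deviation != 0) {
    truth[off] <- truth[off] + spec$deviation
  }
  reps <- spec$n_reps
  board <- data.frame(
    d1 = rep(grid$d1, each = reps),
    d2 = rep(grid$d2, each = reps),
    effect = rep(truth, each = reps),
    replicate = rep(seq_len(reps), times = nrow(grid)))
  board$effect <- with_seed(spec$seed,
    board$effect + stats::rnorm(nrow(board), 0, spec$noise_sd))
  out <- checkerboard(board)
  attr(out, "truth") <- data.frame(grid, true_effect = truth)
  out
}

#' Type-I error study on simulated additive boards
#'
#' Simulates `n_sims` additive checkerboards (the spec's deviation is
#' forced to zero), runs the full synergy pipeline on each, and reports
#' the MeanR and MaxR rejection rates at level `alpha` with exact binomial
#' confidence intervals. Board `i` uses seed `seed + i - 1`, which also
#' seeds its bootstrap stages, so the study is fully reproducible. Boards
#' whose marginal fit fails are counted and excluded from the denominator.
#'
#' @param spec A [simulation_spec()] (its `deviation` is set to 0).
#' @param n_sims Number of simulated boards.
#' @param alpha Significance level.
#' @param null_method,n_boot_null,n_boot_cp,decreasing_effect Passed to
#'   [run_synergy_analysis()].
#' @param seed Base seed for the simulation stream.
#' @param conf_level Confidence level of the binomial interval.
#' @return A list of class `typeI_study`: `rates` (data.frame with one
#'   row per test: `test`, `n_sims`, `n_failed`, `rejections`, `rate`,
#'   `ci_low`, `ci_high`), `pvalues` (matrix, one row per board) and the
#'   call settings.
#' @export
run_typeI_study <- function(spec, n_sims = 500, alpha = 0.05,
                            null_method = "bootstrap", n_boot_null = 200,
                            n_boot_cp = 50, seed = 1,
                            decreasing_effect = TRUE, conf_level = 0.95) {
  if (!inherits(spec, "simulation_spec"))
    stop_invalid("spec must be a simulation_spec")
  if (n_sims < 1) stop_invalid("n_sims must be >= 1")
  spec$deviation <- 0
  study <- run_typeI_study_at(spec, n_sims, alpha, null_method, n_boot_null,
                              n_boot_cp, seed, decreasing_effect, conf_level)
  structure(list(rates = study$rates, pvalues = study$pvalues, alpha = alpha,
                 null_method = null_method, seed = seed),
            class = "typeI_study")
}

# Per-board seeds: an arithmetic stream from the study seed, kept < 2^31.
derive_board_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + i - 1) %% 2147483647)
}

#' @export
print.typeI_study <- function(x, ...) {
  cat(sprintf("Type-I error study (alpha = %g, %s null)\n", x$alpha,
              x$null_method))
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Power study over a range of injected deviations
#'
#' For each deviation magnitude, simulates `n_sims` boards with that
#' scalar shift applied to every off-axis readout and records the MeanR
#' and MaxR rejection rates. The zero entry reproduces the type-I rate;
#' rates should grow toward one as the deviation dwarfs the noise.
#'
#' @param spec A [simulation_spec()] providing curves, grid and noise.
#' @param deviations Numeric vector of additive shifts (readout units).
#' @param n_sims Boards per deviation level.
#' @inheritParams run_typeI_study
#' @return A data.frame of class `power_study`: `deviation`, `test`,
#'   `n_sims`, `n_failed`, `rejections`, `rate`, `ci_low`, `ci_high`.
#' @export
run_power_study <- function(spec, deviations, n_sims = 100, alpha = 0.05,
                            null_method = "bootstrap", n_boot_null = 200,
                            n_boot_cp = 50, seed = 1,
                            decreasing_effect = TRUE, conf_level = 0.95) {
  rows <- lapply(seq_along(deviations), function(di) {
    sp <- spec
    sp$deviation <- deviations[di]
    study <- run_typeI_study_at(sp, n_sims, alpha, null_method,
                                n_boot_null, n_boot_cp,
                                derive_seed(seed, di), decreasing_effect,
                                conf_level)
    cbind(deviation = deviations[di], study$rates)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_study", "data.frame")
  out
}

# Same machinery as run_typeI_study but honoring a nonzero deviation.
run_typeI_study_at <- function(spec, n_sims, alpha, null_method,
                               n_boot_null, n_boot_cp, seed,
                               decreasing_effect, conf_level) {
  dev0 <- spec$deviation
  study <- local({
    pv <- matrix(NA_real_, n_sims, 2,
                 dimnames = list(NULL, c("meanR", "maxR")))
    failed <- 0L
    for (i in seq_len(n_sims)) {
      si <- spec
      si$deviation <- dev0
      si$seed <- derive_board_seed(seed, i)
      res <- tryCatch(
        run_synergy_analysis(generate_board(si), alpha = alpha,
                             null_method = null_method,
                             n_boot_null = n_boot_null,
                             n_boot_cp = n_boot_cp, seed = si$seed,
                             decreasing_effect = decreasing_effect),
        genloewe_fit_failure = function(e) NULL)
      if (is.null(res) || res$status != "ok") { failed <- failed + 1L; next }
      pv[i, ] <- c(res$meanR$p_value, res$maxR$p_value)
    }
    ok <- !is.na(pv[, 1])
    rates <- do.call(rbind, lapply(c("meanR", "maxR"), function(tst) {
      rej <- sum(pv[ok, tst] <= alpha)
      ci <- stats::binom.test(rej, sum(ok),
                              conf.level = conf_level)$conf.int
      data.frame(test = tst, n_sims = sum(ok), n_failed = failed,
                 rejections = rej, rate = rej / sum(ok),
                 ci_low = ci[1], ci_high = ci[2])
    }))
    list(rates = rates, pvalues = pv)
  })
  study
}
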
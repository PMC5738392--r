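#' Fit both mono-therapy curves jointly with a shared baseline
#'
#' Fits the two 4PLL marginal curves of a checkerboard experiment by
#' non-linear least squares, subject to the constraint that both compounds
#' share the same baseline readout `b` (the baseline refers to the untreated
#' system, which is common to both). The free parameters are
#' `(b, m1, m2, log(ec50_1), log(ec50_2), hill_1, hill_2)` — seven in total.
#' EC50s are estimated on the log scale so they stay positive and so the
#' standard error of `log(EC50)` used by the quality filter is read directly
#' off the parameter covariance (Gauss-Newton approximation at the optimum).
#'
#' Optimization uses Levenberg-Marquardt with an analytic Jacobian, started
#' from a heuristic guess (baseline = readout at dose zero, maximal effect =
#' readout at the top dose, EC50 = dose nearest the half effect, Hill = 1)
#' and restarted from deterministically perturbed starts if it fails to
#' converge. Hill coefficients are box-constrained to `hill_bounds` to keep
#' fits on flat or degenerate data finite.
#'
#' @param data A [checkerboard()] or data.frame with columns `d1`, `d2`,
#'   `effect`; only the mono-therapy and untreated rows are used.
#' @param log_transform Apply [growth_transform()] to the readouts before
#'   fitting (for growth-type readouts with multiplicative noise).
#' @param hill_bounds Length-2 numeric, lower/upper bounds for both Hill
#'   coefficients.
#' @param start Optional named start vector
#'   `c(b, m1, m2, li1, li2, h1, h2)` (`li` = log EC50) overriding the
#'   heuristic.
#' @return An object of class `marginal_fit`: a list with `curves` (two
#'   [marginal_curve()]s sharing `b`), `sigma2` (residual variance),
#'   `df` (residual degrees of freedom), `se_log_ec50` (per compound),
#'   `cov` (7x7 parameter covariance), `converged`, `rss`, `n_obs`,
#'   `fitted` (fitted mono-therapy values) and the internal design used
#'   for bootstrap refits.
#' @export
fit_marginals <- function(data, log_transform = FALSE,
                          hill_bounds = c(0.1, 10), start = NULL) {
  board <- checkerboard(data)
  if (log_transform) board$effect <- growth_transform(board$effect)

  mono1 <- board_view(board, "mono1")
  mono2 <- board_view(board, "mono2")
  untr  <- board_view(board, "untreated")
  for (j in 1:2) {
    nd <- length(unique(list(mono1, mono2)[[j]][[paste0("d", j)]]))
    if (nd < 4)
      stop_invalid("compound ", j, " has only ", nd,
                   " distinct nonzero doses; at least 4 are required")
  }
  design <- list(
    dose = c(untr$d1, mono1$d1, mono2$d2),
    comp = c(rep(0L, nrow(untr)), rep(1L, nrow(mono1)), rep(2L, nrow(mono2))),
    y    = c(untr$effect, mono1$effect, mono2$effect))
  n <- length(design$y)
  if (n <= 7L)
    stop_invalid("need more mono-therapy observations (", n,
                 ") than free parameters (7)")

  if (is.null(start)) start <- heuristic_start(design)
  fit <- lm_fit_marginals(design, start, hill_bounds)
  if (!fit$converged)
    stop_fit_failure(
      paste0("marginal fit did not converge: ", fit$message),
      diagnostics = fit)

  finish_marginal_fit(fit, design, hill_bounds, log_transform)
}

# Heuristic initial values: b from the lowest-total-dose readouts, m_j from
# the top dose, ec50_j the dose nearest the half effect, hill = 1.
heuristic_start <- function(design) {
  y <- design$y; comp <- design$comp; dose <- design$dose
  b0 <- if (any(comp == 0L)) mean(y[comp == 0L]) else {
    mean(c(y[comp == 1L][which.min(dose[comp == 1L])],
           y[comp == 2L][which.min(dose[comp == 2L])]))
  }
  st <- c(b = b0, m1 = NA, m2 = NA, li1 = NA, li2 = NA, h1 = 1, h2 = 1)
  for (j in 1:2) {
    dj <- dose[comp == j]; yj <- y[comp == j]
    mj <- mean(yj[dj == max(dj)])
    half <- (b0 + mj) / 2
    ij <- dj[which.min(abs(yj - half))]
    st[paste0("m", j)] <- mj
    st[paste0("li", j)] <- log(max(ij, min(dj[dj > 0])))
  }
  st
}

# Predicted mono readouts and analytic Jacobian for theta =
# (b, m1, m2, li1, li2, h1, h2); comp 0 rows are untreated (pred = b).
marginal_pred <- function(theta, design) {
  comp <- design$comp; dose <- design$dose
  pred <- rep(theta[["b"]], length(dose))
  for (j in 1:2) {
    k <- comp == j
    o <- stats::plogis(theta[[paste0("h", j)]] *
                         (log(dose[k]) - theta[[paste0("li", j)]]))
    pred[k] <- theta[["b"]] + (theta[[paste0("m", j)]] - theta[["b"]]) * o
  }
  pred
}

marginal_jac <- function(theta, design) {
  comp <- design$comp; dose <- design$dose
  n <- length(dose)
  J <- matrix(0, n, 7,
              dimnames = list(NULL, c("b", "m1", "m2", "li1", "li2",
                                      "h1", "h2")))
  J[, "b"] <- 1
  for (j in 1:2) {
    k <- comp == j
    lc <- log(dose[k]) - theta[[paste0("li", j)]]
    h <- theta[[paste0("h", j)]]
    o <- stats::plogis(h * lc)
    scale <- theta[[paste0("m", j)]] - theta[["b"]]
    J[k, "b"] <- 1 - o
    J[k, paste0("m", j)] <- o
    J[k, paste0("li", j)] <- -scale * o * (1 - o) * h
    J[k, paste0("h", j)] <- scale * o * (1 - o) * lc
  }
  # Jacobian of residuals y - pred
  -J
}

# One LM run plus deterministic perturbed restarts. log(EC50) is kept in a
# generous window around the observed dose range so degenerate resamples
# cannot drive the EC50 to zero or infinity.
lm_fit_marginals <- function(design, start, hill_bounds) {
  pos <- design$dose > 0
  li_lo <- log(min(design$dose[pos])) - 30
  li_hi <- log(max(design$dose[pos])) + 30
  lower <- c(-Inf, -Inf, -Inf, li_lo, li_lo, hill_bounds[1], hill_bounds[1])
  upper <- c(Inf, Inf, Inf, li_hi, li_hi, hill_bounds[2], hill_bounds[2])
  start[c("li1", "li2")] <- pmin(pmax(start[c("li1", "li2")], li_lo), li_hi)
  resid_fn <- function(th) {
    names(th) <- names(start)
    design$y - marginal_pred(th, design)
  }
  jac_fn <- function(th) {
    names(th) <- names(start)
    marginal_jac(th, design)
  }
  perturb <- list(
    c(0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, log(4), log(4), 0, 0),
    c(0, 0, 0, -log(4), -log(4), 0, 0),
    c(0, 0, 0, 0, 0, 1, 1),
    c(0, 0, 0, log(16), -log(16), -0.5, -0.5))
  best <- NULL
  start[c("h1", "h2")] <- pmin(pmax(start[c("h1", "h2")],
                                    hill_bounds[1]), hill_bounds[2])
  for (p in perturb) {
    st <- start + p
    st[c("h1", "h2")] <- pmin(pmax(st[c("h1", "h2")],
                                   hill_bounds[1]), hill_bounds[2])
    st[c("li1", "li2")] <- pmin(pmax(st[c("li1", "li2")], li_lo), li_hi)
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper,
        fn = resid_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-14, ptol = 1e-14, gtol = 0))),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$deviance)) next
    # info 1-4: converged; info -1: iteration cap on a near-flat ridge
    # (typically an unidentified top asymptote, later caught by the
    # log(EC50) quality filter) — keep as a candidate
    ok <- res$info %in% c(-1, 1:4)
    if (ok && (is.null(best) || res$deviance < best$deviance)) {
      best <- res
      if (res$info %in% 1:3) break  # clean convergence on this start
    }
  }
  if (is.null(best))
    return(list(converged = FALSE, message = "all starts failed"))
  theta <- stats::coef(best)
  names(theta) <- names(start)
  list(converged = TRUE, theta = theta, deviance = best$deviance,
       info = best$info, message = best$message)
}

finish_marginal_fit <- function(fit, design, hill_bounds, log_transform) {
  theta <- fit$theta
  n <- length(design$y)
  df <- n - 7L
  rss <- fit$deviance
  sigma2 <- rss / df
  J <- marginal_jac(theta, design)
  JtJ <- crossprod(J)
  inv <- tryCatch(chol2inv(chol(JtJ)), error = function(e) NULL)
  if (is.null(inv)) {
    # near-singular information (flat or unidentified curve): ridge inverse,
    # which yields very large variances on the unidentified directions
    ridge <- 1e-12 * mean(diag(JtJ))
    inv <- solve(JtJ + diag(ridge, 7))
  }
  covm <- sigma2 * inv
  dimnames(covm) <- dimnames(JtJ)
  se_li <- sqrt(pmax(diag(covm)[c("li1", "li2")], 0))
  curves <- list(
    marginal_curve(theta[["b"]], theta[["m1"]], exp(theta[["li1"]]),
                   theta[["h1"]]),
    marginal_curve(theta[["b"]], theta[["m2"]], exp(theta[["li2"]]),
                   theta[["h2"]]))
  structure(list(
    curves = curves, theta = theta, sigma2 = sigma2, df = df, rss = rss,
    n_obs = n, se_log_ec50 = unname(se_li), cov = covm, converged = TRUE,
    fitted = marginal_pred(theta, design), design = design,
    hill_bounds = hill_bounds, log_transform = log_transform),
    class = "marginal_fit")
}

# Fast refit of the same design against new readouts (bootstrap workhorse):
# starts from the original optimum, falls back to the full restart ladder.
refit_marginals <- function(fit, y_new) {
  design <- fit$design
  design$y <- y_new
  res <- lm_fit_marginals(design, fit$theta, fit$hill_bounds)
  if (!res$converged) {
    res <- lm_fit_marginals(design, heuristic_start(design), fit$hill_bounds)
    if (!res$converged) return(NULL)
  }
  theta <- res$theta
  if (any(!is.finite(c(theta, exp(theta[c("li1", "li2")])))) ||
      any(exp(theta[c("li1", "li2")]) <= 0))
    return(NULL)
  list(theta = theta,
       sigma2 = res$deviance / (length(y_new) - 7L),
       curves = list(
         marginal_curve(theta[["b"]], theta[["m1"]], exp(theta[["li1"]]),
                        theta[["h1"]]),
         marginal_curve(theta[["b"]], theta[["m2"]], exp(theta[["li2"]]),
                        theta[["h2"]])))
}

#' @export
print.marginal_fit <- function(x, ...) {
  cat("Shared-baseline 4PLL marginal fit\n")
  cat(sprintf("  b = %.4g (shared)\n", x$theta[["b"]]))
  for (j in 1:2)
    cat(sprintf(
      "  compound %d: m = %.4g, ec50 = %.4g, hill = %.4g, se(log ec50) = %.3g\n",
      j, x$curves[[j]]$m, x$curves[[j]]$ec50, x$curves[[j]]$hill,
      x$se_log_ec50[j]))
  cat(sprintf("  sigma2 = %.4g on %d df (%d mono-therapy observations)\n",
              x$sigma2, x$df, x$n_obs))
  invisible(x)
}

#' @export
coef.marginal_fit <- function(object, ...) object$theta

#' Screen a marginal fit for acceptable EC50 precision
#'
#' A fitted pair is considered usable for synergy testing only if the
#' standard deviation of the `log(EC50)` estimate of each compound does not
#' exceed `threshold` (inclusive). Poorly identified EC50s — flat curves,
#' out-of-range dose windows — otherwise propagate into meaningless null
#' surfaces.
#'
#' @param fit A [fit_marginals()] result.
#' @param threshold Maximum admissible standard deviation of `log(EC50)`
#'   (natural log scale).
#' @return A list of class `quality_check` with `pass` (logical), `reasons`
#'   (character, naming offending compounds), `se_log_ec50` and `threshold`.
#' @export
quality_filter <- function(fit, threshold = 10) {
  if (!inherits(fit, "marginal_fit")) stop_invalid("fit must be a marginal_fit")
  se <- fit$se_log_ec50
  if (is.null(se) || length(se) != 2L || anyNA(se))
    stop_invalid("fit carries no log(EC50) standard errors")
  check_number(threshold, "threshold", min = 0)
  bad <- which(se > threshold)
  structure(list(
    pass = length(bad) == 0L,
    reasons = if (length(bad))
      sprintf("compound %d: sd(log EC50) = %.3g exceeds threshold %g",
              bad, se[bad], threshold) else character(0),
    se_log_ec50 = se, threshold = threshold),
    class = "quality_check")
}

#' @export
print.quality_check <- function(x, ...) {
  cat(sprintf("Quality filter (threshold %g): %s\n", x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  for (r in x$reasons) cat("  ", r, "\n")
  invisible(x)
}
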
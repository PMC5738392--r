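#' Loewe occupancy of a dose combination
#'
#' Solves the concentration-additivity equation for the total occupancy `o`
#' of (virtual) enzyme exposed to a mixture: the sum of dose fractions
#' \deqn{\sum_j \frac{c_j}{C_j(o)} \;=\;
#'       \sum_j \frac{c_j}{i_j}\,(o^{-1} - 1)^{1/h_j} \;=\; 1,}
#' where `C_j(o)` is the mono-therapy concentration of compound `j` giving
#' occupancy `o`. The left-hand side is continuous and strictly decreasing
#' in `o`, from `+Inf` as `o -> 0` to `0` as `o -> 1`, so the root exists
#' and is unique whenever at least one dose is positive; it is found by
#' bracketed bisection on `[1e-12, 1 - 1e-12]`. The all-zero combination
#' returns occupancy `0`. Compounds at zero dose contribute nothing. Any
#' number of compounds (>= 1) is supported.
#'
#' @param curves List of [marginal_curve()]s, one per compound.
#' @param doses Numeric vector of doses (one per curve), or a matrix with
#'   one column per curve and one combination per row.
#' @return Occupancy value(s) in `[0, 1)`.
#' @export
solve_occupancy <- function(curves, doses) {
  curves <- check_curve_list(curves)
  D <- as_dose_matrix(doses, length(curves))
  ivec <- vapply(curves, `[[`, numeric(1), "ec50")
  hvec <- vapply(curves, `[[`, numeric(1), "hill")
  solve_occupancy_core(D, ivec, hvec)
}

check_curve_list <- function(curves) {
  if (inherits(curves, "marginal_curve")) curves <- list(curves)
  if (!is.list(curves) || !length(curves) ||
      !all(vapply(curves, inherits, logical(1), "marginal_curve")))
    stop_invalid("curves must be a list of marginal_curve objects")
  curves
}

as_dose_matrix <- function(doses, n_comp) {
  if (is.data.frame(doses)) doses <- as.matrix(doses)
  if (!is.matrix(doses)) {
    if (length(doses) != n_comp)
      stop_invalid("doses must have one entry per curve (", n_comp, ")")
    doses <- matrix(doses, nrow = 1)
  }
  if (ncol(doses) != n_comp)
    stop_invalid("dose matrix must have one column per curve (", n_comp, ")")
  if (anyNA(doses) || any(doses < 0) || any(!is.finite(doses)))
    stop_invalid("doses must be finite and non-negative")
  unname(doses)
}

# Vectorized bisection for the occupancy root, one root per row of D.
# Zero-dose terms vanish identically for o in (0,1) so no special-casing
# of the active set is needed; 90 halvings take the bracket well below
# the 1e-12 tolerance.
solve_occupancy_core <- function(D, ivec, hvec) {
  nr <- nrow(D)
  out <- numeric(nr)
  active <- rowSums(D) > 0
  if (!any(active)) return(out)
  Da <- D[active, , drop = FALSE]
  frac <- sweep(Da, 2, ivec, `/`)  # c_j / i_j
  lhs <- function(o) {
    # sum_j (c_j/i_j) (1/o - 1)^(1/h_j); o vector over rows
    s <- numeric(length(o))
    x <- (1 - o) / o  # avoids cancellation as o -> 1
    for (j in seq_along(ivec))
      s <- s + frac[, j] * x^(1 / hvec[j])
    s
  }
  eps <- 1e-12
  lo <- rep(eps, nrow(Da)); hi <- rep(1 - eps, nrow(Da))
  flo <- lhs(lo); fhi <- lhs(hi)
  o <- ifelse(flo <= 1, lo, ifelse(fhi >= 1, hi, NA_real_))
  todo <- is.na(o)
  if (any(todo)) {
    l <- lo[todo]; h <- hi[todo]
    fr <- frac[todo, , drop = FALSE]
    for (iter in 1:90) {
      mid <- (l + h) / 2
      x <- (1 - mid) / mid
      s <- numeric(length(mid))
      for (j in seq_along(ivec))
        s <- s + fr[, j] * x^(1 / hvec[j])
      up <- s > 1
      l[up] <- mid[up]
      h[!up] <- mid[!up]
    }
    o[todo] <- (l + h) / 2
  }
  out[active] <- o
  out
}

#' Predicted combination readout under generalized Loewe
#'
#' Computes the null-model readout for one dose combination. The occupancy
#' `o` comes from classical concentration additivity ([solve_occupancy()]),
#' which involves only the EC50s and Hill coefficients. The readout then
#' blends the compound-specific scaled effects in proportion to the
#' fraction of bound enzyme occupied by each compound,
#' \deqn{r = b + o \sum_j (m_j - b)\, f_j, \qquad
#'       f_j = \frac{c_j}{i_j}\,(o^{-1} - 1)^{1/h_j},}
#' with the weights `f_j` summing to one over the compounds present. When
#' all maximal effects `m_j` are equal this reduces exactly to the
#' classical Loewe readout `b + o (m - b)`; unequal `m_j` (partial,
#' neutral or inverse agonists) are handled without modification. A
#' neutral antagonist (`m_j = b`) still competes for occupancy but
#' contributes nothing to the readout sum — that is the mechanism by which
#' it dilutes an agonist's effect.
#'
#' All curves must share the same baseline `b` (within 1e-6 relative).
#'
#' @param curves List of [marginal_curve()]s sharing a baseline.
#' @param doses Numeric dose vector, one entry per curve.
#' @return A list of class `null_prediction` with `occupancy`, `weights`
#'   (`NA` for the all-zero combination) and `readout`.
#' @export
predict_readout <- function(curves, doses) {
  curves <- check_curve_list(curves)
  b <- shared_baseline(curves)
  D <- as_dose_matrix(doses, length(curves))
  if (nrow(D) != 1L) stop_invalid("predict_readout takes a single combination")
  o <- solve_occupancy(curves, D)
  if (o == 0) {
    return(structure(list(occupancy = 0,
                          weights = rep(NA_real_, length(curves)),
                          readout = b),
                     class = "null_prediction"))
  }
  ivec <- vapply(curves, `[[`, numeric(1), "ec50")
  hvec <- vapply(curves, `[[`, numeric(1), "hill")
  mvec <- vapply(curves, `[[`, numeric(1), "m")
  f <- (D[1, ] / ivec) * ((1 - o) / o)^(1 / hvec)
  f <- f / sum(f)  # fractions of bound enzyme: sum to one exactly
  r <- b + o * sum((mvec - b) * f)
  structure(list(occupancy = o, weights = f, readout = r),
            class = "null_prediction")
}

shared_baseline <- function(curves) {
  bs <- vapply(curves, `[[`, numeric(1), "b")
  ref <- bs[1]
  tol <- 1e-6 * max(1, abs(ref))
  if (any(abs(bs - ref) > tol))
    stop_invalid("curves do not share a common baseline (b = ",
                 paste(signif(bs, 8), collapse = ", "), ")")
  ref
}

#' Null response surface over a dose grid
#'
#' Vectorizes [predict_readout()] over the off-axis points of a
#' checkerboard (or any list of dose combinations), returning the
#' predicted occupancy and readout per point in grid order.
#'
#' @param curves List of [marginal_curve()]s sharing a baseline.
#' @param grid Data.frame or matrix of dose combinations, one column per
#'   curve (columns `d1`, `d2`, ... by position).
#' @return A data.frame of class `null_surface` with the dose columns plus
#'   `occupancy` and `predicted`.
#' @export
predict_surface <- function(curves, grid) {
  curves <- check_curve_list(curves)
  b <- shared_baseline(curves)
  D <- as_dose_matrix(grid, length(curves))
  ivec <- vapply(curves, `[[`, numeric(1), "ec50")
  hvec <- vapply(curves, `[[`, numeric(1), "hill")
  mvec <- vapply(curves, `[[`, numeric(1), "m")
  o <- solve_occupancy_core(D, ivec, hvec)
  r <- rep(b, nrow(D))
  pos <- o > 0
  if (any(pos)) {
    x <- (1 - o[pos]) / o[pos]
    acc <- numeric(sum(pos))
    for (j in seq_along(curves))
      acc <- acc + (mvec[j] - b) * (D[pos, j] / ivec[j]) * x^(1 / hvec[j])
    r[pos] <- b + o[pos] * acc
  }
  out <- as.data.frame(D)
  names(out) <- paste0("d", seq_along(curves))
  out$occupancy <- o
  out$predicted <- r
  class(out) <- c("null_surface", "data.frame")
  out
}

#' Write a null surface to CSV
#'
#' @param surface A [predict_surface()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
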
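#' Serialize a synergy result to a JSON-ready list
#'
#' Builds the versioned result record: marginal-fit parameters, quality
#' verdict, MeanR/MaxR statistics and p-values, per-point calls, the
#' overall call, and an echo of the configuration and seed.
#'
#' @param result A [run_synergy_analysis()] result.
#' @return A nested list suitable for [write_result_json()].
#' @export
as_result_json <- function(result) {
  if (!inherits(result, "synergy_result"))
    stop_invalid("result must be a synergy_result")
  fit <- result$fit
  out <- list(
    schema_version = "1.0",
    status = result$status,
    marginal_fit = list(
      b = fit$theta[["b"]],
      m1 = fit$curves[[1]]$m, m2 = fit$curves[[2]]$m,
      ec50_1 = fit$curves[[1]]$ec50, ec50_2 = fit$curves[[2]]$ec50,
      hill_1 = fit$curves[[1]]$hill, hill_2 = fit$curves[[2]]$hill,
      sigma2 = fit$sigma2, df = fit$df,
      se_log_ec50 = fit$se_log_ec50,
      converged = fit$converged),
    qc = list(pass = result$qc$pass, reasons = result$qc$reasons),
    config = result$config,
    seed = if (is.null(result$seed)) NA else result$seed)
  if (result$status == "ok") {
    calls <- result$maxR$calls
    out$meanR <- list(stat = result$meanR$statistic,
                      p = result$meanR$p_value)
    out$maxR <- list(
      stat = result$maxR$statistic, p = result$maxR$p_value,
      crit = result$maxR$crit,
      calls = lapply(seq_len(nrow(calls)), function(i)
        list(d1 = calls$d1[i], d2 = calls$d2[i], t = calls$t[i],
             call = calls$call[i])))
    out$null_method <- result$null_method
    out$overall_call <- result$overall_call
  }
  out
}

#' Write a synergy result as JSON
#'
#' Full-precision, deterministically ordered JSON: identical analyses
#' (same board, config and seed) produce byte-identical files.
#'
#' @param result A [run_synergy_analysis()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  jsonlite::write_json(as_result_json(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Write the per-point synergy calls as CSV
#'
#' One row per off-axis dose combination: doses, mean observed readout,
#' null prediction, standardized deviation and the MaxR call.
#'
#' @param result A [run_synergy_analysis()] result with status `"ok"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(result, path) {
  if (!inherits(result, "synergy_result"))
    stop_invalid("result must be a synergy_result")
  if (result$status != "ok")
    stop_invalid("no per-point calls: analysis was ", result$status)
  calls <- result$maxR$calls
  df <- data.frame(d1 = calls$d1, d2 = calls$d2,
                   observed_mean = calls$observed,
                   predicted = calls$predicted,
                   t_value = calls$t, call = calls$call)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
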
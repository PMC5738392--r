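# Internal helpers: classed conditions and local RNG scoping.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("genloewe_invalid_input", "genloewe_error")))
}

stop_fit_failure <- function(msg, diagnostics = NULL) {
  stop(errorCondition(msg, diagnostics = diagnostics,
                      class = c("genloewe_fit_failure", "genloewe_error")))
}

stop_numerical <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("genloewe_numerical_error", "genloewe_error")))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream as-is".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic derived seeds for pipeline sub-stages, kept below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset * 1000003) %% 2147483647)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (strict && x <= min) stop_invalid(name, " must be > ", min)
  if (!strict && x < min) stop_invalid(name, " must be >= ", min)
  invisible(x)
}
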
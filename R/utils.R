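# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can distinguish failure modes.
rp_stop <- function(msg, class, call. = sys.call(-1)) {
  cond <- structure(
    class = c(class, "ramanpipe_error", "error", "condition"),
    list(message = msg, call = call.)
  )
  stop(cond)
}

rp_value_error  <- function(msg) rp_stop(msg, "ramanpipe_value_error")
rp_dim_error    <- function(msg) rp_stop(msg, "ramanpipe_dimension_error")
rp_format_error <- function(msg) rp_stop(msg, "ramanpipe_format_error")
rp_range_error  <- function(msg) rp_stop(msg, "ramanpipe_range_error")
rp_cal_error    <- function(msg) rp_stop(msg, "ramanpipe_calibration_error")
rp_io_error     <- function(msg) rp_stop(msg, "ramanpipe_io_error")

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Evaluate a polynomial with ascending coefficients c0 + c1*x + c2*x^2 + ...
# via an explicit power basis (tests check it against a Horner oracle).
polyval_asc <- function(coeffs, x) {
  powers <- outer(x, seq_along(coeffs) - 1, `^`)
  drop(powers %*% coeffs)
}

# Population (1/N) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

is_count <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x == round(x)

odd_at_most <- function(w, n) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  if (w > n) w <- if (n %% 2L == 1L) n else n - 1L
  max(w, 1L)
}
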
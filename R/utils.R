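# Internal helpers shared across modules.

# Evaluate `expr` with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# A metric whose denominator is empty is reported as an explicit
# not-a-value carrying a reason code, never silently imputed.
undefined_metric <- function(reason) {
  structure(NA_real_, reason = reason, class = c("undefined_metric", "numeric"))
}

is_undefined_metric <- function(x) inherits(x, "undefined_metric")

#' @export
print.undefined_metric <- function(x, ...) {
  cat("<undefined metric:", attr(x, "reason"), ">\n")
  invisible(x)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}

# Logistic sigmoid, numerically safe for large |x|.
sigmoid <- function(x) 1 / (1 + exp(-x))

# Smooth FFT length: smallest 2,3,5-smooth integer >= n that is also a
# multiple of `mult` (needed by the dyadic packet tree).
smooth_length <- function(n, mult = 1L) {
  m <- stats::nextn(as.integer(ceiling(n / mult)), c(2, 3, 5))
  m * mult
}
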
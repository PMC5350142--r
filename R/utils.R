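#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

# Decimal rounding with ties away from zero (base round() rounds half to even,
# which would print 0.5 -> 0).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Draw a sub-seed so nested generators don't reuse the caller's stream.
derive_seed <- function(seed, k) {
  (seed * 48271 + k * 8191) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
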
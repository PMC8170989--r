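# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so that library code never
#' perturbs the user's random number stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a stream seed from a master seed
#'
#' One RNG stream per generated object: stream k of master seed m is
#' (m * 48271 + k) mod (2^31 - 1). Documented so that any stage can be
#' rerun in isolation with the same draws. Keys are small integers fixed
#' per output object and listed where used.
#' @noRd
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(key)) %% 2147483647)
}

# Percentages are truncated (not rounded) to 2 decimals, matching the
# reporting convention for silencing fractions (2/23 -> 8.69).
trunc_pct <- function(x) floor(x * 10000) / 100

# largest-remainder apportionment of n into parts proportional to p
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

stop_typed <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "epimutr_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
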
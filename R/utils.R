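## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed below 2^31 (double arithmetic:
## the product can exceed integer range before the modulo).
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stream)) %% 2147483647)
}

logit <- function(p) qlogis(p)
invLogit <- function(x) plogis(x)

#' Small-sample corrected AIC
#'
#' \deqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1).}
#'
#' @param logLik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (sites).
#' @return AICc value (Inf when \code{n <= k + 1}).
#' @export
aiccValue <- function(logLik, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
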
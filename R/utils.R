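#' @keywords internal
"_PACKAGE"

#' @importFrom stats dpois lm coef sd pchisq p.adjust aggregate plogis qlogis setNames
#' @importFrom utils read.delim write.table combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic substream seed; doubles are exact well past 2^52 so the
# modulus keeps results identical across platforms.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483587) + 1L
}

# x*log(x) with the 0*log(0) = 0 convention used throughout the likelihoods.
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# Binomial log-likelihood (up to the constant binomial coefficient) of x
# successes in n trials at rate p, with saturated 0/1 rates allowed.
binom_loglik <- function(x, n, p) {
  term1 <- ifelse(x > 0, x * log(p), 0)
  term2 <- ifelse(n - x > 0, (n - x) * log(1 - p), 0)
  sum(term1 + term2)
}

# Add-one permutation p-value: never exactly zero.
perm_pvalue <- function(null_stats, observed, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  hits <- if (tail == "greater") sum(null_stats >= observed) else sum(null_stats <= observed)
  (1 + hits) / (length(null_stats) + 1)
}
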
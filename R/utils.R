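#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm pnorm rnorm rgamma rpois rlnorm runif optimize setNames
#' @importFrom utils read.csv write.csv
NULL

# Numerically stable log(sum(exp(x))) / log(mean(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

# Row-wise log-mean-exp of a matrix (one estimate per row).
row_logmeanexp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowMeans(exp(m - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

#' Evaluate an expression with a temporary RNG seed
#'
#' All stochastic operations in ounet take an explicit `seed`; the global RNG
#' stream is left untouched so that seeded calls are reproducible and
#' side-effect free.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

# Derive a stream-specific child seed from a master seed. Kept below 2^31.
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483587
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_contract <- function(...) stop(..., call. = FALSE)
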
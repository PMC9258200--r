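#' @keywords internal
"_PACKAGE"

#' @useDynLib varmodnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic substream seed derived from a master seed and an index.
# Lehmer-style mixing modulo the Mersenne prime 2^31 - 1; all intermediate
# products stay below 2^53 so the double arithmetic is exact.
derive_seed <- function(seed, index) {
  m <- 2147483647
  x <- as.numeric(seed) %% m
  for (k in c(as.numeric(index), 104729)) {
    x <- (x * 48271 + k + 1) %% m
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_("'%s' must be a single probability in [0, 1], got %s",
          name, paste(format(x), collapse = ", "))
  }
  invisible(x)
}
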
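#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd quantile dist hclust cutree predict var aggregate
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

# Deterministic string hash (polynomial, base 31, modulus a prime < 2^29 so
# all intermediates stay exact in doubles). Used to map fingerprint feature
# strings and stream names to integers; platform-independent by construction.
hash_string <- function(s, mod = 536870909) {
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% mod
  h
}

hash_strings <- function(v, mod = 536870909) {
  vapply(v, hash_string, numeric(1), mod = mod, USE.NAMES = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, stream).
# Each named stream gets an independent, reproducible substream so that one
# global integer seed drives every operation without coupling their draws.
with_stream <- function(seed, stream, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  derived <- (as.numeric(seed) %% 2147483647 + hash_string(stream, 2147483629)) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(derived))
  expr
}

ls_stop <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(paste0("ligandscreen_", code), "ligandscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
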
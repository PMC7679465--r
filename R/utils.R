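`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_invalid(sprintf("`%s` must be finite numeric", name))
  invisible(x)
}

check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0 || temperature >= 1)
    stop_invalid("`temperature` must lie in the open interval (0, 1)")
  invisible(temperature)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched.  seed = NULL runs in the current stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## all unordered pairs (i < j) of 1..n as a two-column integer matrix
pair_indices <- function(n) {
  n <- as.integer(n)
  if (n < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("i", "j"))))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  cbind(i = i, j = j)
}

## unique double key for an unordered pair; safe for n < 2^26
pair_key <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * n + hi
}

circular_mean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta))) %% (2 * pi)
}

gl_quadrature <- function(n = 64L, a = 0, b = pi) {
  pracma::gaussLegendre(n, a, b)
}
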
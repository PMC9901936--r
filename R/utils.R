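#' @keywords internal
"_PACKAGE"

#' @useDynLib conemosaiq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rnbinom rpois pchisq pt sd quantile
#' @importFrom utils write.csv read.csv modifyList
NULL

#' Null-default operator
#' @param a,b values; `b` is returned when `a` is `NULL`.
#' @return `a` unless it is `NULL`, else `b`.
#' @name null-default
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(..., call. = call.)
  invisible(NULL)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE, strict_max = FALSE) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           name, " must be a single finite number")
  abort_if(if (strict_min) x <= min else x < min,
           name, " must be ", if (strict_min) "> " else ">= ", min)
  abort_if(if (strict_max) x >= max else x > max,
           name, " must be ", if (strict_max) "< " else "<= ", max)
  invisible(x)
}

#' Evaluate an expression under a fixed, named RNG configuration
#'
#' All stochastic code in the package runs through this helper so that
#' identical spec + seed always yields identical output: Mersenne-Twister,
#' inversion normals, rejection sampling. The caller's RNG state is
#' restored on exit.
#'
#' @param seed integer seed (< 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  abort_if(!is.numeric(seed) || length(seed) != 1L || is.na(seed),
           "seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, done in 16-bit halves so
# the arithmetic stays exact in doubles. Used to derive per-field seeds and
# config hashes; result is in [0, 2^31).
fnv1a31 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(s, collapse = "\x1f"))))
  h <- 2166136261
  prime_lo <- 403  # 16777619 = 256 * 65536 + 403
  prime_hi <- 256
  for (b in bytes) {
    h <- bitwXorUL(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    # (hi*2^16 + lo) * prime mod 2^32
    h <- ((hi * prime_lo + lo * prime_hi) %% 65536) * 65536 + lo * prime_lo
    h <- h %% 4294967296
  }
  h %% 2147483648
}

# xor for non-negative doubles < 2^32 (base bitwXor needs integers)
bitwXorUL <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Derive a reproducible child seed
#'
#' Deterministically maps a base seed plus any string/integer tags (for
#' example group name and field index) to a new seed below 2^31.
#'
#' @param base_seed integer base seed.
#' @param ... tags (coerced to character) identifying the child stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(base_seed, ...) {
  tags <- paste(c(as.character(base_seed), vapply(list(...), as.character,
                                                  character(1))),
                collapse = "/")
  as.integer(fnv1a31(tags) %% 2147483647 + 1)
}

# short stable hash of an R object (via its canonical JSON) for manifests
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("%08x", fnv1a31(as.character(json)))
}
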
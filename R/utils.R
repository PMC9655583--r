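#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom Rcpp evalCpp
#' @useDynLib rnadsn, .registration = TRUE
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package funnels through this so results depend only on
# (seed, canonically ordered input), never on ambient RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed and a stream index, staying inside
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + as.double(index) * 9176) %% 2147483587L)
}

assert_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer, got %s", name, deparse(x)))
  }
  if (!is.null(min) && x < min) {
    abort(sprintf("`%s` must be >= %s, got %s", name, min, x))
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

RNA_BASES <- c("A", "C", "G", "U")
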
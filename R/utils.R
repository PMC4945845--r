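# internal helpers

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package randomness never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# derive a child seed from a base seed, kept within 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fraction <- function(x, name) {
  if (!is_scalar_num(x) || x < 0 || x > 1)
    stopf("`%s` must be a single value in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

# normalize a length-1-or-3 numeric to length 3
rep3 <- function(x, name) {
  if (!is.numeric(x) || !length(x) %in% c(1L, 3L) || any(!is.finite(x)))
    stopf("`%s` must be a finite numeric of length 1 or 3", name)
  if (length(x) == 1L) rep(x, 3L) else as.numeric(x)
}
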
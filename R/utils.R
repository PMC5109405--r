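# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_fraction <- function(x, name, min = 0, max = 1,
                            open_min = FALSE, open_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < min || x > max ||
      (open_min && x == min) || (open_max && x == max)) {
    stop(sprintf("`%s` must be a fraction in %s%g, %g%s, got %s",
                 name, if (open_min) "(" else "[", min, max,
                 if (open_max) ")" else "]",
                 deparse(substitute(x))), call. = FALSE)
  }
  invisible(x)
}

.check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < if (positive) 1 else 0) {
    stop(sprintf("`%s` must be a %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Derive independent sub-seeds from one master seed so that stages
# (normals, cancers, PPI, permutations) can be regenerated independently.
# Kept below 2^31 - 1 so callers can pass them straight to set.seed().
.derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  sample.int(2147483646L, n)
}

# Run expr with a local RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  expr
}
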
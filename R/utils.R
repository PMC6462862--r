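# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      rlang::abort("`seed` must be a single non-missing number.",
                   class = "clonehet_invalid_argument")
    }
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "clonehet_invalid_argument")
}

# scalar checks ---------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_invalid(sprintf("`%s` must be a single number.", name))
  }
  if (x < lower || x > upper) {
    abort_invalid(sprintf("`%s` must be in [%s, %s], got %s.",
                          name, format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_proportion <- function(x, name, allow_na = FALSE) {
  check_number(x, name, lower = 0, upper = 1, allow_na = allow_na)
}

check_count <- function(x, name, lower = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x)) {
    abort_invalid(sprintf("`%s` must be a single non-negative integer.", name))
  }
  if (x < lower) {
    abort_invalid(sprintf("`%s` must be >= %s.", name, lower))
  }
  invisible(as.integer(x))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
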
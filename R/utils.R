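#' @keywords internal
"_PACKAGE"

# Shared argument checks; all user-facing errors go through stop() with a
# classed condition so callers and tests can match on the failure mode.

dpa_error <- function(class, msg) {
  stop(structure(
    class = c(class, "dpanet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_count <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    dpa_error("invalid_parameter", sprintf(
      "`%s` must be a single %s integer, got %s",
      name, if (positive) "positive" else "non-negative",
      paste(format(x), collapse = ", ")
    ))
  }
  as.integer(x)
}

check_probability <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    dpa_error("invalid_parameter",
              sprintf("`%s` must be a probability in [0, 1]", name))
  }
  as.numeric(x)
}

check_prob_vector <- function(x, name, tol = 1e-9) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    dpa_error("invalid_parameter",
              sprintf("`%s` must be a non-negative numeric vector", name))
  }
  if (abs(sum(x) - 1) > tol) {
    dpa_error("invalid_parameter",
              sprintf("`%s` must sum to 1 (within %g)", name, tol))
  }
  x
}

# with_seed: run expr under a local RNG state so generators are deterministic
# given (parameters, seed) and never leak into the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}
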
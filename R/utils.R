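#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Run `expr` under a locally seeded RNG stream, restoring the caller's
# .Random.seed afterwards so library code never perturbs user randomness.
local_seed <- function(seed, expr) {
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
  force(expr)
}

# Deterministic 31-bit sub-seed derived from a master seed and a tag
# (e.g. a gene-set size), so cached null pools do not depend on the order
# in which gene sets are visited.
derive_seed <- function(seed, tag) {
  s <- (as.double(seed) %% 2147483647) + 1
  t <- (as.double(tag) %% 2147483647) + 1
  as.integer((s * 48271 + t * 16807) %% 2147483629)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "lncpath_parameter_error")
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "lncpath_parameter_error")
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  if (!low_ok || x > upper) {
    abort(sprintf("`%s` must be in %s%s, %s].", name,
                  if (strict_lower) "(" else "[", lower, upper),
          class = "lncpath_parameter_error")
  }
  invisible(x)
}
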
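#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------

mi_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "metintegrate_error")))
}

mi_warn <- function(msg, class = "metintegrate_warning") {
  warning(warningCondition(msg, class = c(class, "metintegrate_warning")))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the Mersenne-Twister stream seeded at `seed`, then restores
#' the caller's RNG state, so generators are reproducible without clobbering
#' the session's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    mi_stop("`seed` must be a single finite number", "invalid_parameter")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Argument checks --------------------------------------------------------------

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    mi_stop(sprintf("`%s` must be a single integer >= %d", name, min),
            "invalid_parameter")
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    mi_stop(sprintf("`%s` must be a single value in [0, 1]", name),
            "invalid_parameter")
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    mi_stop(sprintf("`%s` must be a single positive number", name),
            "invalid_parameter")
  }
  as.numeric(x)
}
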
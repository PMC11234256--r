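# Internal helpers shared across modules.

# Channel roles recognised in a plex layout.
.plex_roles <- c("WT_BAIT", "VARIANT_BAIT", "NEGATIVE_CONTROL", "UNUSED")

# Classed error so callers and tests can catch specific failure modes.
.stop2 <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "apms_error", "error", "condition")))
}

.assert <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) .stop2(class, fmt, ...)
  invisible(TRUE)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; seed = NULL leaves the stream untouched.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.check_pvalues <- function(p, what = "p_values") {
  .assert(is.numeric(p) && length(p) >= 1L, "apms_validation_error",
          "%s must be a non-empty numeric vector", what)
  .assert(!anyNA(p) && all(p >= 0 & p <= 1), "apms_validation_error",
          "%s must lie in [0, 1] with no missing values", what)
  invisible(TRUE)
}
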
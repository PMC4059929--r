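# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' generators are deterministic without clobbering the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed and a label
#'
#' Stable polynomial hash of the label folded into the master seed, kept below
#' 2^31 so the result is a valid `set.seed()` argument. Identical
#' (seed, label) pairs always map to the same derived seed, so a stage can be
#' re-run in isolation.
#' @noRd
derive_seed <- function(seed, label) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# stopifnot-style check with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

# required columns present in a data.frame
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  check_that(length(missing) == 0L, "%s is missing column(s): %s",
             what, paste(missing, collapse = ", "))
}
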
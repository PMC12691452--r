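#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so deterministic generators do not disturb (and are
#' not disturbed by) surrounding code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

# Derive a stream of child seeds from a parent seed, kept inside 32-bit
# integer range. Used so each generated WSI owns an independent seed.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

#' The five ovarian carcinoma histotype labels
#'
#' Clear cell (CC), mucinous (MC), low-grade serous (LGSC), high-grade
#' serous (HGSC) and endometrioid (EC) carcinoma, in the fixed order used
#' throughout the package.
#'
#' @return character vector of length 5.
#' @export
histotype_classes <- function() c("CC", "MC", "LGSC", "HGSC", "EC")
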
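#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector of sequences over `{A,C,G,T,N}`.
#' `N` is its own complement.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Classed error helper: all package errors carry class "tfscout_error" plus
# a specific subclass so callers can branch on failure mode.
tfs_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "tfscout_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Run an expression with a deterministic RNG state derived from `seed`,
# restoring the caller's RNG state afterwards. Keeps the generators pure
# functions of (config, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
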
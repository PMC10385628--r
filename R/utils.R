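`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All synthetic generators route their randomness through this helper so that
#' a seed fully determines a fixture without clobbering global RNG state.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

# row-wise Euclidean norms of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))

# package data file
cz_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "contactzones")
  if (!nzchar(path)) stop("missing packaged data file: ", file.path(...))
  path
}

stop_cz <- function(...) stop(..., call. = FALSE)
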
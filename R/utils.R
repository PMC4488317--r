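#' Derive reproducible sub-seeds from a master seed
#'
#' Every stochastic stage of the pipeline (meiosis, QTL architecture, noise,
#' weather, ABC proposals per worker) draws its seed from the master seed
#' through this function, so that one integer reproduces a whole run while
#' the stages remain decoupled: changing, say, the number of ABC workers
#' does not disturb the dataset that was generated earlier.
#'
#' @param master Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` must be finite and numeric", what), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
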
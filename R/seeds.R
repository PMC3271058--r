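#' Derive a reproducible sub-seed
#'
#' All randomness in the package flows from one master seed; every operation
#' (panel generation, causal selection, phenotype draw, permutation stream)
#' derives its own substream seed from the master seed plus a string/integer
#' context, so partial re-runs reproduce the corresponding pieces of a full
#' run.
#'
#' @param master integer master seed.
#' @param ... context components (integers or strings) identifying the
#'   substream, e.g. \code{deriveSeed(s, "panel", 3)}.
#' @return a single integer in [1, 2^31 - 2], suitable for
#'   \code{set.seed()}.
#' @examples
#' deriveSeed(1, "panel", 3)
#' @export
deriveSeed <- function(master, ...) {
  parts <- list(...)
  h <- as.numeric(master) %% 2147483563
  for (p in parts) {
    if (is.character(p)) {
      for (ch in utf8ToInt(p)) h <- (h * 69069 + ch) %% 2147483563
    } else {
      h <- (h * 69069 + as.numeric(p) %% 2147483563) %% 2147483563
    }
  }
  as.integer(h %% 2147483562) + 1L
}

withSeed <- function(seed, expr) {
  # evaluate expr under a local RNG state
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
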
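#' Derive a reproducible child seed from a master seed
#'
#' Folds the master seed and any number of string/integer qualifiers into a
#' single integer below 2^31 with a multiplicative string hash. Every source
#' of randomness in the package draws its seed through this function so that
#' one master seed fixes the whole pipeline.
#'
#' @param master_seed integer master seed.
#' @param ... qualifiers (fold index, algorithm name, stage label, ...)
#'   coerced to character and hashed in order.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "split", 10)
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- abs(as.double(master_seed)) %% m
  for (part in as.character(unlist(list(...)))) {
    for (v in utf8ToInt(part)) {
      h <- (h * 31 + v) %% m
    }
  }
  as.integer(h)
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# informational logging, silenced unless option(xmittn.verbose = TRUE)
xmittn_log <- function(...) {
  if (isTRUE(getOption("xmittn.verbose", FALSE))) {
    message("[xmittn] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
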
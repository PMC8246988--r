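# Internal helpers: classed errors, deterministic seed derivation, local RNG.

tn_error <- function(class, msg, ...) {
  stop(errorCondition(msg,
                      class = c(paste0("tractnorm_", class), "tractnorm_error"),
                      ...))
}

tn_assert <- function(ok, class, msg) {
  if (!isTRUE(ok)) tn_error(class, msg)
  invisible(TRUE)
}

#' Derive a deterministic child seed from a master seed and string labels
#'
#' Polynomial string hash (base 31, modulus 2^31 - 1) of the master seed and
#' any number of labels. Used so that per-subject and per-stage random
#' streams depend only on `(seed, labels)`, never on row order.
#'
#' @param seed integer master seed.
#' @param ... character or numeric labels identifying the stream.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = ":")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h + 1L)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
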
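# Internal helpers: error classes, seeded substreams, misc.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("alarmsieve_validation_error", "error")))
}

abort_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("alarmsieve_usage_error", "error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

#' Derive a named sub-stream seed from a root seed
#'
#' A single user-facing seed fans out to independent named streams (model
#' initialization, fold splitting, baseline resampling, dropout, simulation)
#' so that toggling one component never shifts another component's draws.
#' Uses a small multiplicative string hash reduced mod 2^31 - 1.
#'
#' @param root integer root seed.
#' @param ... name components (coerced to character) identifying the stream.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(root, ...) {
  key <- paste(c(as.character(root), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147483647
  as.integer(h + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# -log(sigmoid(x)), numerically stable for large |x|
neg_log_sigmoid <- function(x) {
  ifelse(x > 0, log1p(exp(-x)), -x + log1p(exp(x)))
}
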
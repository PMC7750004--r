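# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed, stably across
# platforms and below .Machine$integer.max.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L)
  key <- paste0(master, "/", stream)
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483563
  as.integer(h + 1L)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("entroread_validation_error", "error")))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_validation(...)
  invisible(TRUE)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
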
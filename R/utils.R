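#' @importFrom Rcpp sourceCpp
#' @useDynLib mpsampler, .registration = TRUE
NULL

MISSING_TOKEN <- "-"

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# One log line per pipeline stage; machine-parsable key=value pairs.
stage_log <- function(quiet, stage, ...) {
  if (isTRUE(quiet)) return(invisible(NULL))
  kv <- c(...)
  msg <- paste0("[mpsampler] stage=", stage)
  if (length(kv))
    msg <- paste(msg, paste(names(kv), unname(kv), sep = "=", collapse = " "))
  message(msg)
  invisible(NULL)
}
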
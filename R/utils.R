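logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) plogis(x)

clip01 <- function(x) pmin(pmax(x, 0), 1)

ct_abort <- function(..., class = "cotwin_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

ct_log <- function(..., verbose = getOption("cotwin.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[cotwin] ", ...)
  invisible(NULL)
}

# Deterministic per-stage seed derived from a master seed; stays within
# the 32-bit signed integer range R requires.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
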
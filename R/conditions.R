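# Classed conditions so callers (and tests) can distinguish failure modes.

abv_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "abv_error")))
}

stopf <- function(class, fmt, ...) {
  abv_error(class, sprintf(fmt, ...))
}
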
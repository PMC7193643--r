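stop_ts <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ts(name, " must be a single finite number")
  as.numeric(x)
}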
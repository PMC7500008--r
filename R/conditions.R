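# Classed conditions. Every error raised by this package carries a specific
# condition class (e.g. "duplicate_id_error") plus the umbrella class
# "lymphomir_error", so callers can test for precise failure modes.

lm_abort <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "lymphomir_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

lm_warn <- function(message, class = "lymphomir_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
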
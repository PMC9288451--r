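# Classed conditions so callers (and tests) can distinguish failure modes.
# Every validation failure raises a condition inheriting from "fc_error" plus
# a specific subclass, e.g. "fc_negative_count".

fc_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "fc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fc_assert_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    fc_stop("fc_missing_file", "file not found: %s", as.character(path)[1])
  }
  invisible(path)
}
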
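# Internal helpers shared across modules.

# Signal a classed error so callers and tests can condition on failure mode
# rather than on message wording.
ds_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "divscape_error")))
}

DNA_ALPHABET <- c("A", "C", "G", "T", "-", "N")
DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a
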
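# internal helpers shared across modules

# optional progress/log messages, gated on an option so tests stay quiet
vlog <- function(fmt, ...) {
  if (isTRUE(getOption("fhirvariant.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

# deterministic per-entity sub-seed so cohort content is invariant to the
# order patients are generated in; stays below .Machine$integer.max
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 69621 + as.double(index) * 104729
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_missing_token <- function(x) {
  is.null(x) || length(x) == 0L || all(is.na(x)) ||
    (is.character(x) && all(gsub("[/|.]", "", x) == ""))
}
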
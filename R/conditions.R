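# Classed conditions so callers can distinguish failure modes per frame.

dtw_abort <- function(type, msg, frame = NULL) {
  if (!is.null(frame)) msg <- sprintf("[frame %d] %s", frame, msg)
  cond <- structure(
    class = c(paste0("dtwstrain_", type), "dtwstrain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), frame = frame)
  )
  stop(cond)
}

# convenience predicates used in tests
is_dtw_error <- function(e, type) inherits(e, paste0("dtwstrain_", type))
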
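# Classed conditions so callers can distinguish validation, numerical and
# I/O failures programmatically (tryCatch on the subclass).

ek_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "esterkin_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ek_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "esterkin_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                    nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ek_stop(sprintf("'%s' must be a single finite number", name),
            "esterkin_validation_error")
  if (positive && x <= 0)
    ek_stop(sprintf("'%s' must be > 0", name), "esterkin_validation_error")
  if (nonnegative && x < 0)
    ek_stop(sprintf("'%s' must be >= 0", name), "esterkin_validation_error")
  invisible(x)
}
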
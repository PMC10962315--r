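# Internal helpers shared across modules.

# Classed error so callers can distinguish failure modes programmatically.
sf_stop <- function(message, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "specflow_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

sf_warn <- function(message, class = "specflow_warning") {
  warning(warningCondition(message, class = class))
}

# Robust SD used throughout QC: 1.4826 * MAD (consistent with a Gaussian SD,
# resistant to the heavy tails typical of cytometry noise).
robust_sd <- function(x) {
  stats::mad(x, constant = 1.4826)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
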
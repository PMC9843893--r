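# Internal helpers shared across modules.

# Stop with a classed condition so callers can distinguish error kinds.
stop_pancrad <- function(msg, class) {
  stop(structure(
    class = c(class, "pancrad_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds derived from one root seed; kept below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}

is_binary01 <- function(x) all(x %in% c(0, 1))

as_label01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    u <- sort(unique(labels))
    if (length(u) > 2) stop_pancrad("more than two classes", "pancrad_input_error")
    return(as.integer(labels == u[length(u)]))
  }
  if (!is_binary01(labels)) stop_pancrad("labels must be binary", "pancrad_input_error")
  as.integer(labels)
}
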
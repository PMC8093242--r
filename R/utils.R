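# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_semscan <- function(msg, class, ...) {
  stop(structure(class = c(class, "semscan_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when equal to numerical precision
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

# deterministic child seeds derived from a master seed (kept < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
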
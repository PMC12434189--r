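# internal numeric helpers shared across modules

# elementwise log(exp(a) + exp(b)), safe for -Inf
logspace_add <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_erodiv <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "erodiv_error")))
}
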
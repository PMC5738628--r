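# numerically stable helpers shared across modules

# log(1 + exp(x)) without overflow for large |x|
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x < 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

# log(sum(exp(lx))) for a vector of log-values
logsumexp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_config <- function(field, msg) {
  rlang::abort(
    sprintf("invalid configuration: field `%s` %s", field, msg),
    class = "preopbayes_config_error",
    field = field
  )
}
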
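# internal numerical helpers

# log(sum(exp(x))) along rows of a matrix, stable
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# softmax over rows of an eta matrix that already includes the reference
# column of zeros; rows sum to one
softmax_rows <- function(eta) {
  p <- exp(eta - apply(eta, 1L, max))
  p / rowSums(p)
}

stop_trajmix <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "trajmix_error")))
}
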
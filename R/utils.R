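# Internal numerical helpers.

# Row-wise log-sum-exp with guard against all -Inf rows.
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  bad <- !is.finite(mx)
  mx[bad] <- 0  # all -Inf row -> log(0) = -Inf restored below
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- -Inf
  out
}

logit <- function(p) log(p) - log1p(-p)

# Fast logistic for the hot path (equivalent to plogis on doubles).
sigmoid <- function(q) 1 / (1 + exp(-q))

# log(1 + exp(q)), stable; preserves matrix shape
softplus <- function(q) {
  out <- pmax(q, 0) + log1p(exp(-abs(q)))
  if (is.matrix(q)) dim(out) <- dim(q)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All community states z in {0,1}^S, lexicographic in the fixed species order:
# species 1 is the most significant bit, so rows run (0,...,0), (0,...,1), ...
state_matrix <- function(S) {
  stopifnot(S >= 1)
  idx <- 0:(2^S - 1)
  m <- matrix(0L, nrow = 2^S, ncol = S)
  for (i in seq_len(S)) m[, i] <- as.integer((idx %/% 2^(S - i)) %% 2)
  m
}
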
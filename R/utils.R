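# Numerically stable helpers shared across modules. All Bayes factors are
# carried in natural-log space; probabilities in linear space.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(mean(exp(x)))
logmeanexp <- function(x) logsumexp(x) - log(length(x))

# Row-wise logsumexp for a matrix of log terms.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  finite <- is.finite(m)
  out <- m
  if (any(finite)) {
    out[finite] <- m[finite] +
      log(rowSums(exp(x[finite, , drop = FALSE] - m[finite])))
  }
  out
}

# posterior = prior*BF / (prior*BF + 1 - prior), stable for large |log_bf|.
posterior_from_log_bf <- function(prior, log_bf) {
  stopifnot(length(prior) == length(log_bf) || length(prior) == 1L ||
              length(log_bf) == 1L)
  n <- max(length(prior), length(log_bf))
  prior <- rep_len(prior, n)
  log_bf <- rep_len(log_bf, n)
  out <- numeric(n)
  pos <- prior > 0 & prior < 1
  out[prior >= 1] <- 1
  if (any(pos)) {
    la <- log(prior[pos]) + log_bf[pos]
    lb <- log1p(-prior[pos])
    out[pos] <- 1 / (1 + exp(lb - la))
  }
  out
}

is_prob <- function(x, tol = 0) {
  is.numeric(x) && all(is.finite(x)) && all(x >= -tol & x <= 1 + tol)
}

check_prob <- function(x, what, tol = 0) {
  if (!is_prob(x, tol = tol)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1].", what),
          class = "multipcg_argument_error")
  }
  invisible(x)
}

abort_arg <- function(msg) abort(msg, class = "multipcg_argument_error")
abort_format <- function(msg) abort(msg, class = "multipcg_format_error")
abort_validation <- function(msg) abort(msg, class = "multipcg_validation_error")
abort_alignment <- function(msg) abort(msg, class = "multipcg_alignment_error")
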
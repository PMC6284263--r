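# Linear-chain CRF over BIO labels.
#
# A label path y is scored as the sum of per-position emission scores
# P[i, y_i] plus transition scores A[y_i, y_{i+1}], with augmented START
# and STOP states supplying the boundary terms, so that the transition
# sum runs over n+1 edges:
#
#   s(X, y) = sum_i P[i, y_i] + A[START, y_1]
#             + sum_i A[y_i, y_{i+1}] + A[y_n, STOP]
#
# The path distribution is p(y|X) = exp(s(X,y)) / Z with
# Z = sum_y exp(s(X,y)), computed exactly by the forward algorithm in
# log space. Decoding is max-product (Viterbi) with ties broken toward
# the lower label index in the fixed order B < I < O.

CRF_LABELS <- c("B", "I", "O")
CRF_K <- 3L
CRF_START <- 4L
CRF_STOP <- 5L

crf_check <- function(P, A) {
  if (!is.matrix(P) || ncol(P) != CRF_K) stop("P must be an n x 3 matrix")
  if (!is.matrix(A) || any(dim(A) != c(CRF_K + 2L, CRF_K + 2L))) {
    stop("A must be a 5 x 5 matrix (labels + START/STOP)")
  }
}

labels_to_ids <- function(y) {
  if (is.character(y)) {
    ids <- match(y, CRF_LABELS)
    if (anyNA(ids)) stop("illegal label: must be in {B, I, O}")
    ids
  } else {
    y <- as.integer(y)
    if (any(y < 1 | y > CRF_K)) stop("illegal label index")
    y
  }
}

#' Score a label path under the CRF
#'
#' @param P n x 3 emission matrix (raw Bi-LSTM projection scores, no
#'   softmax).
#' @param A 5 x 5 transition matrix; rows/cols 1..3 are B, I, O, row 4 is
#'   START (used only as a source), column 5 is STOP (used only as a
#'   target).
#' @param y label path: character vector over `{"B","I","O"}` or integer
#'   indices, length n = nrow(P).
#' @return scalar path score.
#' @export
sequence_score <- function(P, A, y) {
  crf_check(P, A)
  y <- labels_to_ids(y)
  n <- nrow(P)
  if (length(y) != n) stop("label path length must equal nrow(P)")
  s <- sum(P[cbind(seq_len(n), y)]) + A[CRF_START, y[1]] + A[y[n], CRF_STOP]
  if (n > 1) s <- s + sum(A[cbind(y[-n], y[-1])])
  s
}

#' Log-partition function of the CRF
#'
#' `log sum_y exp(s(X, y))` over all 3^n label paths, via the forward
#' recursion in log space.
#'
#' @inheritParams sequence_score
#' @return scalar log Z.
#' @export
log_partition <- function(P, A) {
  crf_check(P, A)
  n <- nrow(P)
  alpha <- A[CRF_START, 1:CRF_K] + P[1, ]
  if (n > 1) {
    for (t in 2:n) {
      alpha <- vapply(1:CRF_K, function(j) {
        logsumexp(alpha + A[1:CRF_K, j]) + P[t, j]
      }, numeric(1))
    }
  }
  logsumexp(alpha + A[1:CRF_K, CRF_STOP])
}

# Forward-backward: logZ, per-position posteriors and expected
# transition counts (the sufficient statistics for the NLL gradient).
crf_forward_backward <- function(P, A) {
  crf_check(P, A)
  n <- nrow(P)
  k <- CRF_K
  alpha <- matrix(0, n, k)
  alpha[1, ] <- A[CRF_START, 1:k] + P[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in 1:k) {
        alpha[t, j] <- logsumexp(alpha[t - 1, ] + A[1:k, j]) + P[t, j]
      }
    }
  }
  logZ <- logsumexp(alpha[n, ] + A[1:k, CRF_STOP])
  beta <- matrix(0, n, k)
  beta[n, ] <- A[1:k, CRF_STOP]
  if (n > 1) {
    for (t in (n - 1):1) {
      for (i in 1:k) {
        beta[t, i] <- logsumexp(A[i, 1:k] + P[t + 1, ] + beta[t + 1, ])
      }
    }
  }
  node_marg <- exp(alpha + beta - logZ)
  trans_exp <- matrix(0, k + 2L, k + 2L)
  trans_exp[CRF_START, 1:k] <- exp(A[CRF_START, 1:k] + P[1, ] + beta[1, ] - logZ)
  trans_exp[1:k, CRF_STOP] <- exp(alpha[n, ] + A[1:k, CRF_STOP] - logZ)
  if (n > 1) {
    for (t in 1:(n - 1)) {
      blk <- outer(alpha[t, ], P[t + 1, ] + beta[t + 1, ], "+") + A[1:k, 1:k]
      trans_exp[1:k, 1:k] <- trans_exp[1:k, 1:k] + exp(blk - logZ)
    }
  }
  list(logZ = logZ, node_marginals = node_marg, trans_expected = trans_exp)
}

#' Viterbi decoding
#'
#' Returns the highest-scoring label path and its score. Ties are broken
#' toward the lower label index (B < I < O), making the decode fully
#' deterministic.
#'
#' @inheritParams sequence_score
#' @param constrain_bio when TRUE, the transition O -> I is forbidden at
#'   decode time (score -Inf).
#' @return list with `path` (character vector over B/I/O) and `score`;
#'   `score` equals `sequence_score(P, A, path)`.
#' @export
viterbi_decode <- function(P, A, constrain_bio = FALSE) {
  crf_check(P, A)
  if (constrain_bio) A[3L, 2L] <- -Inf   # O -> I
  n <- nrow(P)
  k <- CRF_K
  delta <- matrix(-Inf, n, k)
  back <- matrix(0L, n, k)
  delta[1, ] <- A[CRF_START, 1:k] + P[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in 1:k) {
        cand <- delta[t - 1, ] + A[1:k, j]
        b <- which.max(cand)           # first max = lowest label index
        delta[t, j] <- cand[b] + P[t, j]
        back[t, j] <- b
      }
    }
  }
  final <- delta[n, ] + A[1:k, CRF_STOP]
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1) {
    for (t in seq(n, 2L)) path[t - 1L] <- back[t, path[t]]
  }
  list(path = CRF_LABELS[path], score = final[path[n]])
}

#' Negative log-likelihood of a gold path, with gradients
#'
#' `loss = log Z - s(X, y_gold) >= 0`. The gradients are the difference
#' between expected and observed sufficient statistics:
#' `dP = posterior - onehot(gold)`, `dA = E[transition counts] -
#' observed transitions` (including the START/STOP boundary entries).
#'
#' @inheritParams sequence_score
#' @param gold_y gold label path.
#' @return list with `loss`, `dP` (n x 3) and `dA` (5 x 5).
#' @export
crf_nll <- function(P, A, gold_y) {
  y <- labels_to_ids(gold_y)
  n <- nrow(P)
  if (length(y) != n) stop("gold path length must equal nrow(P)")
  fb <- crf_forward_backward(P, A)
  loss <- fb$logZ - sequence_score(P, A, y)
  dP <- fb$node_marginals
  dP[cbind(seq_len(n), y)] <- dP[cbind(seq_len(n), y)] - 1
  dA <- fb$trans_expected
  dA[CRF_START, y[1]] <- dA[CRF_START, y[1]] - 1
  dA[y[n], CRF_STOP] <- dA[y[n], CRF_STOP] - 1
  if (n > 1) {
    for (t in 1:(n - 1)) dA[y[t], y[t + 1]] <- dA[y[t], y[t + 1]] - 1
  }
  list(loss = loss, dP = dP, dA = dA)
}
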
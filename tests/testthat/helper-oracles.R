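# Independent oracles used across test files. These deliberately avoid
# the package's own dynamic-programming / vectorized code paths.

# Exhaustive enumeration over all 3^n label paths.
brute_crf <- function(P, A) {
  n <- nrow(P)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  scores <- apply(paths, 1, function(y) {
    s <- A[4, y[1]] + A[y[n], 5]
    for (t in seq_len(n)) s <- s + P[t, y[t]]
    if (n > 1) for (t in 1:(n - 1)) s <- s + A[y[t], y[t + 1]]
    s
  })
  best <- which.max(scores)
  m <- max(scores)
  list(logZ = m + log(sum(exp(scores - m))),
       best_score = scores[best],
       best_path = c("B", "I", "O")[paths[best, ]],
       scores = scores)
}

rand_crf_instance <- function(n) {
  list(P = matrix(stats::rnorm(n * 3), n, 3),
       A = matrix(stats::rnorm(25), 5, 5))
}

# Scalar-loop transcription of the coupled-gate peephole cell: explicit
# elementwise sums, no matrix products.
lstm_step_scalar <- function(x, h_prev, c_prev, cell) {
  H <- length(cell$b_i)
  i <- numeric(H); g <- numeric(H); c_t <- numeric(H)
  o <- numeric(H); h_t <- numeric(H)
  sig <- function(z) 1 / (1 + exp(-z))
  for (r in 1:H) {
    ai <- cell$b_i[r]
    for (col in seq_along(x)) ai <- ai + cell$W_xi[r, col] * x[col]
    for (col in 1:H) ai <- ai + cell$W_hi[r, col] * h_prev[col] +
        cell$W_ci[r, col] * c_prev[col]
    i[r] <- sig(ai)
    ag <- cell$b_c[r]
    for (col in seq_along(x)) ag <- ag + cell$W_xc[r, col] * x[col]
    for (col in 1:H) ag <- ag + cell$W_hc[r, col] * h_prev[col]
    g[r] <- tanh(ag)
    c_t[r] <- (1 - i[r]) * c_prev[r] + i[r] * g[r]
  }
  for (r in 1:H) {
    ao <- cell$b_o[r]
    for (col in seq_along(x)) ao <- ao + cell$W_xo[r, col] * x[col]
    for (col in 1:H) ao <- ao + cell$W_ho[r, col] * h_prev[col] +
        cell$W_co[r, col] * c_t[col]
    o[r] <- sig(ao)
    h_t[r] <- o[r] * tanh(c_t[r])
  }
  list(h = h_t, c = c_t)
}

rand_cell <- function(D, H) {
  cell <- distagger:::new_lstm_cell(D, H, seed = NULL)
  for (nm in names(cell)) {
    cell[[nm]] <- if (is.matrix(cell[[nm]])) {
      matrix(stats::rnorm(length(cell[[nm]])) * 0.5,
             nrow(cell[[nm]]), ncol(cell[[nm]]))
    } else stats::rnorm(length(cell[[nm]])) * 0.5
  }
  cell
}

# Flatten a tagger model's parameters / gradient structure into one
# numeric vector (embedding table included), for finite differences.
flatten_tagger <- function(params) {
  c(as.numeric(params$emb),
    unlist(lapply(params$fwd, as.numeric), use.names = FALSE),
    unlist(lapply(params$bwd, as.numeric), use.names = FALSE),
    as.numeric(params$W_e), params$b_e, as.numeric(params$A))
}

unflatten_tagger <- function(template, x) {
  pos <- 1L
  take <- function(obj) {
    n <- length(obj)
    v <- x[pos:(pos + n - 1L)]
    pos <<- pos + n
    if (is.matrix(obj)) matrix(v, nrow(obj), ncol(obj)) else v
  }
  p <- template
  p$emb <- take(template$emb)
  for (nm in names(template$fwd)) p$fwd[[nm]] <- take(template$fwd[[nm]])
  for (nm in names(template$bwd)) p$bwd[[nm]] <- take(template$bwd[[nm]])
  p$W_e <- take(template$W_e)
  p$b_e <- take(template$b_e)
  p$A <- take(template$A)
  p
}

flatten_tagger_grads <- function(g, V, D) {
  emb <- if (is.matrix(g$emb)) g$emb else {
    m <- matrix(0, V, D)
    for (t in seq_along(g$emb$ids)) {
      m[g$emb$ids[t], ] <- m[g$emb$ids[t], ] + g$emb$rows[t, ]
    }
    m
  }
  c(as.numeric(emb),
    unlist(lapply(g$fwd, as.numeric), use.names = FALSE),
    unlist(lapply(g$bwd, as.numeric), use.names = FALSE),
    as.numeric(g$W_e), g$b_e, as.numeric(g$A))
}

# Fixed synthetic predictions: drop every third gold mention, leaving a
# deterministic imperfect tagger for bootstrap experiments.
perturbed_predictions <- function(docs) {
  lapply(docs, function(d) {
    m <- d$mentions
    keep <- rep(TRUE, nrow(m))
    if (nrow(m)) keep[seq(1, nrow(m), by = 3)] <- FALSE
    m <- m[keep, , drop = FALSE]
    annotated_document(d$doc_id, d$title, d$abstract,
                       mention_frame(m$start, m$end, m$text, m$label),
                       validate = FALSE)
  })
}

# A tiny deterministic annotated corpus for tagger smoke tests.
tiny_docs <- function(n_docs = 4, seed = 5) {
  generate_ner_corpus(fixture_config(n_docs = n_docs,
                                     sentences_per_doc = 4,
                                     disease_lexicon_size = 20,
                                     seed = seed))
}
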
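# Skip-gram word embeddings trained with negative sampling (NEG).
#
# The score of a (center, context) pair is the inner product of the
# center word's input vector with the context word's output vector. The
# per-pair objective, maximized by stochastic gradient ascent, is
#
#   L = log sigma(s(w, c)) + sum_i log sigma(-s(w~_i, c)),
#
# with k noise words w~_i drawn from Q(w) proportional to
# count(w)^power. No hierarchical softmax and no frequent-word
# subsampling: the objective is exactly the NEG contrast above.

#' Build a vocabulary from a token stream
#'
#' @param tokens character vector (or list of character vectors) of
#'   tokens.
#' @param min_count words occurring fewer than `min_count` times are
#'   dropped; must be >= 1.
#' @return an object of class `vocabulary`: list with `words` (ordered by
#'   descending count, ties lexicographic), `counts`, `min_count` and an
#'   `index` lookup environment.
#' @export
build_vocab <- function(tokens, min_count = 1L) {
  if (min_count < 1) stop("min_count must be >= 1")
  if (is.list(tokens)) tokens <- unlist(tokens, use.names = FALSE)
  tab <- table(tokens)
  counts <- as.integer(tab)
  words <- as.character(names(tab))
  keep <- counts >= min_count
  words <- words[keep]; counts <- counts[keep]
  ord <- order(-counts, words, method = "radix")
  words <- words[ord]; counts <- counts[ord]
  index <- new.env(parent = emptyenv())
  for (i in seq_along(words)) assign(words[i], i, envir = index)
  structure(list(words = words, counts = counts,
                 min_count = as.integer(min_count), index = index),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d words, min_count=%d>\n",
              length(x$words), x$min_count))
  invisible(x)
}

vocab_lookup <- function(vocab, words) {
  vapply(words, function(w) {
    v <- mget(w, envir = vocab$index, ifnotfound = list(NA_integer_))[[1]]
    as.integer(v)
  }, integer(1), USE.NAMES = FALSE)
}

#' Noise distribution for negative sampling
#'
#' `Q(w)` proportional to `count(w)^power`, normalized over the
#' vocabulary. `power = 0.75` is the conventional smoothing; `power = 0`
#' gives the uniform distribution and `power = 1` the unigram
#' distribution.
#'
#' @param vocab a [build_vocab()] vocabulary; must be non-empty.
#' @param power nonnegative exponent.
#' @return an object of class `noise_distribution`: list with
#'   `probabilities` (sums to 1) and `power`.
#' @export
noise_distribution <- function(vocab, power = 0.75) {
  if (!length(vocab$words)) stop("empty vocabulary")
  if (power < 0) stop("power must be >= 0")
  w <- vocab$counts^power
  structure(list(probabilities = w / sum(w), power = power),
            class = "noise_distribution")
}

new_embedding_model <- function(vocab, dimension, seed = 1L) {
  V <- length(vocab$words)
  with_seed(seed, {
    inp <- matrix(runif(V * dimension, -0.5 / dimension, 0.5 / dimension),
                  V, dimension)
  })
  structure(list(
    vocab = vocab,
    input_vectors = inp,          # center-word vectors
    output_vectors = matrix(0, V, dimension),  # context-word vectors
    dimension = as.integer(dimension)
  ), class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model: |V|=%d, D=%d>\n",
              length(x$vocab$words), x$dimension))
  invisible(x)
}

#' Pair score of a (center, context) pair
#'
#' The inner product of the center word's input vector with the context
#' word's output vector.
#'
#' @param center_index,context_index 1-based vocabulary indices.
#' @param model an `embedding_model`.
#' @return a scalar score.
#' @export
pair_score <- function(center_index, context_index, model) {
  V <- nrow(model$input_vectors)
  if (center_index < 1 || center_index > V ||
        context_index < 1 || context_index > V) {
    stop("word index out of range")
  }
  sum(model$input_vectors[center_index, ] *
        model$output_vectors[context_index, ])
}

#' Negative-sampling objective for one positive pair
#'
#' `log sigma(s(center, context)) + sum_i log sigma(-s(neg_i, context))`.
#' This is an objective to maximize; its value is always <= 0.
#'
#' @param center,context 1-based vocabulary indices of the positive pair.
#' @param negatives integer vector of sampled noise-word indices (may be
#'   empty, in which case only the positive term is returned).
#' @param model an `embedding_model`.
#' @return scalar objective value.
#' @export
neg_objective <- function(center, context, negatives, model) {
  val <- log(sigmoid(pair_score(center, context, model)))
  for (ng in negatives) {
    val <- val + log(sigmoid(-pair_score(ng, context, model)))
  }
  val
}

#' Analytic gradient of the negative-sampling objective
#'
#' Returns the gradient of [neg_objective()] with respect to every
#' parameter row it touches. Used for gradient ascent and checked against
#' central finite differences in the test suite.
#'
#' @inheritParams neg_objective
#' @return list with `d_input` (named by row index) and `d_output`
#'   gradient rows.
#' @export
neg_objective_grad <- function(center, context, negatives, model) {
  v_w <- model$input_vectors[center, ]
  u_c <- model$output_vectors[context, ]
  g_pos <- 1 - sigmoid(sum(v_w * u_c))
  d_vw <- g_pos * u_c
  d_uc <- g_pos * v_w
  d_input <- list(); d_output <- list()
  for (ng in negatives) {
    v_n <- model$input_vectors[ng, ]
    g_neg <- -sigmoid(sum(v_n * u_c))
    key <- as.character(ng)
    d_input[[key]] <- (if (is.null(d_input[[key]])) 0 else d_input[[key]]) +
      g_neg * u_c
    d_uc <- d_uc + g_neg * v_n
  }
  key_c <- as.character(center)
  d_input[[key_c]] <- (if (is.null(d_input[[key_c]])) 0 else d_input[[key_c]]) +
    d_vw
  d_output[[as.character(context)]] <- d_uc
  list(d_input = d_input, d_output = d_output)
}

#' Train skip-gram embeddings with negative sampling
#'
#' For each corpus position and each context offset within the (fixed)
#' window, performs one stochastic gradient-ascent step on the NEG
#' objective: the positive pair plus `k_negatives` noise words drawn from
#' the unigram^power distribution. The learning rate decays linearly from
#' `learning_rate` to `learning_rate/100` over all scheduled updates.
#' Single-threaded and bit-reproducible for a fixed seed.
#'
#' @param corpus a list of character vectors (sentences of tokens) or a
#'   single character vector treated as one sentence.
#' @param dimension embedding dimension (default 200).
#' @param window context half-width n: offsets -n..n excluding 0,
#'   truncated at sentence edges.
#' @param k_negatives noise words per positive pair (default 5, the
#'   small-corpus setting).
#' @param epochs passes over the corpus.
#' @param learning_rate initial step size.
#' @param min_count vocabulary threshold.
#' @param power noise-distribution exponent.
#' @param seed integer seed controlling initialization and sampling.
#' @return an `embedding_model`.
#' @export
train_skipgram <- function(corpus, dimension = 200L, window = 5L,
                           k_negatives = 5L, epochs = 5L,
                           learning_rate = 0.025, min_count = 1L,
                           power = 0.75, seed = 1L) {
  if (window < 1) stop("window must be >= 1")
  if (k_negatives < 0) stop("k_negatives must be >= 0")
  if (dimension < 1) stop("dimension must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  if (!is.list(corpus)) corpus <- list(corpus)
  if (!length(corpus) || !sum(lengths(corpus))) stop("empty corpus")
  vocab <- build_vocab(corpus, min_count = min_count)
  model <- new_embedding_model(vocab, dimension, seed = seed)
  q <- noise_distribution(vocab, power)$probabilities
  V <- length(vocab$words)
  sent_ids <- lapply(corpus, function(s) {
    ids <- vocab_lookup(vocab, s)
    ids[!is.na(ids)]
  })
  sent_ids <- sent_ids[lengths(sent_ids) > 0]
  n_pairs_sched <- sum(vapply(sent_ids, function(ids) {
    n <- length(ids)
    sum(pmin(seq_len(n) - 1L, window) + pmin(n - seq_len(n), window))
  }, numeric(1))) * epochs
  if (n_pairs_sched == 0) stop("corpus has no context pairs")
  inp <- model$input_vectors
  out <- model$output_vectors
  lr0 <- learning_rate
  done <- 0
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      for (ids in sent_ids) {
        n <- length(ids)
        for (t in seq_len(n)) {
          w <- ids[t]
          lo <- max(1L, t - window); hi <- min(n, t + window)
          for (j in lo:hi) {
            if (j == t) next
            lr <- lr0 * max(1 - done / n_pairs_sched, 0.01)
            cx <- ids[j]
            u_c <- out[cx, ]
            v_w <- inp[w, ]
            # positive update
            g <- (1 - sigmoid(sum(v_w * u_c))) * lr
            d_uc <- g * v_w
            d_vw <- g * u_c
            if (k_negatives > 0) {
              negs <- sample.int(V, k_negatives, replace = TRUE, prob = q)
              for (ng in negs) {
                v_n <- inp[ng, ]
                gn <- -sigmoid(sum(v_n * u_c)) * lr
                d_uc <- d_uc + gn * v_n
                inp[ng, ] <- v_n + gn * u_c
              }
            }
            inp[w, ] <- inp[w, ] + d_vw
            out[cx, ] <- u_c + d_uc
            done <- done + 1
          }
        }
      }
    }
  })
  model$input_vectors <- inp
  model$output_vectors <- out
  model
}

#' Mean NEG objective over a frozen sample of pairs
#'
#' Deterministically enumerates (center, context, negatives) triples from
#' the corpus at a fixed seed and averages [neg_objective()] under the
#' given model. Used to monitor training progress.
#'
#' @param corpus as in [train_skipgram()].
#' @param model an `embedding_model`.
#' @param window,k_negatives context and noise settings.
#' @param n_pairs number of pairs to sample.
#' @param seed sampling seed.
#' @return mean objective value (<= 0; higher is better).
#' @export
mean_neg_objective <- function(corpus, model, window = 5L, k_negatives = 5L,
                               n_pairs = 500L, seed = 99L) {
  if (!is.list(corpus)) corpus <- list(corpus)
  vocab <- model$vocab
  q <- noise_distribution(vocab)$probabilities
  V <- length(vocab$words)
  sent_ids <- lapply(corpus, function(s) {
    ids <- vocab_lookup(vocab, s); ids[!is.na(ids)]
  })
  sent_ids <- sent_ids[lengths(sent_ids) >= 2]
  with_seed(seed, {
    vals <- numeric(n_pairs)
    for (p in seq_len(n_pairs)) {
      ids <- sent_ids[[sample.int(length(sent_ids), 1)]]
      n <- length(ids)
      t <- sample.int(n, 1)
      lo <- max(1L, t - window); hi <- min(n, t + window)
      js <- setdiff(lo:hi, t)
      j <- if (length(js) == 1) js else js[sample.int(length(js), 1)]
      negs <- if (k_negatives > 0) {
        sample.int(V, k_negatives, replace = TRUE, prob = q)
      } else integer(0)
      vals[p] <- neg_objective(ids[t], ids[j], negs, model)
    }
    mean(vals)
  })
}

#' Cosine similarity between two words
#'
#' Computed over the input vectors.
#'
#' @param word_a,word_b vocabulary words.
#' @param model an `embedding_model`.
#' @return scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(word_a, word_b, model) {
  ia <- vocab_lookup(model$vocab, word_a)
  ib <- vocab_lookup(model$vocab, word_b)
  if (is.na(ia)) stop(sprintf("word %s not in vocabulary", dQuote(word_a)))
  if (is.na(ib)) stop(sprintf("word %s not in vocabulary", dQuote(word_b)))
  a <- model$input_vectors[ia, ]; b <- model$input_vectors[ib, ]
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Nearest neighbors of a word by cosine similarity
#'
#' @param word query word (excluded from the result).
#' @param model an `embedding_model`.
#' @param top_n number of neighbors.
#' @return data.frame with columns `word`, `similarity`, sorted by
#'   descending similarity, ties broken lexicographically.
#' @export
nearest_neighbors <- function(word, model, top_n = 10L) {
  iq <- vocab_lookup(model$vocab, word)
  if (is.na(iq)) stop(sprintf("word %s not in vocabulary", dQuote(word)))
  M <- model$input_vectors
  qv <- M[iq, ]
  norms <- sqrt(rowSums(M^2))
  sims <- as.numeric(M %*% qv) / (norms * sqrt(sum(qv^2)))
  sims[iq] <- -Inf
  ord <- order(-sims, model$vocab$words, method = "radix")
  ord <- ord[seq_len(min(top_n, length(ord)))]
  ord <- ord[is.finite(sims[ord])]
  data.frame(word = model$vocab$words[ord], similarity = sims[ord],
             stringsAsFactors = FALSE)
}
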
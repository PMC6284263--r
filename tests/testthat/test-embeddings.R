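test_that("vocabulary building counts, thresholds and orders correctly", {
  v <- build_vocab(c("a", "a", "b"), min_count = 2)
  expect_equal(v$words, "a")
  expect_equal(v$counts, 2L)
  expect_error(build_vocab(letters, min_count = 0), "min_count")
  # min_count = 1 keeps every distinct token
  v1 <- build_vocab(c("x", "y", "x"))
  expect_setequal(v1$words, c("x", "y"))
  # counts match a brute-force frequency table on a larger stream
  set.seed(2)
  stream <- sample(sprintf("t%02d", 1:40), 10000, replace = TRUE)
  v2 <- build_vocab(stream)
  brute <- table(stream)
  expect_equal(v2$counts, as.integer(brute[v2$words]),
               ignore_attr = TRUE)
  # descending count order, ties lexicographic
  expect_true(all(diff(v2$counts) <= 0))
})

test_that("noise distribution follows count^power, normalized", {
  v <- build_vocab(c(rep("a", 3), "b"))
  expect_equal(noise_distribution(v, power = 0)$probabilities, c(0.5, 0.5))
  expect_equal(noise_distribution(v, power = 1)$probabilities, c(0.75, 0.25))
  v2 <- build_vocab(c(rep("a", 16), "b"))
  expect_equal(noise_distribution(v2, power = 0.75)$probabilities,
               c(8 / 9, 1 / 9))
  expect_error(noise_distribution(build_vocab(character(0))), "empty")
  # sampling 1e5 draws reproduces Q (chi-squared, p > 0.001)
  set.seed(7)
  v3 <- build_vocab(rep(sprintf("w%d", 1:8), times = c(40, 25, 12, 9, 6, 4, 3, 1)))
  q <- noise_distribution(v3)$probabilities
  draws <- sample.int(8, 1e5, replace = TRUE, prob = q)
  p <- stats::chisq.test(tabulate(draws, 8), p = q)$p.value
  expect_gt(p, 0.001)
})

test_that("pair score is the input-output inner product", {
  v <- build_vocab(c("a", "b", "c"))
  m <- distagger:::new_embedding_model(v, 5, seed = 1)
  m$input_vectors[] <- 0
  expect_equal(pair_score(1, 2, m), 0)
  m$input_vectors[1, ] <- c(1, 0, 0, 0, 0)
  m$output_vectors[2, ] <- c(1, 0, 0, 0, 0)
  expect_equal(pair_score(1, 2, m), 1)
  set.seed(3)
  m$input_vectors <- matrix(stats::rnorm(15), 3, 5)
  m$output_vectors <- matrix(stats::rnorm(15), 3, 5)
  naive <- sum(m$input_vectors[2, ] * m$output_vectors[3, ])
  expect_equal(pair_score(2, 3, m), naive, tolerance = 1e-12)
  expect_error(pair_score(9, 1, m), "out of range")
})

test_that("NEG objective matches its closed forms", {
  v <- build_vocab(c("a", "b", "c"))
  m <- distagger:::new_embedding_model(v, 4, seed = 1)
  m$input_vectors[] <- 0   # zero model: every score 0, sigma(0) = 0.5
  expect_equal(neg_objective(1, 2, rep(3L, 5), m), 6 * log(0.5),
               tolerance = 1e-12)
  # k = 0: positive term only
  set.seed(5)
  m$input_vectors <- matrix(stats::rnorm(12) * 0.5, 3, 4)
  m$output_vectors <- matrix(stats::rnorm(12) * 0.5, 3, 4)
  s <- pair_score(1, 2, m)
  expect_equal(neg_objective(1, 2, integer(0), m), log(1 / (1 + exp(-s))))
})

test_that("NEG analytic gradient matches finite differences", {
  set.seed(11)
  worst <- 0
  for (rep in 1:100) {
    v <- build_vocab(letters[1:4])
    m <- distagger:::new_embedding_model(v, 5, seed = rep)
    m$input_vectors <- matrix(stats::rnorm(20) * 0.6, 4, 5)
    m$output_vectors <- matrix(stats::rnorm(20) * 0.6, 4, 5)
    negs <- sample.int(4, 3, replace = TRUE)   # repeats allowed
    g <- neg_objective_grad(1L, 2L, negs, m)
    h <- 1e-5
    for (tab in c("input_vectors", "output_vectors")) {
      for (row in 1:4) for (col in 1:5) {
        m1 <- m; m1[[tab]][row, col] <- m1[[tab]][row, col] + h
        m2 <- m; m2[[tab]][row, col] <- m2[[tab]][row, col] - h
        fd <- (neg_objective(1L, 2L, negs, m1) -
                 neg_objective(1L, 2L, negs, m2)) / (2 * h)
        key <- as.character(row)
        ana <- if (tab == "input_vectors") {
          if (is.null(g$d_input[[key]])) 0 else g$d_input[[key]][col]
        } else {
          if (is.null(g$d_output[[key]])) 0 else g$d_output[[key]][col]
        }
        worst <- max(worst, abs(fd - ana) / max(abs(fd), abs(ana), 1e-8))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("skip-gram training is a no-op at lr = 0 and seed-reproducible", {
  corp <- list(c("a", "b", "c", "a"), c("b", "c", "a"))
  m0 <- train_skipgram(corp, dimension = 6, window = 2, epochs = 1,
                       learning_rate = 0, seed = 3)
  init <- distagger:::new_embedding_model(build_vocab(corp), 6, seed = 3)
  expect_equal(m0$input_vectors, init$input_vectors)
  expect_equal(m0$output_vectors, init$output_vectors)
  m1 <- train_skipgram(corp, dimension = 6, window = 2, epochs = 2, seed = 4)
  m2 <- train_skipgram(corp, dimension = 6, window = 2, epochs = 2, seed = 4)
  expect_identical(m1$input_vectors, m2$input_vectors)
  expect_error(train_skipgram(corp, window = 0), "window")
  expect_error(train_skipgram(list()), "empty")
})

test_that("one epoch of training raises the mean NEG objective", {
  corp <- generate_embedding_corpus(vocab_size = 20, cluster_count = 2,
                                    n_tokens = 4000, seed = 8)
  vocab <- build_vocab(corp)
  init <- distagger:::new_embedding_model(vocab, 15, seed = 21)
  before <- mean_neg_objective(corp, init, n_pairs = 400, seed = 50)
  trained <- train_skipgram(corp, dimension = 15, window = 3,
                            epochs = 1, seed = 21)
  after <- mean_neg_objective(corp, trained, n_pairs = 400, seed = 50)
  expect_gt(after, before)
})

test_that("cosine similarity and neighbor ranking match a brute-force scan", {
  v <- build_vocab(sprintf("w%02d", 1:20))
  m <- distagger:::new_embedding_model(v, 8, seed = 2)
  set.seed(14)
  m$input_vectors <- matrix(stats::rnorm(160), 20, 8)
  w <- v$words
  expect_equal(cosine_similarity(w[1], w[1], m), 1.0, tolerance = 1e-12)
  m$input_vectors[2, ] <- c(1, 0, 0, 0, 0, 0, 0, 0)
  m$input_vectors[3, ] <- c(0, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(cosine_similarity(w[2], w[3], m), 0.0)
  expect_error(cosine_similarity("nope", w[1], m), "nope")
  nn <- nearest_neighbors(w[5], m, top_n = 3)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- vapply(seq_len(20), function(i) {
    if (i == 5) -Inf else cos(m$input_vectors[5, ], m$input_vectors[i, ])
  }, numeric(1))
  expect_equal(nn$word[1], w[which.max(sims)])
  expect_false(w[5] %in% nn$word)
  expect_true(all(diff(nn$similarity) <= 0))
})
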
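test_that("emission projection has the right shape and zero case", {
  cfg <- tagger_config(word_dim = 6, hidden = 4, seed = 2)
  m <- new_tagger_model(c("alpha", "beta"), cfg)
  ids <- distagger:::token_ids(m, c("alpha", "beta", "unknown", "alpha"))
  expect_equal(ids[3], 1L)  # OOV -> <unk>
  P <- emission_scores(m, ids)
  expect_equal(dim(P), c(4L, 3L))
  m$params$W_e[] <- 0; m$params$b_e[] <- 0
  expect_equal(emission_scores(m, ids), matrix(0, 4, 3))
})

test_that("training with lr = 0 returns the initialization", {
  docs <- tiny_docs(2, seed = 3)
  cfg <- tagger_config(word_dim = 8, hidden = 4, learning_rate = 0,
                       epochs = 2, seed = 6)
  m <- train_tagger(docs, config = cfg)
  sents <- distagger:::docs_to_sentences(docs)
  words <- sort(unique(tolower(unlist(lapply(sents, function(s) s$tokens$text)))),
                method = "radix")
  init <- new_tagger_model(words, cfg)
  expect_equal(m$params, init$params)
  expect_error(train_tagger(list(), config = cfg), "empty")
})

test_that("sentence NLL gradients match finite differences through the encoder", {
  set.seed(51)
  cfg <- tagger_config(word_dim = 4, hidden = 3, dropout = 0, seed = 8)
  m <- new_tagger_model(c("aa", "bb", "cc"), cfg)
  ids <- c(2L, 4L, 1L, 3L)
  gold <- c("B", "I", "O", "B")
  res <- tagger_sentence_loss(m, ids, gold, full_emb_grad = TRUE)
  ana <- flatten_tagger_grads(res$grads, nrow(m$params$emb), 4)
  x0 <- flatten_tagger(m$params)
  h <- 1e-5
  worst <- 0
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    mp <- m; mp$params <- unflatten_tagger(m$params, xp)
    mm <- m; mm$params <- unflatten_tagger(m$params, xm)
    fd <- (tagger_sentence_loss(mp, ids, gold)$loss -
             tagger_sentence_loss(mm, ids, gold)$loss) / (2 * h)
    worst <- max(worst, abs(fd - ana[i]) / max(abs(fd), abs(ana[i]), 1e-6))
  }
  expect_lt(worst, 1e-4)
})

test_that("training loss is non-increasing early at a small learning rate", {
  docs <- tiny_docs(3, seed = 15)
  cfg <- tagger_config(word_dim = 10, hidden = 5, dropout = 0,
                       learning_rate = 0.01, epochs = 5, seed = 9)
  m <- train_tagger(docs, config = cfg)
  expect_true(all(diff(m$history$mean_loss) < 1e-6))
})

test_that("the no-CRF ablation decodes legal BIO after repair", {
  docs <- tiny_docs(3, seed = 19)
  cfg <- tagger_config(word_dim = 8, hidden = 4, use_crf = FALSE,
                       epochs = 2, seed = 10)
  m <- train_tagger(docs, config = cfg)
  for (d in docs) {
    pred <- predict_mentions(m, d)
    # legal mentions only: decodable as B I* runs (no overlap, in range)
    expect_true(all(pred$start < pred$end))
    if (nrow(pred) > 1) {
      expect_true(all(pred$start[-1] >= pred$end[-nrow(pred)]))
    }
  }
  # per-token path from a random emission matrix is repaired to legal BIO
  tags <- distagger:::repair_bio(c("I", "O", "I", "I", "B"))
  expect_equal(tags, c("B", "O", "B", "I", "B"))
})

test_that("the no-Bi-LSTM ablation trains a per-token affine classifier", {
  docs <- tiny_docs(3, seed = 23)
  cfg <- tagger_config(word_dim = 8, hidden = 4, use_bilstm = FALSE,
                       dropout = 0, epochs = 3, seed = 11)
  m <- train_tagger(docs, config = cfg)
  # emission projection must read the embedding dimension directly
  expect_equal(nrow(m$params$W_e), 8L)
  ids <- distagger:::token_ids(m, c("the", "of"))
  expect_equal(dim(emission_scores(m, ids)), c(2L, 3L))
})

test_that("training is deterministic for a fixed seed", {
  docs <- tiny_docs(2, seed = 27)
  cfg <- tagger_config(word_dim = 6, hidden = 3, epochs = 2, seed = 13)
  m1 <- train_tagger(docs, config = cfg)
  m2 <- train_tagger(docs, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(predict_mentions(m1, docs[[1]]),
                   predict_mentions(m2, docs[[1]]))
})

test_that("pretrained vectors seed the embedding table", {
  docs <- tiny_docs(2, seed = 29)
  sents <- distagger:::docs_to_sentences(docs)
  words <- sort(unique(tolower(unlist(lapply(sents, function(s) s$tokens$text)))),
                method = "radix")
  pre <- list(words = words[1:3],
              vectors = matrix(7, 3, 6))
  cfg <- tagger_config(word_dim = 6, hidden = 3, learning_rate = 0,
                       epochs = 1, seed = 14)
  m <- train_tagger(docs, embeddings = pre, config = cfg)
  rows <- match(words[1:3], m$words)
  expect_true(all(m$params$emb[rows, ] == 7))
  expect_error(
    train_tagger(docs, embeddings = list(words = "a", vectors = matrix(0, 1, 9)),
                 config = cfg),
    "dimension")
})
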
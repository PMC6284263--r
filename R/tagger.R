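# The sequence tagger: embedding lookup -> Bi-LSTM encoder -> affine
# emission projection P^sem (n x 3, raw scores) -> linear-chain CRF.
# Trained by sentence-level SGD on the CRF negative log-likelihood with
# input dropout and global-norm gradient clipping. All gradients are
# computed analytically (see lstm.R / crf.R) and flow through the
# encoder into the embedding table.

#' Tagger configuration
#'
#' Defaults follow the tuned settings for this architecture: 200-dim
#' word vectors, 100 hidden LSTM units per direction, bidirectional
#' encoding, a CRF output layer and input dropout, trained with plain
#' SGD.
#'
#' @param word_dim token embedding dimension.
#' @param hidden LSTM hidden size per direction.
#' @param use_bilstm when FALSE the emission projection reads the
#'   embedded token directly (per-token affine classifier ablation).
#' @param use_crf when FALSE training uses per-token softmax
#'   cross-entropy and decoding is per-token argmax followed by BIO
#'   repair.
#' @param dropout input dropout rate applied to embedded tokens during
#'   training only.
#' @param word_dropout_alpha strength of frequency-based word dropout:
#'   during training a token of corpus count c is replaced by the
#'   `<unk>` symbol with probability alpha / (alpha + c), so the UNK
#'   embedding is trained on realistic contexts; 0 disables.
#' @param learning_rate SGD step size.
#' @param epochs training epochs.
#' @param clip global gradient-norm clip.
#' @param constrain_bio forbid the O -> I transition at decode time.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return a named list of settings.
#' @export
tagger_config <- function(word_dim = 200L, hidden = 100L,
                          use_bilstm = TRUE, use_crf = TRUE,
                          dropout = 0.5, word_dropout_alpha = 0.25,
                          learning_rate = 0.1,
                          epochs = 10L, clip = 5, constrain_bio = FALSE,
                          seed = 1L) {
  list(word_dim = as.integer(word_dim), hidden = as.integer(hidden),
       use_bilstm = isTRUE(use_bilstm), use_crf = isTRUE(use_crf),
       dropout = dropout, word_dropout_alpha = word_dropout_alpha,
       learning_rate = learning_rate,
       epochs = as.integer(epochs), clip = clip,
       constrain_bio = isTRUE(constrain_bio), seed = as.integer(seed))
}

UNK_TOKEN <- "<unk>"

#' Initialize a tagger model
#'
#' @param words character vector of vocabulary words (lowercased); an
#'   `<unk>` entry is prepended for out-of-vocabulary tokens.
#' @param config a [tagger_config()].
#' @param embeddings optional pretrained vectors (an `embedding_model`
#'   or a list with `words`/`vectors`); matching rows (by lowercased
#'   word) initialize the embedding table, which remains trainable.
#' @return an object of class `tagger_model`.
#' @export
new_tagger_model <- function(words, config = tagger_config(),
                             embeddings = NULL) {
  words <- c(UNK_TOKEN, setdiff(unique(words), UNK_TOKEN))
  V <- length(words)
  D <- config$word_dim
  H <- config$hidden
  enc_dim <- if (config$use_bilstm) 2L * H else D
  with_seed(config$seed, {
    emb <- matrix(runif(V * D, -sqrt(3 / D), sqrt(3 / D)), V, D)
    lim <- sqrt(6 / (enc_dim + CRF_K))
    W_e <- matrix(runif(enc_dim * CRF_K, -lim, lim), enc_dim, CRF_K)
  })
  if (!is.null(embeddings)) {
    src_words <- if (inherits(embeddings, "embedding_model")) {
      embeddings$vocab$words
    } else embeddings$words
    src_vec <- if (inherits(embeddings, "embedding_model")) {
      embeddings$input_vectors
    } else embeddings$vectors
    if (ncol(src_vec) != D) {
      stop(sprintf("pretrained vectors have dimension %d, config wants %d",
                   ncol(src_vec), D))
    }
    hit <- match(words, tolower(src_words))
    ok <- which(!is.na(hit))
    if (length(ok)) emb[ok, ] <- src_vec[hit[ok], , drop = FALSE]
  }
  params <- list(
    emb = emb,
    fwd = new_lstm_cell(D, H, seed = config$seed + 1L),
    bwd = new_lstm_cell(D, H, seed = config$seed + 2L),
    W_e = W_e,
    b_e = numeric(CRF_K),
    A = matrix(0, CRF_K + 2L, CRF_K + 2L)
  )
  index <- new.env(parent = emptyenv())
  for (i in seq_along(words)) assign(words[i], i, envir = index)
  structure(list(words = words, index = index, config = config,
                 params = params, label_order = CRF_LABELS,
                 history = NULL),
            class = "tagger_model")
}

#' @export
print.tagger_model <- function(x, ...) {
  cat(sprintf(
    "<tagger_model: |V|=%d, D=%d, H=%d, bilstm=%s, crf=%s>\n",
    length(x$words), x$config$word_dim, x$config$hidden,
    x$config$use_bilstm, x$config$use_crf))
  invisible(x)
}

token_ids <- function(model, token_texts) {
  low <- tolower(token_texts)
  ids <- vapply(low, function(w) {
    v <- mget(w, envir = model$index, ifnotfound = list(1L))[[1]]
    as.integer(v)
  }, integer(1), USE.NAMES = FALSE)
  ids
}

# Emission scores P^sem for one sentence of token ids. Returns caches
# needed for backprop.
tagger_forward <- function(model, ids, drop_mask = NULL) {
  p <- model$params
  X0 <- p$emb[ids, , drop = FALSE]
  X <- if (is.null(drop_mask)) X0 else X0 * drop_mask
  if (model$config$use_bilstm) {
    fw <- lstm_forward(X, p$fwd)
    rev_idx <- rev(seq_len(nrow(X)))
    bw <- lstm_forward(X[rev_idx, , drop = FALSE], p$bwd)
    Hcat <- cbind(fw$H_out, bw$H_out[rev_idx, , drop = FALSE])
  } else {
    fw <- NULL; bw <- NULL
    Hcat <- X
  }
  P <- Hcat %*% p$W_e + matrix(p$b_e, nrow(X), CRF_K, byrow = TRUE)
  list(P = P, X = X, Hcat = Hcat, fw = fw, bw = bw)
}

#' Emission scores for a sentence
#'
#' The raw n x 3 affine projection of the encoder states; no softmax is
#' applied (the scores enter the CRF directly).
#'
#' @param model a `tagger_model`.
#' @param ids integer token ids (see vocabulary in `model$words`).
#' @return n x 3 matrix of emission scores.
#' @export
emission_scores <- function(model, ids) {
  tagger_forward(model, ids)$P
}

#' Sentence loss and analytic gradients
#'
#' Negative log-likelihood of the gold path (CRF mode) or summed
#' per-token softmax cross-entropy (`use_crf = FALSE`), with gradients
#' for every parameter: emission projection, transition matrix, both
#' LSTM cells and the embedding rows used by the sentence.
#'
#' @param model a `tagger_model`.
#' @param ids integer token ids of the sentence.
#' @param gold_tags gold BIO labels.
#' @param drop_mask optional n x D multiplicative input-dropout mask.
#' @param full_emb_grad when TRUE the embedding gradient is returned as
#'   a dense V x D matrix (used by gradient checks); otherwise as the
#'   per-token rows plus their ids.
#' @return list with `loss` and `grads`.
#' @export
tagger_sentence_loss <- function(model, ids, gold_tags, drop_mask = NULL,
                                 full_emb_grad = FALSE) {
  p <- model$params
  fwd_res <- tagger_forward(model, ids, drop_mask)
  P <- fwd_res$P
  n <- nrow(P)
  if (model$config$use_crf) {
    nl <- crf_nll(P, p$A, gold_tags)
    loss <- nl$loss; dP <- nl$dP; dA <- nl$dA
  } else {
    y <- labels_to_ids(gold_tags)
    mx <- apply(P, 1, max)
    ex <- exp(P - mx)
    probs <- ex / rowSums(ex)
    loss <- -sum(log(probs[cbind(seq_len(n), y)]))
    dP <- probs
    dP[cbind(seq_len(n), y)] <- dP[cbind(seq_len(n), y)] - 1
    dA <- matrix(0, CRF_K + 2L, CRF_K + 2L)
  }
  dHcat <- dP %*% t(p$W_e)
  gW_e <- crossprod(fwd_res$Hcat, dP)
  gb_e <- colSums(dP)
  if (model$config$use_bilstm) {
    H <- model$config$hidden
    rev_idx <- rev(seq_len(n))
    bk_f <- lstm_backward(p$fwd, fwd_res$fw$cache,
                          dHcat[, 1:H, drop = FALSE])
    bk_b <- lstm_backward(p$bwd, fwd_res$bw$cache,
                          dHcat[rev_idx, (H + 1L):(2L * H), drop = FALSE])
    dX <- bk_f$dX + bk_b$dX[rev_idx, , drop = FALSE]
    g_fwd <- bk_f$grads; g_bwd <- bk_b$grads
  } else {
    dX <- dHcat
    g_fwd <- zero_like_cell(p$fwd); g_bwd <- zero_like_cell(p$bwd)
  }
  if (!is.null(drop_mask)) dX <- dX * drop_mask
  if (full_emb_grad) {
    g_emb <- matrix(0, nrow(p$emb), ncol(p$emb))
    for (t in seq_len(n)) g_emb[ids[t], ] <- g_emb[ids[t], ] + dX[t, ]
    emb_grad <- g_emb
  } else {
    emb_grad <- list(ids = ids, rows = dX)
  }
  list(loss = loss,
       grads = list(emb = emb_grad, fwd = g_fwd, bwd = g_bwd,
                    W_e = gW_e, b_e = gb_e, A = dA))
}

# Sum of squares over a sentence-gradient structure (sparse emb form).
.grad_sq_norm <- function(g) {
  s <- sum(g$emb$rows^2) + sum(g$W_e^2) + sum(g$b_e^2) + sum(g$A^2)
  s + sum(flatten_params(unclass(g$fwd))^2) +
    sum(flatten_params(unclass(g$bwd))^2)
}

.apply_grads <- function(params, g, lr) {
  ids <- g$emb$ids
  for (t in seq_along(ids)) {
    params$emb[ids[t], ] <- params$emb[ids[t], ] - lr * g$emb$rows[t, ]
  }
  for (nm in names(params$fwd)) {
    params$fwd[[nm]] <- params$fwd[[nm]] - lr * g$fwd[[nm]]
    params$bwd[[nm]] <- params$bwd[[nm]] - lr * g$bwd[[nm]]
  }
  params$W_e <- params$W_e - lr * g$W_e
  params$b_e <- params$b_e - lr * g$b_e
  params$A <- params$A - lr * g$A
  params
}

#' Decode BIO tags for a sentence
#'
#' Viterbi under the CRF, or per-token argmax plus BIO repair when the
#' model was configured without the CRF layer.
#'
#' @param model a `tagger_model`.
#' @param ids integer token ids.
#' @return character vector of BIO tags.
#' @export
decode_tags <- function(model, ids) {
  P <- tagger_forward(model, ids)$P
  if (model$config$use_crf) {
    viterbi_decode(P, model$params$A,
                   constrain_bio = model$config$constrain_bio)$path
  } else {
    repair_bio(CRF_LABELS[apply(P, 1, which.max)])
  }
}

# Turn annotated documents into tokenized, BIO-tagged sentences.
docs_to_sentences <- function(docs) {
  out <- list()
  for (d in docs) {
    sents <- split_sentences(d$text)
    for (si in seq_len(nrow(sents))) {
      stext <- substr(d$text, sents$start[si] + 1L, sents$end[si])
      toks <- tokenize(stext)
      if (!nrow(toks)) next
      toks$start <- toks$start + sents$start[si]
      toks$end <- toks$end + sents$start[si]
      tags <- mentions_to_bio(toks, d$mentions)
      out[[length(out) + 1L]] <-
        list(doc_id = d$doc_id, tokens = toks, tags = tags)
    }
  }
  out
}

#' Predict disease mentions for one document
#'
#' Splits the document into sentences, decodes each with the tagger and
#' converts the BIO tags back to character-offset mentions.
#'
#' @param model a trained `tagger_model`.
#' @param doc an [annotated_document()] (its gold mentions are ignored).
#' @return a mention table of predictions.
#' @export
predict_mentions <- function(model, doc) {
  sents <- split_sentences(doc$text)
  all_m <- empty_mentions()
  for (si in seq_len(nrow(sents))) {
    stext <- substr(doc$text, sents$start[si] + 1L, sents$end[si])
    toks <- tokenize(stext)
    if (!nrow(toks)) next
    toks$start <- toks$start + sents$start[si]
    toks$end <- toks$end + sents$start[si]
    tags <- decode_tags(model, token_ids(model, toks$text))
    m <- bio_to_mentions(toks, tags, text = doc$text)
    all_m <- rbind(all_m, m)
  }
  mention_frame(all_m$start, all_m$end, all_m$text, all_m$label)
}

#' Tag a corpus
#'
#' @param model a trained `tagger_model`.
#' @param docs list of annotated documents.
#' @param use_abbrev when TRUE, abbreviation pairs are resolved per
#'   document and merged over the tagger output with abbreviation
#'   precedence (see [merge_labels()]).
#' @return list of documents whose mention tables are the predictions.
#' @export
tag_corpus <- function(model, docs, use_abbrev = FALSE) {
  lapply(docs, function(d) {
    pred <- predict_mentions(model, d)
    if (use_abbrev) {
      pairs <- resolve_pairs(d$text)
      ab <- abbreviation_labels(d, pred, pairs)
      pred <- merge_labels(pred, ab)
    }
    annotated_document(d$doc_id, d$title, d$abstract, pred)
  })
}

#' Train the Bi-LSTM-CRF tagger
#'
#' Sentence-level SGD on the sequence NLL with input dropout and
#' global-norm gradient clipping. When dev documents are supplied,
#' mention-level F1 is computed after each epoch and the best-dev
#' parameters are returned. Deterministic for a fixed seed and
#' single-threaded execution.
#'
#' @param train_docs list of annotated documents (training).
#' @param dev_docs optional list of annotated documents for model
#'   selection.
#' @param embeddings optional pretrained word vectors.
#' @param config a [tagger_config()].
#' @param quiet suppress per-epoch progress messages.
#' @return a trained `tagger_model` with a `history` data.frame
#'   (`epoch`, `mean_loss`, `dev_f1`).
#' @export
train_tagger <- function(train_docs, dev_docs = NULL, embeddings = NULL,
                         config = tagger_config(), quiet = TRUE) {
  if (!length(train_docs)) stop("empty training set")
  sents <- docs_to_sentences(train_docs)
  if (!length(sents)) stop("training documents contain no sentences")
  vocab_words <- sort(unique(tolower(unlist(
    lapply(sents, function(s) s$tokens$text)))), method = "radix")
  model <- new_tagger_model(vocab_words, config, embeddings)
  sent_ids <- lapply(sents, function(s) token_ids(model, s$tokens$text))
  # frequency-based word dropout: p(unk) = alpha / (alpha + count)
  wd_alpha <- if (is.null(config$word_dropout_alpha)) 0 else
    config$word_dropout_alpha
  counts <- tabulate(unlist(sent_ids), nbins = length(model$words))
  p_unk <- if (wd_alpha > 0) wd_alpha / (wd_alpha + pmax(counts, 1)) else
    rep(0, length(model$words))
  D <- config$word_dim
  lr <- config$learning_rate
  best_f1 <- -Inf
  best_params <- NULL
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_f1 <- numeric(0)
  with_seed(config$seed + 17L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(sents))
      tot_loss <- 0
      for (si in ord) {
        ids <- sent_ids[[si]]
        n <- length(ids)
        if (wd_alpha > 0) {
          drop_word <- stats::runif(n) < p_unk[ids]
          if (any(drop_word)) ids[drop_word] <- 1L   # <unk>
        }
        mask <- if (config$dropout > 0) {
          matrix(rbinom(n * D, 1, 1 - config$dropout) / (1 - config$dropout),
                 n, D)
        } else NULL
        res <- tagger_sentence_loss(model, ids, sents[[si]]$tags,
                                    drop_mask = mask)
        tot_loss <- tot_loss + res$loss
        nrm <- sqrt(.grad_sq_norm(res$grads))
        g <- res$grads
        if (is.finite(config$clip) && nrm > config$clip) {
          sc <- config$clip / nrm
          g$emb$rows <- g$emb$rows * sc
          g$fwd <- scale_params(g$fwd, sc); g$bwd <- scale_params(g$bwd, sc)
          g$W_e <- g$W_e * sc; g$b_e <- g$b_e * sc; g$A <- g$A * sc
        }
        model$params <- .apply_grads(model$params, g, lr)
      }
      dev_f1 <- NA_real_
      if (!is.null(dev_docs) && length(dev_docs)) {
        pred <- tag_corpus(model, dev_docs)
        dev_f1 <- evaluate_corpus(dev_docs, pred)$f1
        if (dev_f1 >= best_f1) {
          best_f1 <- dev_f1
          best_params <- model$params
        }
      }
      hist_epoch <- c(hist_epoch, ep)
      hist_loss <- c(hist_loss, tot_loss / length(sents))
      hist_f1 <- c(hist_f1, dev_f1)
      if (!quiet) {
        message(sprintf("epoch %d: mean loss %.4f%s", ep,
                        tot_loss / length(sents),
                        if (is.na(dev_f1)) "" else sprintf(", dev F1 %.4f", dev_f1)))
      }
    }
  })
  if (!is.null(best_params)) model$params <- best_params
  model$history <- data.frame(epoch = hist_epoch, mean_loss = hist_loss,
                              dev_f1 = hist_f1)
  model
}
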
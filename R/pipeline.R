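# End-to-end pipeline: (optional) embedding training/loading ->
# sequence tagger training -> decoding with optional abbreviation merge
# -> evaluation. Every stage is reachable independently through the
# exported module functions; this wiring adds config resolution,
# seeding and a structured run log.

#' Resolved pipeline configuration
#'
#' Merges defaults, an optional YAML config file and direct overrides
#' (later wins). The keys mirror the tuned tagger settings
#' (`word_dim = 200`, `hidden = 100`, bidirectional encoder, CRF layer,
#' input dropout, SGD) plus the ablation switches: `use_embeddings`
#' (pretrained vectors), `use_bilstm` (per-token affine classifier when
#' off), `use_crf` (per-token argmax + BIO repair when off) and
#' `use_abbrev` (abbreviation merge).
#'
#' @param file optional YAML file of settings (requires the `yaml`
#'   package).
#' @param ... overrides of individual keys.
#' @return named list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(
    word_dim = 200L, hidden = 100L,
    use_bilstm = TRUE, use_crf = TRUE,
    use_embeddings = TRUE, use_abbrev = TRUE,
    input_dropout = 0.5, optimizer = "sgd",
    learning_rate = 0.1, epochs = 10L,
    embed_window = 5L, embed_negatives = 5L, embed_epochs = 5L,
    constrain_bio = FALSE,
    seed = 1L
  )
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a config file requires the 'yaml' package")
    }
    fromfile <- yaml::read_yaml(file)
    cfg[names(fromfile)] <- fromfile
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!identical(cfg$optimizer, "sgd")) {
    stop("only the 'sgd' optimizer is implemented")
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  # small deterministic fingerprint (polynomial rolling hash, mod 2^31)
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full tagging pipeline
#'
#' Stages run in order: embedding training (or loading) when
#' `use_embeddings` is on, tagger training, decoding of the test
#' documents (with the abbreviation merge when `use_abbrev` is on), and
#' evaluation when the test documents carry gold mentions. Every
#' ablation is reachable through the config switches. Identical config
#' and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @param train_docs,dev_docs,test_docs lists of annotated documents
#'   (`dev_docs` may be NULL).
#' @param embedding_corpus optional token corpus for embedding
#'   pretraining; alternatively `word_vectors` gives pre-trained
#'   vectors.
#' @param word_vectors optional result of [read_word_vectors()] or an
#'   `embedding_model`.
#' @param evaluate compute an evaluation report against the gold
#'   mentions of `test_docs` (error if requested without gold).
#' @return list with `model`, `tagged` (documents with predicted
#'   mentions), `report` (or NULL), `config`, `config_hash` and `log`
#'   (per-stage timings and counts).
#' @export
run_pipeline <- function(config, train_docs, dev_docs = NULL,
                         test_docs = list(), embedding_corpus = NULL,
                         word_vectors = NULL, evaluate = TRUE) {
  if (!inherits(config, "run_config")) stop("config must be a run_config()")
  if (!length(train_docs)) stop("no training documents supplied")
  if (evaluate && length(test_docs) &&
        all(vapply(test_docs, function(d) nrow(d$mentions) == 0, logical(1)))) {
    stop("evaluation requested but test documents carry no gold mentions")
  }
  log <- list()
  stamp <- function(stage, t0, ...) {
    log[[stage]] <<- c(list(seconds = round(as.numeric(
      difftime(Sys.time(), t0, units = "secs")), 3)), list(...))
  }
  emb <- NULL
  if (config$use_embeddings) {
    t0 <- Sys.time()
    if (!is.null(word_vectors)) {
      emb <- word_vectors
      stamp("embeddings", t0, source = "precomputed")
    } else if (!is.null(embedding_corpus)) {
      emb <- train_skipgram(embedding_corpus,
                            dimension = config$word_dim,
                            window = config$embed_window,
                            k_negatives = config$embed_negatives,
                            epochs = config$embed_epochs,
                            seed = config$seed)
      stamp("embeddings", t0, source = "trained",
            vocab = length(emb$vocab$words))
    } else {
      stamp("embeddings", t0, source = "none-available")
    }
  }
  t0 <- Sys.time()
  tcfg <- tagger_config(word_dim = config$word_dim, hidden = config$hidden,
                        use_bilstm = config$use_bilstm,
                        use_crf = config$use_crf,
                        dropout = config$input_dropout,
                        learning_rate = config$learning_rate,
                        epochs = config$epochs,
                        constrain_bio = config$constrain_bio,
                        seed = config$seed)
  model <- train_tagger(train_docs, dev_docs, embeddings = emb,
                        config = tcfg)
  stamp("tagger", t0, sentences = length(docs_to_sentences(train_docs)),
        vocab = length(model$words))
  tagged <- list(); report <- NULL
  if (length(test_docs)) {
    t0 <- Sys.time()
    tagged <- tag_corpus(model, test_docs, use_abbrev = config$use_abbrev)
    stamp("decode", t0, documents = length(test_docs),
          mentions = sum(vapply(tagged, function(d) nrow(d$mentions), 1L)))
    if (evaluate) {
      t0 <- Sys.time()
      report <- evaluate_corpus(test_docs, tagged)
      stamp("evaluate", t0, f1 = report$f1)
    }
  }
  list(model = model, tagged = tagged, report = report, config = config,
       config_hash = config_hash(config), log = log)
}

#' Write an evaluation report as JSON
#'
#' Machine-readable twin of the printed report.
#'
#' @param report an `eval_report` or `bootstrap_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_eval_json <- function(report, path) {
  if (inherits(report, "bootstrap_report")) {
    obj <- list(matching = report$point$matching,
                tp = report$point$tp, fp = report$point$fp,
                fn = report$point$fn,
                precision = report$point$precision,
                recall = report$point$recall, f1 = report$point$f1,
                bootstrap = list(rounds = report$rounds,
                                 level = report$level,
                                 f1_low = report$f1_low,
                                 f1_high = report$f1_high))
  } else {
    obj <- list(matching = report$matching, tp = report$tp, fp = report$fp,
                fn = report$fn, precision = report$precision,
                recall = report$recall, f1 = report$f1)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
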
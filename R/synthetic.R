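# Deterministic synthetic corpora.
#
# The NER generator emulates the shape of an annotated abstract corpus:
# title plus abstract sentences of ~21 words, disease mentions drawn
# from a generated lexicon of single-word, hyphenated and multi-word
# Greco-Latin-style names (root + affix concatenation, e.g.
# "hemo-chromatosis", "chronic hepatic syndrome"), parenthesized
# abbreviation definitions "Long Form (SF)" whose short form is reused
# later in the document, and character-exact gold offsets. The
# embedding generator plants word clusters that share sentence contexts
# so that skip-gram training must separate them.

.fixture_roots <- c(
  "hemo", "neuro", "cardio", "hepato", "nephro", "osteo", "dermato",
  "gastro", "myelo", "arthro", "encephalo", "leuko", "angio", "fibro",
  "adeno", "broncho", "entero", "thrombo", "glyco", "chondro")

.fixture_suffixes <- c(
  "chromatosis", "pathy", "itis", "osis", "oma", "emia", "trophy",
  "plasia", "sclerosis", "megaly", "dynia", "genesis")

.fixture_modifiers <- c(
  "chronic", "recurrent", "familial", "juvenile", "acute", "hereditary",
  "congenital", "idiopathic", "X-linked", "early-onset", "late-onset",
  "severe")

.fixture_organs <- c(
  "liver", "kidney", "cardiac", "hepatic", "renal", "cerebral",
  "pulmonary", "ocular", "skeletal", "muscular")

.fixture_heads <- c(
  "syndrome", "disease", "deficiency", "carcinoma", "dystrophy",
  "anemia", "lymphoma", "disorder", "atrophy", "toxicosis")

.fixture_starters <- c("The", "We", "These", "Our", "This", "Several",
                       "Recent", "Previous")

# Non-disease long forms (procedures/techniques). Their short forms are
# initials and can collide with disease short forms (e.g. "CT" from
# both "computed tomography" and "cardiac toxicosis"), reproducing the
# abbreviation ambiguity that makes token identity alone insufficient.
.fixture_nd_first <- c("computed", "magnetic", "positron", "electron",
                       "quantitative", "functional", "digital", "optical",
                       "serial", "targeted", "automated", "longitudinal")

.fixture_nd_second <- c("tomography", "imaging", "resonance", "microscopy",
                        "sequencing", "analysis", "mapping", "screening",
                        "stimulation", "testing")

.fixture_fillers <- c(
  "patients", "analysis", "observed", "study", "gene", "mutation",
  "expression", "clinical", "treatment", "results", "in", "of", "the",
  "a", "with", "and", "were", "was", "for", "to", "showed", "that",
  "cohort", "samples", "control", "group", "levels", "protein",
  "associated", "identified", "reported", "cases", "data", "findings",
  "suggest", "evidence", "role", "novel", "variants", "screening",
  "diagnosis", "therapy", "response", "outcome", "risk", "factors",
  "among", "between", "during", "after", "before", "under", "several",
  "common", "rare", "specific", "related", "present", "absent",
  "measured", "compared", "detected", "examined", "evaluated",
  "confirmed", "assessed", "followed", "enrolled", "included",
  "individuals", "families", "children", "adults", "tissue", "cells",
  "sequence", "region", "locus", "allele", "frequency", "population")

#' Configuration for the synthetic NER corpus generator
#'
#' Defaults mirror the shape of a typical annotated abstract corpus:
#' 10 sentences per document averaging ~21 words.
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences per document (title counts as one).
#' @param words_per_sentence target mean sentence length in words.
#' @param disease_lexicon_size number of distinct disease names.
#' @param p_mention probability that a sentence carries a mention.
#' @param p_multiword probability that a lexicon entry is multi-word.
#' @param p_abbrev_definition probability that a document introduces one
#'   mention as `"Long Form (SF)"` and reuses the SF later.
#' @param p_nondisease_definition probability that a document also
#'   defines a non-disease abbreviation (a procedure/technique long
#'   form) whose short form may collide with disease short forms;
#'   reproduces the ambiguity that motivates definition-based
#'   abbreviation resolution.
#' @param seed integer seed; the same seed gives byte-identical output.
#' @return validated configuration list of class `fixture_config`.
#' @export
fixture_config <- function(n_docs = 80L, sentences_per_doc = 10L,
                           words_per_sentence = 21L,
                           disease_lexicon_size = 150L,
                           p_mention = 0.7, p_multiword = 0.5,
                           p_abbrev_definition = 0.2,
                           p_nondisease_definition = 0.3, seed = 1L) {
  cfg <- list(n_docs = as.integer(n_docs),
              sentences_per_doc = as.integer(sentences_per_doc),
              words_per_sentence = as.integer(words_per_sentence),
              disease_lexicon_size = as.integer(disease_lexicon_size),
              p_mention = p_mention, p_multiword = p_multiword,
              p_abbrev_definition = p_abbrev_definition,
              p_nondisease_definition = p_nondisease_definition,
              seed = as.integer(seed))
  probs <- c(cfg$p_mention, cfg$p_multiword, cfg$p_abbrev_definition,
             cfg$p_nondisease_definition)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$n_docs < 0 || cfg$sentences_per_doc < 1 ||
        cfg$words_per_sentence < 8 || cfg$disease_lexicon_size < 1) {
    stop("invalid fixture configuration sizes")
  }
  structure(cfg, class = "fixture_config")
}

#' Generate a disease-name lexicon
#'
#' Entries are built by Greco-Latin-style affix concatenation: fused or
#' hyphenated root+suffix single words ("hemochromatosis",
#' "hemo-chromatosis") and 2-4-word forms with descriptive modifiers
#' ("chronic hepatic syndrome"). Entries are unique; each entry is a
#' character vector of its words.
#'
#' @param size number of entries.
#' @param p_multiword probability of a multi-word entry.
#' @param seed integer seed.
#' @return list of character vectors.
#' @export
generate_disease_lexicon <- function(size, p_multiword = 0.5, seed = 1L) {
  with_seed(seed, {
    seen <- character(0)
    out <- list()
    guard <- 0L
    while (length(out) < size && guard < size * 100L) {
      guard <- guard + 1L
      if (stats::runif(1) < p_multiword) {
        n_pre <- sample(1:3, 1)
        pre <- sample(c(.fixture_modifiers, .fixture_organs), n_pre)
        entry <- c(pre, sample(.fixture_heads, 1))
      } else {
        root <- sample(.fixture_roots, 1)
        suf <- sample(.fixture_suffixes, 1)
        entry <- if (stats::runif(1) < 0.3) {
          paste0(root, "-", suf)
        } else {
          paste0(root, suf)
        }
      }
      key <- paste(entry, collapse = " ")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- entry
    }
    out
  })
}

# Build one sentence. `inserts` is a list of insertions, each a list
# with `words` (character vector), `gold` (does the span become a gold
# mention?) and optional `sf` (a parenthesized short form appended
# after the words; gold iff the insertion is gold). Returns the
# sentence text (trailing period included) plus gold mention offsets
# relative to the sentence start.
.build_sentence <- function(n_words, inserts) {
  n_ins_words <- sum(vapply(inserts, function(x) length(x$words), 1L))
  n_fill <- max(3L, n_words - n_ins_words)
  words <- c(sample(.fixture_starters, 1),
             sample(.fixture_fillers, n_fill - 1L, replace = TRUE))
  # gap g means "insert before filler position g"; keep off the start
  gaps <- sort(sample(2:(length(words) + 1L),
                      min(length(inserts), length(words) - 1L)))
  tokens <- character(0)
  men_s <- integer(0); men_e <- integer(0)    # gold token index ranges
  sf_tok <- integer(0); sf_len <- integer(0)  # gold SF tokens
  gi <- 1L
  for (pos in seq_len(length(words) + 1L)) {
    while (gi <= length(gaps) && gaps[gi] == pos) {
      ins <- inserts[[gi]]
      first <- length(tokens) + 1L
      tokens <- c(tokens, ins$words)
      if (isTRUE(ins$gold)) {
        men_s <- c(men_s, first)
        men_e <- c(men_e, length(tokens))
      }
      if (!is.null(ins$sf)) {
        tokens <- c(tokens, paste0("(", ins$sf, ")"))
        if (isTRUE(ins$gold)) {
          sf_tok <- c(sf_tok, length(tokens))
          sf_len <- c(sf_len, nchar(ins$sf))
        }
      }
      gi <- gi + 1L
    }
    if (pos <= length(words)) tokens <- c(tokens, words[pos])
  }
  # character offsets: tokens joined by single spaces, "." appended
  starts <- cumsum(c(0L, nchar(tokens) + 1L))[seq_along(tokens)]
  ends <- starts + nchar(tokens)
  text <- paste0(paste(tokens, collapse = " "), ".")
  m_start <- starts[men_s]
  m_end <- ends[men_e]
  if (length(sf_tok)) {
    m_start <- c(m_start, starts[sf_tok] + 1L)
    m_end <- c(m_end, starts[sf_tok] + 1L + sf_len)
  }
  list(text = text, mention_start = m_start, mention_end = m_end)
}

#' Generate a synthetic annotated NER corpus
#'
#' Documents have a one-sentence title and an abstract; disease mentions
#' are drawn from a generated lexicon; with probability
#' `p_abbrev_definition` a document introduces a multi-word mention as
#' `"Long Form (SF)"` (SF = initial letters) and reuses the SF later as
#' a standalone gold mention. All gold offsets are character-exact and
#' round-trip through the PubTator writer/reader.
#'
#' @param config a [fixture_config()].
#' @return list of [annotated_document()] objects.
#' @export
generate_ner_corpus <- function(config = fixture_config()) {
  lexicon <- generate_disease_lexicon(config$disease_lexicon_size,
                                      config$p_multiword, config$seed)
  multi_idx <- which(lengths(lexicon) >= 2)
  with_seed(config$seed + 1L, {
    docs <- vector("list", config$n_docs)
    for (di in seq_len(config$n_docs)) {
      n_sent <- config$sentences_per_doc
      # plan: which sentences carry mentions, where definitions go
      has_mention <- stats::runif(n_sent) < config$p_mention
      def_sent <- 0L; use_sents <- integer(0)
      sf <- NULL; def_entry <- NULL
      if (length(multi_idx) && n_sent >= 2 &&
            stats::runif(1) < config$p_abbrev_definition) {
        def_sent <- sample.int(max(1L, n_sent - 1L), 1)
        def_entry <- lexicon[[multi_idx[sample.int(length(multi_idx), 1)]]]
        sf <- paste(toupper(substr(def_entry, 1, 1)), collapse = "")
        later <- (def_sent + 1L):n_sent
        use_sents <- later[sample.int(length(later),
                                      min(2L, length(later)))]
      }
      # non-disease definition (procedure/technique); its SF may
      # coincide with a disease SF elsewhere in the corpus
      nd_sent <- 0L; nd_use <- integer(0); nd_sf <- NULL; nd_entry <- NULL
      if (n_sent >= 2 && stats::runif(1) < config$p_nondisease_definition) {
        nd_sent <- sample.int(max(1L, n_sent - 1L), 1)
        if (nd_sent == def_sent) nd_sent <- nd_sent %% n_sent + 1L
        nd_entry <- c(sample(.fixture_nd_first, 1),
                      sample(.fixture_nd_second, 1))
        nd_sf <- paste(toupper(substr(nd_entry, 1, 1)), collapse = "")
        # same-document SF collision would make the gold labels
        # inconsistent with document-wide propagation; skip those
        if (!is.null(sf) && identical(nd_sf, sf)) {
          nd_sent <- 0L; nd_entry <- NULL; nd_sf <- NULL
        }
        if (nd_sent > 0L && nd_sent < n_sent) {
          later <- (nd_sent + 1L):n_sent
          nd_use <- later[sample.int(length(later),
                                     min(2L, length(later)))]
        }
      }
      sent_texts <- character(n_sent)
      men_s <- integer(0); men_e <- integer(0)
      offset <- 0L
      for (si in seq_len(n_sent)) {
        inserts <- list()
        if (si == def_sent) {
          inserts <- c(inserts, list(list(words = def_entry, gold = TRUE,
                                          sf = sf)))
        } else if (si %in% use_sents) {
          inserts <- c(inserts, list(list(words = sf, gold = TRUE)))
        } else if (has_mention[si]) {
          n_m <- if (stats::runif(1) < 0.25) 2L else 1L
          picked <- lexicon[sample.int(length(lexicon), n_m)]
          inserts <- c(inserts, lapply(picked, function(w) {
            list(words = w, gold = TRUE)
          }))
        }
        if (si == nd_sent) {
          inserts <- c(inserts, list(list(words = nd_entry, gold = FALSE,
                                          sf = nd_sf)))
        } else if (si %in% nd_use) {
          inserts <- c(inserts, list(list(words = nd_sf, gold = FALSE)))
        }
        n_words <- sample(seq(config$words_per_sentence - 6L,
                              config$words_per_sentence + 6L), 1)
        sb <- .build_sentence(n_words, inserts)
        sent_texts[si] <- sb$text
        if (length(sb$mention_start)) {
          men_s <- c(men_s, offset + sb$mention_start)
          men_e <- c(men_e, offset + sb$mention_end)
        }
        offset <- offset + nchar(sb$text) + 1L   # single-space joins
      }
      title <- sent_texts[1]
      abstract <- if (n_sent > 1) {
        paste(sent_texts[-1], collapse = " ")
      } else ""
      text <- paste(title, abstract)
      mm <- mention_frame(men_s, men_e,
                          substring(text, men_s + 1L, men_e),
                          rep("Disease", length(men_s)))
      docs[[di]] <- annotated_document(sprintf("%d", 100000L + di),
                                       title, abstract, mm)
    }
    docs
  })
}

#' Generate a token corpus with planted word clusters
#'
#' Words are split into `cluster_count` groups; every sentence draws all
#' its tokens from a single group, so words within a group share
#' contexts and words across groups never co-occur. Skip-gram training
#' on this corpus must place intra-cluster pairs closer (higher cosine)
#' than inter-cluster pairs.
#'
#' @param vocab_size number of distinct words.
#' @param cluster_count number of planted clusters (must be <=
#'   `vocab_size`).
#' @param n_tokens total number of tokens emitted (exact).
#' @param sentence_length tokens per sentence.
#' @param seed integer seed.
#' @return list of character-vector sentences; the planted assignment is
#'   attached as `attr(, "clusters")`.
#' @export
generate_embedding_corpus <- function(vocab_size = 40L, cluster_count = 2L,
                                      n_tokens = 20000L,
                                      sentence_length = 10L, seed = 1L) {
  if (cluster_count > vocab_size) stop("cluster_count > vocab_size")
  words <- sprintf("w%03d", seq_len(vocab_size))
  assign <- rep(seq_len(cluster_count), length.out = vocab_size)
  clusters <- split(words, assign)
  with_seed(seed, {
    sents <- list()
    emitted <- 0L
    while (emitted < n_tokens) {
      cl <- clusters[[sample.int(cluster_count, 1)]]
      len <- min(sentence_length, n_tokens - emitted)
      sents[[length(sents) + 1L]] <- sample(cl, len, replace = TRUE)
      emitted <- emitted + len
    }
    attr(sents, "clusters") <- clusters
    sents
  })
}
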
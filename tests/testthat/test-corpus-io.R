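test_that("tokenizer splits on whitespace, detaches punctuation, keeps hyphens", {
  expect_equal(nrow(tokenize("")), 0L)
  tk <- tokenize("recurrent cat-eye syndrome")
  expect_equal(tk$text, c("recurrent", "cat-eye", "syndrome"))
  expect_equal(tk$start, c(0L, 10L, 18L))
  expect_equal(tk$end, c(9L, 17L, 26L))
  expect_equal(tokenize("CT).")$text, c("CT", ")", "."))
  expect_equal(tokenize("(CT).")$text, c("(", "CT", ")", "."))
  expect_equal(tokenize("it's fine")$text, c("it's", "fine"))
})

test_that("token offsets partition the non-whitespace characters", {
  docs <- tiny_docs(3)
  for (d in docs) {
    toks <- tokenize(d$text)
    cover <- integer(nchar(d$text))
    for (i in seq_len(nrow(toks))) {
      idx <- (toks$start[i] + 1L):toks$end[i]
      cover[idx] <- cover[idx] + 1L
    }
    chars <- strsplit(d$text, "", fixed = TRUE)[[1]]
    expect_true(all(cover[!grepl("\\s", chars)] == 1L))
    expect_true(all(cover[grepl("\\s", chars)] == 0L))
    # concatenating token texts recovers all non-space characters in order
    expect_equal(paste(toks$text, collapse = ""),
                 gsub("\\s+", "", d$text))
  }
})

test_that("PubTator reader handles documents with and without annotations", {
  docs <- read_pubtator(c("1|t|A.", "1|a|B.", ""))
  expect_length(docs, 1)
  expect_equal(docs[[1]]$doc_id, "1")
  expect_equal(nrow(docs[[1]]$mentions), 0L)

  lines <- c("9|t|liver cancer is a disease.",
             "9|a|More text follows here.",
             "9\t0\t12\tliver cancer\tDisease\tD008113",
             "")
  docs <- read_pubtator(lines)
  m <- docs[[1]]$mentions
  expect_equal(m$text, "liver cancer")
  expect_equal(c(m$start, m$end), c(0L, 12L))
  expect_equal(m$concept_id, "D008113")
})

test_that("PubTator reader flags bad annotations and malformed blocks", {
  bad <- c("9|t|liver cancer is a disease.",
           "9|a|More text.",
           "9\t0\t12\tkidney cancer\tDisease",
           "")
  expect_warning(docs <- read_pubtator(bad), "9.*kidney cancer")
  expect_equal(nrow(docs[[1]]$mentions), 0L)
  expect_error(read_pubtator(c("9|t|Only a title.", "")), "title and one abstract")
})

test_that("PubTator writer round-trips generated corpora byte-identically", {
  docs <- generate_ner_corpus(fixture_config(n_docs = 50, seed = 11))
  lines <- write_pubtator(docs)
  docs2 <- read_pubtator(lines)
  expect_identical(write_pubtator(docs2), lines)
  expect_equal(length(docs2), 50)
  # empty corpus and single-mention shape
  expect_identical(write_pubtator(list()), character(0))
  d <- annotated_document("5", "A bad disease here.", "No more.",
                          mention_frame(6, 13, "disease", "Disease"))
  expect_length(write_pubtator(list(d)), 4)  # t, a, 1 annotation, blank
})

test_that("mentions_to_bio follows the B/I/O rules", {
  toks <- tokenize("liver cancer is")
  tags <- mentions_to_bio(toks, mention_frame(0, 12, "liver cancer", "Disease"))
  expect_equal(tags, c("B", "I", "O"))
  expect_equal(mentions_to_bio(toks, empty_mentions()), c("O", "O", "O"))
  # two adjacent single-token mentions restart with B
  toks2 <- tokenize("anemia lymphoma")
  m2 <- mention_frame(c(0, 7), c(6, 15), c("anemia", "lymphoma"), "Disease")
  expect_equal(mentions_to_bio(toks2, m2), c("B", "B"))
  # partial overlap snaps outward to the token
  m3 <- mention_frame(2, 8, "ver ca", "Disease")
  expect_equal(mentions_to_bio(toks, m3), c("B", "I", "O"))
  # overlapping mentions are rejected
  bad <- mention_frame(c(0, 6), c(12, 15), c("liver cancer", "cancer is"),
                       "Disease")
  expect_error(mentions_to_bio(toks, bad), "overlapping")
})

test_that("bio_to_mentions decodes runs and repairs illegal I prefixes", {
  txt <- "liver cancer is"
  toks <- tokenize(txt)
  m <- bio_to_mentions(toks, c("B", "I", "O"), text = txt)
  expect_equal(m$text, "liver cancer")
  expect_equal(nrow(bio_to_mentions(toks, c("O", "O", "O"))), 0L)
  r <- bio_to_mentions(toks, c("O", "I", "I"), text = txt)
  expect_equal(r$text, "cancer is")
  expect_error(bio_to_mentions(toks, c("B", "I")), "length mismatch")
  expect_error(bio_to_mentions(toks, c("B", "X", "O")), "B, I, O")
})

test_that("BIO codec round-trips on generated documents", {
  docs <- tiny_docs(4, seed = 9)
  for (d in docs) {
    sents <- split_sentences(d$text)
    for (si in seq_len(nrow(sents))) {
      stext <- substr(d$text, sents$start[si] + 1, sents$end[si])
      toks <- tokenize(stext)
      toks$start <- toks$start + sents$start[si]
      toks$end <- toks$end + sents$start[si]
      tags <- mentions_to_bio(toks, d$mentions)
      back <- bio_to_mentions(toks, tags, text = d$text)
      gold <- d$mentions[d$mentions$start >= sents$start[si] &
                           d$mentions$end <= sents$end[si], ]
      expect_equal(back$start, gold$start)
      expect_equal(back$end, gold$end)
    }
  }
})

test_that("sentence splitting uses the punctuation-then-uppercase rule", {
  s <- split_sentences("First one. Second here. no split here. Third.")
  expect_equal(nrow(s), 3)
  expect_equal(s$start[1], 0L)
  # "no" is lowercase, so "Second here. no split here." is one sentence
  txt <- "First one. Second here. no split here. Third."
  expect_equal(substr(txt, s$start[2] + 1, s$end[2]),
               "Second here. no split here.")
})

test_that("word vector files round-trip within 1e-6 and reject bad input", {
  parsed <- read_word_vectors(c("2 3", "alpha 1 2 3", "beta 0.5 -1 2e-3"))
  expect_equal(parsed$dimension, 3)
  expect_equal(parsed$vectors["beta", ], c(0.5, -1, 0.002))
  expect_error(read_word_vectors(c("2 3", "a 1 2 3", "b 1 2")), "line 3")
  expect_error(read_word_vectors(c("2 2", "a 1 2", "a 3 4")), "duplicate")

  set.seed(4)
  tbl <- list(words = sprintf("w%03d", 1:100),
              vectors = matrix(stats::rnorm(100 * 200), 100, 200))
  back <- read_word_vectors(write_word_vectors(tbl))
  expect_lt(max(abs(back$vectors - tbl$vectors)), 1e-6)
  expect_identical(back$words, tbl$words)
})

test_that("CoNLL serialization round-trips token/tag content", {
  docs <- tiny_docs(2, seed = 13)
  lines <- write_conll(docs)
  sents <- read_conll(lines)
  relines <- unlist(lapply(sents, function(s) {
    c(paste(s$text, s$tag, sep = "\t"), "")
  }))
  expect_identical(relines, lines)
  expect_true(all(unlist(lapply(sents, function(s) s$tag)) %in%
                    c("B", "I", "O")))
})
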
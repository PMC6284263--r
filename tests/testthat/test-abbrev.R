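test_that("candidate extraction finds parenthesized short forms", {
  cands <- find_candidates("Copper Toxicosis (CT) was studied.")
  expect_length(cands, 1)
  expect_equal(cands[[1]]$sf, "CT")
  w <- cands[[1]]$window
  expect_equal(w$text[nrow(w)], "Toxicosis")
  expect_length(find_candidates("No parentheses here."), 0)
  expect_length(find_candidates("A number (12) only."), 0)
  # SF longer than 10 characters is rejected
  expect_length(find_candidates("Thing (abcdefghijkl) here."), 0)
})

test_that("strategy FC matches first characters of consecutive words", {
  win <- tokenize("Copper Toxicosis")
  hit <- match_strategy_fc("CT", win)
  expect_equal(c(hit$start, hit$end), c(0, 16))
  expect_null(match_strategy_fc("CT", tokenize("liver disease")))
  # minimal suffix: extra leading words are not part of the span
  win2 <- tokenize("studied the Copper Toxicosis")
  hit2 <- match_strategy_fc("CT", win2)
  expect_equal(substr("studied the Copper Toxicosis", hit2$start + 1, hit2$end),
               "Copper Toxicosis")
})

test_that("strategy FCG matches characters after non-alphanumerics", {
  win <- tokenize("insulin-dependent diabetes mellitus")
  hit <- match_strategy_fcg("IDDM", win)
  expect_equal(c(hit$start, hit$end), c(0, 35))
  # FCG generalizes FC
  hit2 <- match_strategy_fcg("CT", tokenize("Copper Toxicosis"))
  expect_equal(c(hit2$start, hit2$end), c(0, 16))
  expect_null(match_strategy_fcg("XY", tokenize("alpha beta")))
})

test_that("pair resolution tries FC, then FCG, then the one-skip fallback", {
  p <- resolve_pairs("Copper Toxicosis (CT) was found.")
  expect_equal(nrow(p), 1)
  expect_equal(p$strategy, "FC")
  expect_equal(p$lf, "Copper Toxicosis")
  expect_equal(p$sf, "CT")
  # two sites resolve in document order
  txt <- paste("Copper Toxicosis (CT) was seen. Patients with",
               "insulin-dependent diabetes mellitus (IDDM) were enrolled.")
  p2 <- resolve_pairs(txt)
  expect_equal(p2$strategy, c("FC", "FCG"))
  expect_equal(p2$sf, c("CT", "IDDM"))
  expect_true(all(p2$sf_start < p2$sf_end))
  # trailing whitespace does not change the result
  p3 <- resolve_pairs(paste0(txt, "   "))
  expect_equal(p3[, c("sf", "lf", "strategy")], p2[, c("sf", "lf", "strategy")])
  # fallback: one interior word skipped
  p4 <- resolve_pairs("Crohn related disease (CD) was found.")
  expect_equal(p4$strategy, "FCS")
  expect_equal(p4$lf, "Crohn related disease")
})

test_that("resolved pairs re-validate under their reported strategy", {
  docs <- generate_ner_corpus(fixture_config(n_docs = 15,
                                             p_abbrev_definition = 1,
                                             seed = 33))
  for (d in docs) {
    pairs <- resolve_pairs(d$text)
    for (i in seq_len(nrow(pairs))) {
      win <- tokenize(pairs$lf[i])
      hit <- switch(pairs$strategy[i],
                    FC = match_strategy_fc(pairs$sf[i], win),
                    FCG = match_strategy_fcg(pairs$sf[i], win),
                    FCS = match_strategy_fcs(pairs$sf[i], win))
      expect_false(is.null(hit))
      expect_lt(nchar(pairs$sf[i]), nchar(pairs$lf[i]))
    }
  }
})

test_that("short forms propagate only from disease-tagged long forms", {
  doc <- annotated_document("d", "Copper Toxicosis (CT) was studied.",
                            "The CT group and the SCT cohort had CT signs.")
  pairs <- resolve_pairs(doc$text)
  tagged <- mention_frame(0, 16, "Copper Toxicosis", "Disease")
  ab <- abbreviation_labels(doc, tagged, pairs)
  expect_equal(nrow(ab), 3)  # defining occurrence + 2 standalone uses
  expect_true(all(ab$text == "CT"))
  # "SCT" contains CT but is not a token-boundary match
  expect_false(any(ab$start == regexpr("SCT", doc$text) - 1 + 1))
  # long form not tagged as disease -> nothing propagates
  expect_equal(nrow(abbreviation_labels(doc, empty_mentions(), pairs)), 0)
})

test_that("merge applies abbreviation precedence and is idempotent", {
  ab <- mention_frame(c(10, 30), c(12, 32), c("CT", "CT"), "Disease")
  # empty sequence-model set: output is the abbreviation set
  expect_equal(merge_labels(empty_mentions(), ab)[, c("start", "end")],
               ab[, c("start", "end")])
  # identical sets: unchanged
  expect_equal(nrow(merge_labels(ab, ab)), 2)
  # conflict: overlapping sequence-model span is replaced
  model_set <- mention_frame(c(8, 50), c(13, 55), c("a CT", "other"), "Disease")
  merged <- merge_labels(model_set, ab)
  expect_true(all(c(10, 30) %in% merged$start))
  expect_false(8 %in% merged$start)     # overlapped model span dropped
  expect_true(50 %in% merged$start)     # non-conflicting model span kept
  # idempotent
  expect_equal(merge_labels(merged, ab), merged)
  # output is non-overlapping
  if (nrow(merged) > 1) {
    expect_true(all(merged$start[-1] >= merged$end[-nrow(merged)]))
  }
})
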
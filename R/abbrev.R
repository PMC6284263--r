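# Short-form / long-form abbreviation definition detection.
#
# A definition site is a parenthesized short form (SF) following its
# spelled-out long form (LF), as in "Copper Toxicosis (CT)". Candidate
# LF windows use the relaxed length restriction of
# min(2*|SF| + 2, |SF| + 5) words, with |SF| the number of alphanumeric
# SF characters. Matching strategies are tried in reliability order:
#
#   FC  - each SF character matches the first character of consecutive
#         words of the LF, ending at the word before the parenthesis;
#   FCG - like FC, but an SF character may also match the character
#         following a non-alphanumeric, non-space character inside a
#         word (so "IDDM" matches "insulin-dependent diabetes
#         mellitus": I, D after "-", D, M);
#   FCS - FC allowing exactly one skipped interior word.
#
# The first strategy that validates a site wins; at most one pair per
# parenthesis site. Strategy matching is case-insensitive; short-form
# propagation through a document is case-sensitive.

sf_chars <- function(sf) {
  ch <- strsplit(sf, "", fixed = TRUE)[[1]]
  tolower(ch[grepl("[[:alnum:]]", ch)])
}

word_anchors <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  idx <- 1L
  if (length(ch) > 1) {
    inner <- which(!grepl("[[:alnum:]]", ch[-length(ch)])) + 1L
    idx <- c(idx, inner)
  }
  idx <- idx[grepl("[[:alnum:]]", ch[idx])]
  tolower(ch[idx])
}

#' Find abbreviation definition candidates
#'
#' For every parenthesized group `"( SF )"` whose content is 1-10
#' characters and contains at least one letter, returns the SF span plus
#' the candidate LF window: the words preceding the open parenthesis in
#' the same sentence, up to `min(2|SF| + 2, |SF| + 5)` words.
#'
#' @param text document text.
#' @return list of candidates, each a list with `sf`, `sf_start`,
#'   `sf_end` (0-based half-open offsets of the SF content) and `window`
#'   (a token table of the preceding words).
#' @export
find_candidates <- function(text) {
  out <- list()
  sents <- split_sentences(text)
  for (si in seq_len(nrow(sents))) {
    stext <- substr(text, sents$start[si] + 1L, sents$end[si])
    m <- gregexpr("\\(([^()]*)\\)", stext)[[1]]
    if (m[1] == -1) next
    toks <- tokenize(stext)
    words <- toks[grepl("[[:alnum:]]", toks$text), , drop = FALSE]
    for (k in seq_along(m)) {
      open_pos <- as.integer(m[k]) - 1L               # 0-based "(" offset
      len <- attr(m, "match.length")[k]
      inner <- substr(stext, open_pos + 2L, open_pos + len - 1L)
      sf <- trimws(inner)
      if (!nchar(sf) || nchar(sf) > 10 || !grepl("[[:alpha:]]", sf)) next
      pad <- regexpr(sf, inner, fixed = TRUE) - 1L
      sf_start <- open_pos + 1L + pad
      sf_end <- sf_start + nchar(sf)
      n_sf <- length(sf_chars(sf))
      if (n_sf == 0) next
      max_words <- min(2L * n_sf + 2L, n_sf + 5L)
      win <- words[words$end <= open_pos, , drop = FALSE]
      if (nrow(win) > max_words) {
        win <- win[(nrow(win) - max_words + 1L):nrow(win), , drop = FALSE]
      }
      if (!nrow(win)) next
      out[[length(out) + 1L]] <- list(
        sf = sf,
        sf_start = sents$start[si] + sf_start,
        sf_end = sents$start[si] + sf_end,
        window = data.frame(
          text = win$text,
          start = win$start + sents$start[si],
          end = win$end + sents$start[si],
          stringsAsFactors = FALSE
        )
      )
    }
  }
  out
}

#' First-character matching strategy (FC)
#'
#' Succeeds iff the SF's alphanumeric characters, in order, match the
#' first characters (case-insensitively) of consecutive words of the LF
#' window, ending at the window's last word. Returns the minimal
#' matching suffix of the window.
#'
#' @param sf short-form string.
#' @param lf_window token table of candidate long-form words.
#' @return list with `start`, `end` (0-based half-open span of the
#'   matched LF) or `NULL` when no match.
#' @export
match_strategy_fc <- function(sf, lf_window) {
  chars <- sf_chars(sf)
  m <- length(chars)
  nw <- nrow(lf_window)
  if (m == 0 || nw < m) return(NULL)
  span <- lf_window[(nw - m + 1L):nw, , drop = FALSE]
  firsts <- tolower(substr(span$text, 1, 1))
  if (all(firsts == chars)) {
    list(start = span$start[1], end = span$end[m])
  } else {
    NULL
  }
}

# Can the SF characters be matched to anchors of words p..nw such that
# the first anchor of word p matches SF char 1 and every word
# contributes at least one matched character? Backtracking over
# (sf position, word, anchor position within word).
.fcg_span_ok <- function(chars, anchor_list) {
  nw <- length(anchor_list)
  hits <- logical(nw)
  # backtracking over (sf position, word, anchor position within word);
  # the very first anchor of the span (first character) must be matched
  bt <- function(si, wi, ai) {
    if (si > length(chars)) return(all(hits))
    if (wi > nw) return(FALSE)
    anchors <- anchor_list[[wi]]
    if (ai <= length(anchors)) {
      if (anchors[ai] == chars[si]) {
        old <- hits[wi]; hits[wi] <<- TRUE
        if (bt(si + 1L, wi, ai + 1L)) return(TRUE)
        hits[wi] <<- old
      }
      if (!(wi == 1L && ai == 1L) && bt(si, wi, ai + 1L)) return(TRUE)
      FALSE
    } else {
      bt(si, wi + 1L, 1L)
    }
  }
  bt(1L, 1L, 1L)
}

#' First-character-generalized matching strategy (FCG)
#'
#' Like [match_strategy_fc()], but an SF character may also match the
#' character immediately following a non-alphanumeric, non-space
#' character inside a word (hyphen, slash, ...). Every word of the
#' matched span must supply at least one SF character, and the match
#' must start at the first character of the span.
#'
#' @inheritParams match_strategy_fc
#' @return list with `start`, `end`, or `NULL`.
#' @export
match_strategy_fcg <- function(sf, lf_window) {
  chars <- sf_chars(sf)
  m <- length(chars)
  nw <- nrow(lf_window)
  if (m == 0 || nw == 0) return(NULL)
  anchor_list <- lapply(lf_window$text, word_anchors)
  # minimal suffix: try the shortest suffix first
  for (p in seq(nw, 1L)) {
    span_anchors <- anchor_list[p:nw]
    if (sum(lengths(span_anchors)) < m) next
    if (length(span_anchors) > m) break  # every word needs >= 1 char
    if (.fcg_span_ok(chars, span_anchors)) {
      return(list(start = lf_window$start[p], end = lf_window$end[nw]))
    }
  }
  NULL
}

#' Fallback strategy: first-character match with one skipped word (FCS)
#'
#' Like FC over a suffix of `|SF| + 1` words where exactly one interior
#' word (never the first of the span) carries no SF character.
#'
#' @inheritParams match_strategy_fc
#' @return list with `start`, `end`, or `NULL`.
#' @export
match_strategy_fcs <- function(sf, lf_window) {
  chars <- sf_chars(sf)
  m <- length(chars)
  nw <- nrow(lf_window)
  if (m == 0 || nw < m + 1L) return(NULL)
  span <- lf_window[(nw - m):nw, , drop = FALSE]   # m + 1 words
  firsts <- tolower(substr(span$text, 1, 1))
  for (skip in 2:(m + 1L)) {
    kept <- firsts[-skip]
    if (all(kept == chars)) {
      return(list(start = span$start[1], end = span$end[m + 1L]))
    }
  }
  NULL
}

#' Resolve abbreviation definition pairs in a document
#'
#' Tries the strategies in fixed reliability order (FC, then FCG, then
#' the one-skip fallback FCS) on every candidate site; the first success
#' wins and yields at most one pair per parenthesis site. Deterministic
#' and insensitive to trailing whitespace.
#'
#' @param text document text.
#' @return data.frame with one row per pair: `sf_start`, `sf_end`, `sf`,
#'   `lf_start`, `lf_end`, `lf`, `strategy` (offsets 0-based half-open).
#' @export
resolve_pairs <- function(text) {
  cands <- find_candidates(text)
  rows <- list()
  for (cd in cands) {
    hit <- NULL; strat <- NULL
    for (s in c("FC", "FCG", "FCS")) {
      hit <- switch(s,
                    FC = match_strategy_fc(cd$sf, cd$window),
                    FCG = match_strategy_fcg(cd$sf, cd$window),
                    FCS = match_strategy_fcs(cd$sf, cd$window))
      if (!is.null(hit)) { strat <- s; break }
    }
    if (is.null(hit)) next
    lf_text <- substr(text, hit$start + 1L, hit$end)
    if (nchar(cd$sf) >= nchar(lf_text)) next   # SF must be shorter than LF
    rows[[length(rows) + 1L]] <- data.frame(
      sf_start = cd$sf_start, sf_end = cd$sf_end, sf = cd$sf,
      lf_start = hit$start, lf_end = hit$end, lf = lf_text,
      strategy = strat, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(sf_start = integer(0), sf_end = integer(0),
                      sf = character(0), lf_start = integer(0),
                      lf_end = integer(0), lf = character(0),
                      strategy = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# All token-boundary, case-sensitive occurrences of a string.
.find_occurrences <- function(text, needle) {
  m <- gregexpr(needle, text, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  starts <- as.integer(m) - 1L
  len <- nchar(needle)
  ok <- vapply(starts, function(s) {
    before <- if (s == 0) "" else substr(text, s, s)
    after <- substr(text, s + len + 1L, s + len + 1L)
    !grepl("[[:alnum:]]", before) && !grepl("[[:alnum:]]", after)
  }, logical(1))
  starts[ok]
}

#' Derive abbreviation-based disease mentions
#'
#' For every resolved pair whose long form overlaps a tagger-predicted
#' disease mention, every token-boundary, case-sensitive occurrence of
#' the short-form string in the document (including the defining one)
#' becomes a disease mention.
#'
#' @param doc an [annotated_document()].
#' @param tagger_mentions mention table predicted by the sequence model.
#' @param pairs pair table from [resolve_pairs()].
#' @return a mention table of abbreviation-derived mentions.
#' @export
abbreviation_labels <- function(doc, tagger_mentions, pairs) {
  starts <- integer(0); ends <- integer(0); txts <- character(0)
  for (i in seq_len(nrow(pairs))) {
    lf_s <- pairs$lf_start[i]; lf_e <- pairs$lf_end[i]
    overlaps <- nrow(tagger_mentions) > 0 &&
      any(tagger_mentions$start < lf_e & tagger_mentions$end > lf_s)
    if (!overlaps) next
    occ <- .find_occurrences(doc$text, pairs$sf[i])
    for (s in occ) {
      starts <- c(starts, s)
      ends <- c(ends, s + nchar(pairs$sf[i]))
      txts <- c(txts, pairs$sf[i])
    }
  }
  if (!length(starts)) return(empty_mentions())
  df <- mention_frame(starts, ends, txts, rep("Disease", length(starts)))
  df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
}

#' Merge sequence-model and abbreviation mention sets
#'
#' The union of the two span sets under abbreviation precedence: where
#' spans overlap with differing extents, the abbreviation mention
#' replaces the overlapping sequence-model mention(s). Idempotent; the
#' output is non-overlapping and always contains every abbreviation
#' mention.
#'
#' @param set_model mention table from the sequence model.
#' @param set_abbrev mention table from [abbreviation_labels()].
#' @return merged mention table.
#' @export
merge_labels <- function(set_model, set_abbrev) {
  if (!nrow(set_abbrev)) return(mention_frame(set_model$start, set_model$end,
                                            set_model$text, set_model$label))
  keep <- rep(TRUE, nrow(set_model))
  for (i in seq_len(nrow(set_model))) {
    if (any(set_model$start[i] < set_abbrev$end &
              set_model$end[i] > set_abbrev$start)) {
      keep[i] <- FALSE
    }
  }
  kept <- set_model[keep, , drop = FALSE]
  out <- rbind(
    mention_frame(kept$start, kept$end, kept$text, kept$label),
    mention_frame(set_abbrev$start, set_abbrev$end, set_abbrev$text,
                  set_abbrev$label)
  )
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  mention_frame(out$start, out$end, out$text, out$label)
}
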
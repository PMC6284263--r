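# Corpus containers and format I/O.
#
# Offsets are 0-based, half-open [start, end) character positions
# everywhere, into the concatenation `title + " " + abstract` for
# document-level annotations. This matches the PubTator dialect.

#' Construct a mention table
#'
#' A mention is a character-offset span of text annotated as an entity.
#' Mentions are stored as a plain data frame with one row per span.
#'
#' @param start,end integer vectors of 0-based, half-open character offsets.
#' @param text character vector; must equal the document substring
#'   `[start, end)`.
#' @param label entity category; this package uses the single category
#'   `"Disease"`.
#' @param concept_id optional opaque identifier (e.g. a MeSH/OMIM id);
#'   carried through I/O, never interpreted.
#' @return a data.frame with columns `start`, `end`, `text`, `label`,
#'   `concept_id`, sorted by `start`.
#' @export
mention_frame <- function(start = integer(), end = integer(),
                          text = character(), label = character(),
                          concept_id = NA_character_) {
  n <- length(start)
  df <- data.frame(
    start = as.integer(start),
    end = as.integer(end),
    text = as.character(text),
    label = if (length(label)) as.character(label) else rep("Disease", n),
    concept_id = rep_len(as.character(concept_id), n),
    stringsAsFactors = FALSE
  )
  if (n > 0) df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname mention_frame
#' @export
empty_mentions <- function() mention_frame()

#' Construct an annotated document
#'
#' Bundles a title, an abstract and a mention table. Mention offsets index
#' into the concatenated text `paste(title, abstract)` (single space
#' separator).
#'
#' @param doc_id identifier string.
#' @param title,abstract document text fields.
#' @param mentions a mention table from [mention_frame()].
#' @param validate check mention invariants against the text (default TRUE).
#' @return an object of class `annotated_document` with fields `doc_id`,
#'   `title`, `abstract`, `text` and `mentions`.
#' @export
annotated_document <- function(doc_id, title, abstract,
                               mentions = empty_mentions(),
                               validate = TRUE) {
  text <- paste(title, abstract)
  doc <- structure(
    list(doc_id = as.character(doc_id), title = title, abstract = abstract,
         text = text, mentions = mentions),
    class = "annotated_document"
  )
  if (validate) validate_mentions(mentions, text, doc_id = doc_id)
  doc
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document %s: %d chars, %d mention(s)>\n",
              x$doc_id, nchar(x$text), nrow(x$mentions)))
  invisible(x)
}

validate_mentions <- function(mentions, text, doc_id = "?") {
  if (nrow(mentions) == 0) return(invisible(TRUE))
  if (any(mentions$start < 0 | mentions$start >= mentions$end |
            mentions$end > nchar(text))) {
    stop(sprintf("document %s: mention offsets out of range", doc_id))
  }
  got <- substr(rep(text, nrow(mentions)), mentions$start + 1L, mentions$end)
  bad <- which(got != mentions$text)
  if (length(bad)) {
    stop(sprintf(
      "document %s: mention text %s does not match substring %s at [%d,%d)",
      doc_id, dQuote(mentions$text[bad[1]]), dQuote(got[bad[1]]),
      mentions$start[bad[1]], mentions$end[bad[1]]
    ))
  }
  if (anyDuplicated(mentions[, c("start", "end")])) {
    stop(sprintf("document %s: duplicate mention spans", doc_id))
  }
  invisible(TRUE)
}

# Characters detached from token edges; hyphens and apostrophes stay
# inside tokens so compounds like "cat-eye" remain one unit.
.detach_punct <- c(".", ",", ";", ":", "(", ")", "[", "]",
                   "{", "}", "\"", "!", "?")

#' Tokenize text with character offsets
#'
#' Splits on whitespace, then detaches leading/trailing punctuation
#' (`.,;:()[]{}"!?`) as single-character tokens. Intra-word hyphens and
#' apostrophes are kept, so "cat-eye" is one token. Deterministic; the
#' token offsets partition the non-whitespace characters of the input.
#'
#' @param text a single string.
#' @return a data.frame with columns `text`, `start`, `end`
#'   (0-based, half-open), sorted and non-overlapping.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  out_text <- character(0); out_start <- integer(0); out_end <- integer(0)
  if (nchar(text) > 0) {
    m <- gregexpr("\\S+", text)[[1]]
    if (m[1] != -1) {
      chunk_start <- as.integer(m) - 1L            # to 0-based
      chunk_len <- attr(m, "match.length")
      for (ci in seq_along(chunk_start)) {
        s <- chunk_start[ci]
        e <- s + chunk_len[ci]                     # half-open
        chars <- strsplit(substr(text, s + 1L, e), "", fixed = TRUE)[[1]]
        lo <- 1L; hi <- length(chars)
        # leading punctuation, one token per character
        while (lo < hi && chars[lo] %in% .detach_punct) {
          out_text <- c(out_text, chars[lo])
          out_start <- c(out_start, s + lo - 1L)
          out_end <- c(out_end, s + lo)
          lo <- lo + 1L
        }
        # trailing punctuation (emitted after the core, in text order)
        trail_lo <- hi + 1L
        while (trail_lo - 1L > lo &&
                 chars[trail_lo - 1L] %in% .detach_punct) {
          trail_lo <- trail_lo - 1L
        }
        core_end <- trail_lo - 1L
        out_text <- c(out_text, paste(chars[lo:core_end], collapse = ""))
        out_start <- c(out_start, s + lo - 1L)
        out_end <- c(out_end, s + core_end)
        if (trail_lo <= hi) {
          for (p in trail_lo:hi) {
            out_text <- c(out_text, chars[p])
            out_start <- c(out_start, s + p - 1L)
            out_end <- c(out_end, s + p)
          }
        }
      }
    }
  }
  data.frame(text = out_text, start = out_start, end = out_end,
             stringsAsFactors = FALSE)
}

#' Split text into sentences
#'
#' Deterministic rule: a sentence boundary is a `.`, `?` or `!` followed by
#' whitespace and an uppercase letter. Returns 0-based half-open spans that
#' exclude inter-sentence whitespace.
#'
#' @param text a single string.
#' @return data.frame with columns `start`, `end`.
#' @export
split_sentences <- function(text) {
  n <- nchar(text)
  if (n == 0) return(data.frame(start = integer(0), end = integer(0)))
  m <- gregexpr("[.?!](?=\\s+[A-Z])", text, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1) integer(0) else as.integer(m)  # 1-based punct pos
  starts <- integer(0); ends <- integer(0)
  s <- 0L
  for (cut in cuts) {
    e <- cut                                  # include the punctuation
    starts <- c(starts, s); ends <- c(ends, e)
    # next sentence starts at first non-space after the cut
    rest <- substr(text, cut + 1L, n)
    off <- regexpr("\\S", rest)
    s <- cut + as.integer(off) - 1L
  }
  if (s < n) {
    # trim trailing whitespace from the final sentence
    e <- n
    while (e > s && grepl("^\\s$", substr(text, e, e))) e <- e - 1L
    starts <- c(starts, s); ends <- c(ends, e)
  }
  data.frame(start = starts, end = ends)
}

#' Encode offset mentions as a BIO tag sequence
#'
#' The first token overlapping a mention gets `B`, further overlapping
#' tokens get `I`, everything else `O`. A token that only partially
#' overlaps a mention boundary counts as inside (the span is snapped
#' outward to token boundaries).
#'
#' @param tokens token table from [tokenize()].
#' @param mentions mention table; spans must not overlap each other.
#' @return character vector of tags over `{"B","I","O"}`, one per token.
#' @export
mentions_to_bio <- function(tokens, mentions) {
  tags <- rep("O", nrow(tokens))
  if (nrow(mentions) == 0) return(tags)
  mn <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
  if (nrow(mn) > 1) {
    prev_end <- mn$end[-nrow(mn)]
    nxt_start <- mn$start[-1]
    bad <- which(nxt_start < prev_end)
    if (length(bad)) {
      stop(sprintf("overlapping mentions: [%d,%d) and [%d,%d)",
                   mn$start[bad[1]], mn$end[bad[1]],
                   mn$start[bad[1] + 1L], mn$end[bad[1] + 1L]))
    }
  }
  for (i in seq_len(nrow(mn))) {
    hit <- which(tokens$start < mn$end[i] & tokens$end > mn$start[i])
    if (length(hit)) {
      tags[hit] <- "I"
      tags[hit[1]] <- "B"
    }
  }
  tags
}

#' Decode a BIO tag sequence into offset mentions
#'
#' Maximal runs matching `B I*` become mentions spanning from the first
#' token's start to the last token's end. An `I` not preceded by `B` or
#' `I` is repaired to `B` (standard BIO repair).
#'
#' @param tokens token table aligned with `tags`.
#' @param tags character vector over `{"B","I","O"}`.
#' @param text optional source string; when given, mention text is the
#'   exact substring, otherwise token texts joined on single spaces.
#' @param label label assigned to decoded mentions.
#' @return a mention table.
#' @export
bio_to_mentions <- function(tokens, tags, text = NULL, label = "Disease") {
  if (nrow(tokens) != length(tags)) {
    stop(sprintf("length mismatch: %d tokens vs %d tags",
                 nrow(tokens), length(tags)))
  }
  if (length(tags) && !all(tags %in% c("B", "I", "O"))) {
    stop("tags must be in {B, I, O}")
  }
  tags <- repair_bio(tags)
  starts <- integer(0); ends <- integer(0); texts <- character(0)
  i <- 1L
  while (i <= length(tags)) {
    if (tags[i] == "B") {
      j <- i
      while (j + 1L <= length(tags) && tags[j + 1L] == "I") j <- j + 1L
      s <- tokens$start[i]; e <- tokens$end[j]
      starts <- c(starts, s); ends <- c(ends, e)
      texts <- c(texts, if (!is.null(text)) {
        substr(text, s + 1L, e)
      } else {
        paste(tokens$text[i:j], collapse = " ")
      })
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  mention_frame(starts, ends, texts, rep(label, length(starts)))
}

#' Repair an illegal BIO sequence
#'
#' Rewrites any `I` that does not follow `B` or `I` to `B`.
#'
#' @param tags character vector over `{"B","I","O"}`.
#' @return legal tag vector.
#' @export
repair_bio <- function(tags) {
  if (!length(tags)) return(tags)
  for (i in seq_along(tags)) {
    if (tags[i] == "I" && (i == 1L || tags[i - 1L] == "O")) tags[i] <- "B"
  }
  tags
}

#' Read a PubTator-style annotated corpus
#'
#' Parses the line-oriented dialect: `PMID|t|title`, `PMID|a|abstract`,
#' then zero or more `PMID<TAB>start<TAB>end<TAB>text<TAB>type[<TAB>id]`
#' annotation lines; a blank line separates documents. Annotation offsets
#' are validated against `title + " " + abstract`; an annotation whose
#' text disagrees with the substring at its offsets is dropped with a
#' warning naming the document and line. A document without both title
#' and abstract lines is a fatal error.
#'
#' @param con a file path, a connection, or a character vector of lines.
#' @return a list of [annotated_document()] objects.
#' @export
read_pubtator <- function(con) {
  lines <- if (is.character(con) && length(con) == 1 && file.exists(con)) {
    readLines(con, encoding = "UTF-8")
  } else if (inherits(con, "connection")) {
    readLines(con, encoding = "UTF-8")
  } else {
    as.character(con)
  }
  docs <- list()
  block <- character(0); block_line0 <- 1L
  flush_block <- function(block, line0) {
    if (!length(block)) return(NULL)
    tm <- regmatches(block, regexec("^([^|]+)\\|t\\|(.*)$", block))
    am <- regmatches(block, regexec("^([^|]+)\\|a\\|(.*)$", block))
    t_idx <- which(vapply(tm, length, 1L) == 3L)
    a_idx <- which(vapply(am, length, 1L) == 3L)
    if (length(t_idx) != 1 || length(a_idx) != 1) {
      stop(sprintf("PubTator block at line %d: need exactly one title and one abstract line",
                   line0))
    }
    doc_id <- tm[[t_idx]][2]
    title <- tm[[t_idx]][3]
    abstract <- am[[a_idx]][3]
    text <- paste(title, abstract)
    ann_idx <- setdiff(seq_along(block), c(t_idx, a_idx))
    starts <- integer(0); ends <- integer(0); txts <- character(0)
    labs <- character(0); ids <- character(0)
    for (k in ann_idx) {
      f <- strsplit(block[k], "\t", fixed = TRUE)[[1]]
      if (length(f) < 5) {
        stop(sprintf("document %s, line %d: malformed annotation line",
                     doc_id, line0 + k - 1L))
      }
      s <- suppressWarnings(as.integer(f[2]))
      e <- suppressWarnings(as.integer(f[3]))
      if (is.na(s) || is.na(e) || s < 0 || e <= s || e > nchar(text)) {
        warning(sprintf("document %s, line %d: annotation offsets out of range; dropped",
                        doc_id, line0 + k - 1L))
        next
      }
      got <- substr(text, s + 1L, e)
      if (got != f[4]) {
        warning(sprintf(
          "document %s, line %d: annotation text %s does not match substring %s; dropped",
          doc_id, line0 + k - 1L, dQuote(f[4]), dQuote(got)))
        next
      }
      starts <- c(starts, s); ends <- c(ends, e); txts <- c(txts, f[4])
      labs <- c(labs, f[5])
      ids <- c(ids, if (length(f) >= 6) f[6] else NA_character_)
    }
    annotated_document(doc_id, title, abstract,
                       mention_frame(starts, ends, txts, labs, ids))
  }
  for (i in seq_along(lines)) {
    if (nzchar(trimws(lines[i]))) {
      if (!length(block)) block_line0 <- i
      block <- c(block, lines[i])
    } else if (length(block)) {
      docs[[length(docs) + 1L]] <- flush_block(block, block_line0)
      block <- character(0)
    }
  }
  if (length(block)) docs[[length(docs) + 1L]] <- flush_block(block, block_line0)
  docs
}

#' Write documents in PubTator format
#'
#' Inverse of [read_pubtator()]; `read_pubtator(write_pubtator(docs))`
#' reproduces the documents exactly.
#'
#' @param docs list of [annotated_document()] objects.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`) the output lines.
#' @export
write_pubtator <- function(docs, path = NULL) {
  out <- character(0)
  for (d in docs) {
    out <- c(out,
             sprintf("%s|t|%s", d$doc_id, d$title),
             sprintf("%s|a|%s", d$doc_id, d$abstract))
    if (nrow(d$mentions)) {
      mn <- d$mentions
      for (i in seq_len(nrow(mn))) {
        fields <- c(d$doc_id, mn$start[i], mn$end[i], mn$text[i], mn$label[i])
        if (!is.na(mn$concept_id[i])) fields <- c(fields, mn$concept_id[i])
        out <- c(out, paste(fields, collapse = "\t"))
      }
    }
    out <- c(out, "")
  }
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Write documents as CoNLL-style BIO token files
#'
#' One token per line as `text<TAB>tag`, blank line between sentences.
#' Sentences follow [split_sentences()]; tags follow [mentions_to_bio()].
#'
#' @param docs list of annotated documents.
#' @param path optional output file.
#' @return the output lines (invisibly when `path` is given).
#' @export
write_conll <- function(docs, path = NULL) {
  out <- character(0)
  for (d in docs) {
    sents <- split_sentences(d$text)
    for (si in seq_len(nrow(sents))) {
      stext <- substr(d$text, sents$start[si] + 1L, sents$end[si])
      toks <- tokenize(stext)
      toks$start <- toks$start + sents$start[si]
      toks$end <- toks$end + sents$start[si]
      tags <- mentions_to_bio(toks, d$mentions)
      out <- c(out, paste(toks$text, tags, sep = "\t"), "")
    }
  }
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Read a CoNLL-style BIO token file
#'
#' @param con file path, connection, or character vector of lines.
#' @return a list of sentences, each a data.frame with columns `text`,
#'   `tag`.
#' @export
read_conll <- function(con) {
  lines <- if (is.character(con) && length(con) == 1 && file.exists(con)) {
    readLines(con, encoding = "UTF-8")
  } else if (inherits(con, "connection")) {
    readLines(con, encoding = "UTF-8")
  } else {
    as.character(con)
  }
  sents <- list(); cur_text <- character(0); cur_tag <- character(0)
  for (ln in lines) {
    if (!nzchar(ln)) {
      if (length(cur_text)) {
        sents[[length(sents) + 1L]] <-
          data.frame(text = cur_text, tag = cur_tag, stringsAsFactors = FALSE)
        cur_text <- character(0); cur_tag <- character(0)
      }
    } else {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 2) stop(sprintf("malformed CoNLL line: %s", dQuote(ln)))
      cur_text <- c(cur_text, f[1]); cur_tag <- c(cur_tag, f[2])
    }
  }
  if (length(cur_text)) {
    sents[[length(sents) + 1L]] <-
      data.frame(text = cur_text, tag = cur_tag, stringsAsFactors = FALSE)
  }
  sents
}

#' Read word vectors in word2vec text format
#'
#' Header line `V D`, then one `word v1 ... vD` line per word.
#'
#' @param con file path, connection, or character vector of lines.
#' @return list with `words` (character), `vectors` (V x D matrix with
#'   rownames = words) and `dimension`.
#' @export
read_word_vectors <- function(con) {
  lines <- if (is.character(con) && length(con) == 1 && file.exists(con)) {
    readLines(con, encoding = "UTF-8")
  } else if (inherits(con, "connection")) {
    readLines(con, encoding = "UTF-8")
  } else {
    as.character(con)
  }
  if (!length(lines)) stop("empty vector file")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2) stop("line 1: header must be 'V D'")
  V <- as.integer(hdr[1]); D <- as.integer(hdr[2])
  if (length(lines) - 1L != V) {
    stop(sprintf("header declares %d rows but file has %d", V, length(lines) - 1L))
  }
  words <- character(V)
  vec <- matrix(0, V, D)
  for (i in seq_len(V)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(f) != D + 1L) {
      stop(sprintf("line %d: expected %d values, found %d",
                   i + 1L, D, length(f) - 1L))
    }
    words[i] <- f[1]
    vec[i, ] <- as.numeric(f[-1])
  }
  if (anyDuplicated(words)) {
    stop(sprintf("duplicate word %s", dQuote(words[duplicated(words)][1])))
  }
  rownames(vec) <- words
  list(words = words, vectors = vec, dimension = D)
}

#' Write word vectors in word2vec text format
#'
#' Values are printed with 9 significant digits, so a round trip through
#' [read_word_vectors()] reproduces them to well under 1e-6.
#'
#' @param model an `embedding_model` (its input vectors are written) or a
#'   list with `words` and `vectors`.
#' @param path optional output file.
#' @return the output lines (invisibly when `path` is given).
#' @export
write_word_vectors <- function(model, path = NULL) {
  if (inherits(model, "embedding_model")) {
    words <- model$vocab$words
    vec <- model$input_vectors
  } else {
    words <- model$words
    vec <- model$vectors
  }
  out <- c(sprintf("%d %d", length(words), ncol(vec)),
           vapply(seq_along(words), function(i) {
             paste(c(words[i], sprintf("%.9g", vec[i, ])), collapse = " ")
           }, character(1)))
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}
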
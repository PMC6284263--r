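# Mention-level evaluation: exact-span matching, precision/recall/F1
# and a put-back (with-replacement) bootstrap confidence interval over
# documents.

#' Match predicted against gold mentions (exact span)
#'
#' A predicted mention is a true positive iff a gold mention with the
#' identical `(start, end)` span exists; unmatched predictions are false
#' positives and unmatched gold mentions false negatives.
#'
#' @param gold,predicted mention tables for one document; each must be
#'   internally non-overlapping.
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
match_mentions <- function(gold, predicted) {
  check_no_overlap <- function(m, what) {
    if (nrow(m) < 2) return(invisible())
    m <- m[order(m$start, m$end), , drop = FALSE]
    if (any(m$start[-1] < m$end[-nrow(m)])) {
      stop(sprintf("overlapping mentions in %s set", what))
    }
  }
  check_no_overlap(gold, "gold")
  check_no_overlap(predicted, "predicted")
  gkey <- paste(gold$start, gold$end)
  pkey <- paste(predicted$start, predicted$end)
  tp <- sum(pkey %in% gkey)
  c(tp = tp, fp = length(pkey) - tp, fn = length(gkey) - tp)
}

#' Precision, recall and F1 from counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`. When a
#' denominator is zero the corresponding metric is 0 by convention, and
#' so is F1.
#'
#' @param tp,fp,fn nonnegative integer counts.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be nonnegative")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Evaluate predictions over a corpus
#'
#' Sums exact-span TP/FP/FN counts over aligned document lists and
#' reports precision, recall and F1.
#'
#' @param gold_docs,pred_docs aligned lists of annotated documents (the
#'   mention tables of `pred_docs` are the predictions).
#' @return an object of class `eval_report`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` and `matching = "exact-span"`.
#' @export
evaluate_corpus <- function(gold_docs, pred_docs) {
  if (length(gold_docs) != length(pred_docs)) {
    stop("gold and predicted document lists must align")
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(gold_docs)) {
    cnt <- match_mentions(gold_docs[[i]]$mentions, pred_docs[[i]]$mentions)
    tp <- tp + cnt["tp"]; fp <- fp + cnt["fp"]; fn <- fn + cnt["fn"]
  }
  m <- prf(tp, fp, fn)
  structure(list(tp = unname(tp), fp = unname(fp), fn = unname(fn),
                 precision = unname(m["precision"]),
                 recall = unname(m["recall"]), f1 = unname(m["f1"]),
                 matching = "exact-span"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("mention-level evaluation (%s matching)\n", x$matching))
  cat(sprintf("  tp=%d fp=%d fn=%d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  P=%.4f R=%.4f F1=%.4f\n", x$precision, x$recall, x$f1))
  invisible(x)
}

#' Bootstrap confidence interval for mention-level F1
#'
#' Put-back (with replacement) resampling of whole documents: each round
#' draws n documents with replacement from the aligned lists and
#' recomputes F1; the interval is the percentile interval of the
#' resampled F1 values at the requested level. Deterministic given the
#' seed.
#'
#' @inheritParams evaluate_corpus
#' @param rounds number of resampling rounds (default 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return an object of class `bootstrap_report`: list with `point`
#'   (the full-corpus [evaluate_corpus()] report), `rounds`, `level`,
#'   `f1_low`, `f1_high` and the resampled `f1_values`.
#' @export
bootstrap_f1 <- function(gold_docs, pred_docs, rounds = 100L,
                         level = 0.95, seed = 1L) {
  n <- length(gold_docs)
  if (n < 1) stop("empty document list")
  if (length(pred_docs) != n) stop("gold and predicted lists must align")
  point <- evaluate_corpus(gold_docs, pred_docs)
  vals <- with_seed(seed, {
    vapply(seq_len(rounds), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      evaluate_corpus(gold_docs[idx], pred_docs[idx])$f1
    }, numeric(1))
  })
  qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(point = point, rounds = as.integer(rounds), level = level,
                 f1_low = qs[1], f1_high = qs[2], f1_values = vals),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  print(x$point)
  cat(sprintf("  bootstrap %d rounds, %.0f%% CI for F1: [%.4f, %.4f]\n",
              x$rounds, 100 * x$level, x$f1_low, x$f1_high))
  invisible(x)
}
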
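# Question-condition bias audit: answer questions from their text alone.
# If a text-only probe scores far above chance, answers leak from question
# wording and a VQA model can succeed without looking at the image.

normalize_question <- function(q) {
  tolower(gsub("\\s+", " ", trimws(q)))
}

qa_questions <- function(qapairs) {
  vapply(qapairs, function(q) normalize_question(q$question), character(1))
}
qa_answers <- function(qapairs) {
  vapply(qapairs, function(q) q$answer, character(1))
}

# lexicographically-first argmax (deterministic tie-break)
argmax_lex <- function(tab) {
  nm <- sort(names(tab))
  nm[which.max(tab[nm])]
}

#' Fit a majority-vote text probe
#'
#' Maps each normalized question string to its most frequent training
#' answer; unseen questions fall back to the global majority answer. Ties
#' break lexicographically.
#'
#' @param train list of `surgvqa_qa` (training split).
#' @return a `surgvqa_probe` closure-style object with a `$predict(questions)`
#'   method.
#' @export
fit_majority_probe <- function(train) {
  if (!length(train)) {
    abort_surgvqa("empty training set", "surgvqa_probe_error")
  }
  qs <- qa_questions(train)
  as <- qa_answers(train)
  per_q <- tapply(as, qs, function(v) argmax_lex(table(v)))
  global <- argmax_lex(table(as))
  predict_fn <- function(questions) {
    questions <- vapply(questions, normalize_question, character(1),
                        USE.NAMES = FALSE)
    out <- unname(per_q[questions])
    out[is.na(out)] <- global
    out
  }
  structure(list(kind = "majority", predict = predict_fn,
                 classes = sort(unique(as))),
            class = "surgvqa_probe")
}

#' Fit a multinomial naive-Bayes token probe
#'
#' A bag-of-words probe over whitespace tokens with additive (Laplace)
#' smoothing: a non-neural stand-in for language-only models, capturing the
#' same phenomenon (answers predictable from question wording). Argmax with
#' a lexicographic tie-break.
#'
#' @param train list of `surgvqa_qa`.
#' @param smoothing additive pseudo-count (> 0).
#' @return a `surgvqa_probe`.
#' @export
fit_token_probe <- function(train, smoothing = 1) {
  if (!length(train)) {
    abort_surgvqa("empty training set", "surgvqa_probe_error")
  }
  if (smoothing <= 0) {
    abort_surgvqa("smoothing must be positive", "surgvqa_config_error")
  }
  qs <- qa_questions(train)
  as <- qa_answers(train)
  classes <- sort(unique(as))
  toks <- strsplit(qs, " ", fixed = TRUE)
  vocab_tok <- sort(unique(unlist(toks)))
  V <- length(vocab_tok)
  # token count matrix per class, and class priors
  counts <- matrix(0, nrow = length(classes), ncol = V,
                   dimnames = list(classes, vocab_tok))
  for (i in seq_along(toks)) {
    tb <- table(toks[[i]])
    counts[as[i], names(tb)] <- counts[as[i], names(tb)] + as.numeric(tb)
  }
  prior <- log(table(factor(as, levels = classes)) / length(as))
  denom <- log(rowSums(counts) + smoothing * V)
  predict_fn <- function(questions) {
    questions <- vapply(questions, normalize_question, character(1),
                        USE.NAMES = FALSE)
    vapply(strsplit(questions, " ", fixed = TRUE), function(tk) {
      tk <- tk[tk %in% vocab_tok]
      ll <- as.numeric(prior) - length(tk) * denom
      if (length(tk)) {
        tb <- table(tk)
        ll <- ll + as.numeric(log(counts[, names(tb), drop = FALSE] +
                                    smoothing) %*% as.numeric(tb))
      }
      names(ll) <- classes
      argmax_lex(ll)
    }, character(1))
  }
  structure(list(kind = "naive-bayes", predict = predict_fn,
                 classes = classes),
            class = "surgvqa_probe")
}

macro_metrics <- function(truth, pred) {
  classes <- sort(unique(truth))  # classes present in the test set
  rec <- f1 <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  }
  list(macro_recall = mean(rec), macro_f1 = mean(f1))
}

#' Evaluate a text-only probe on a test split
#'
#' Reports accuracy, macro-averaged recall and F-score over the answer
#' classes present in the test set (a class predicted but absent from the
#' test truth is excluded from the macro average), plus the empirical answer
#' entropy (bits) of each normalized question under the test distribution —
#' zero entropy everywhere means the question text fully determines the
#' answer.
#'
#' @param probe a `surgvqa_probe`.
#' @param test list of `surgvqa_qa`.
#' @return list of class `surgvqa_bias_report`: `accuracy`, `macro_recall`,
#'   `macro_f1`, `question_entropy` (named, bits), `mean_entropy`, `n`.
#' @export
evaluate_probe <- function(probe, test) {
  if (!length(test)) {
    abort_surgvqa("empty test set", "surgvqa_probe_error")
  }
  qs <- qa_questions(test)
  truth <- qa_answers(test)
  pred <- probe$predict(qs)
  acc <- mean(pred == truth)
  mm <- macro_metrics(truth, pred)
  ent <- tapply(truth, qs, function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  })
  structure(list(
    probe = probe$kind,
    accuracy = acc,
    macro_recall = mm$macro_recall,
    macro_f1 = mm$macro_f1,
    question_entropy = ent,
    mean_entropy = mean(ent),
    n = length(test)
  ), class = "surgvqa_bias_report")
}

#' @export
print.surgvqa_bias_report <- function(x, ...) {
  cat(sprintf(
    "<bias report: %s probe, n=%d>\n  accuracy %.3f | macro recall %.3f | macro F %.3f | mean answer entropy %.3f bits\n",
    x$probe, x$n, x$accuracy, x$macro_recall, x$macro_f1, x$mean_entropy))
  invisible(x)
}
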
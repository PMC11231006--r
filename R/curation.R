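# Curation: phase-balanced frame sampling, template blocklisting,
# degenerate-question elimination and answer-frequency rebalancing.

#' Default curation configuration
#'
#' @param tolerance non-negative integer: each phase may contribute up to
#'   `min phase count + tolerance` frames (default 0, i.e. strictly the
#'   minimum).
#' @param blocklist template ids excluded from generation. By default the
#'   counting-over-names template is blocked: anatomies appear at most once
#'   per frame, so questions such as "how many livers are there?" always
#'   have the same answer and leak it from the text alone.
#' @param cap per-scene question cap.
#' @param answer_cap maximum fraction any single answer may hold within a
#'   question type after rebalancing.
#' @return list of class `surgvqa_curation_config`.
#' @export
curation_config <- function(tolerance = 0L,
                            blocklist = c("cnt0_name_any"),
                            cap = 50L,
                            answer_cap = 0.6) {
  if (tolerance < 0) {
    abort_surgvqa("tolerance must be >= 0", "surgvqa_config_error")
  }
  if (answer_cap <= 0 || answer_cap > 1) {
    abort_surgvqa("answer_cap must be in (0, 1]", "surgvqa_config_error")
  }
  structure(list(tolerance = as.integer(tolerance), blocklist = blocklist,
                 cap = as.integer(cap), answer_cap = answer_cap),
            class = "surgvqa_curation_config")
}

#' Phase-balanced frame sampling
#'
#' Let m be the smallest per-phase frame count. Every phase contributes
#' between m and m + tolerance frames (all of them if it has fewer), drawn
#' uniformly without replacement; overrepresented phases are thereby trimmed
#' to a nearly equal share. Deterministic given the seed.
#'
#' @param frames character vector of frame ids.
#' @param timeline named character vector or data.frame (`frame_id`,
#'   `phase`) mapping every frame to its phase.
#' @param config a [curation_config()].
#' @param seed integer seed.
#' @return character vector of selected frame ids (original order).
#' @export
phase_balanced_sample <- function(frames, timeline,
                                  config = curation_config(), seed = 1L) {
  if (!length(frames)) return(character())
  if (is.data.frame(timeline)) {
    timeline <- stats::setNames(as.character(timeline$phase),
                                as.character(timeline$frame_id))
  }
  miss <- setdiff(frames, names(timeline))
  if (length(miss)) {
    abort_surgvqa(paste("frames missing from phase timeline:",
                        paste(utils::head(miss, 3), collapse = ", ")),
                  "surgvqa_config_error")
  }
  phase_of <- timeline[frames]
  counts <- table(phase_of)
  m <- min(counts)
  keep <- character()
  with_seed(seed, {
    for (ph in sort(names(counts))) {
      in_phase <- frames[phase_of == ph]
      k <- min(length(in_phase), m + config$tolerance)
      keep <- c(keep, if (k == length(in_phase)) in_phase
                      else sample(in_phase, k))
    }
  })
  frames[frames %in% keep]
}

#' Remove blocklisted templates from a registry
#'
#' @param templates named template registry from [load_templates()].
#' @param config a [curation_config()] (or any list with a `blocklist`
#'   element).
#' @return the registry without the blocklisted templates.
#' @export
apply_blocklist <- function(templates, config = curation_config()) {
  bl <- config$blocklist %||% character()
  unknown <- setdiff(bl, names(templates))
  if (length(unknown)) {
    abort_surgvqa(paste("blocklist names unknown template ids:",
                        paste(unknown, collapse = ", ")),
                  "surgvqa_config_error")
  }
  templates[setdiff(names(templates), bl)]
}

#' Drop degenerate question-answer pairs
#'
#' Removes (a) query questions whose referent class is absent from the
#' frame's graph, (b) counting questions that count an anatomy class (their
#' answer is constant because anatomies occur at most once per frame), and
#' (c) questions whose stored program evaluates to `QA_INVALID` on the
#' stored graph. Idempotent.
#'
#' @param qapairs list of `surgvqa_qa`.
#' @param graphs named list of `surgvqa_graph`, keyed by frame id.
#' @param vocab vocabulary config.
#' @return the retained `surgvqa_qa` list.
#' @export
degenerate_filter <- function(qapairs, graphs, vocab = load_vocab()) {
  keep <- vapply(qapairs, function(q) {
    g <- graphs[[q$frame_id]]
    if (is.null(g)) return(FALSE)
    prog <- q$program
    ans <- execute_program(prog, g)
    if (identical(ans, QA_INVALID)) return(FALSE)            # rule (c)
    if (q$qtype == "counting" && counts_anatomy(prog, vocab)) {
      return(FALSE)                                          # rule (b)
    }
    if (q$qtype %in% c("query_object", "query_attribute", "query_relation")) {
      names_present <- vapply(g$objects, function(o) o$name, character(1))
      referents <- unlist(lapply(prog, function(nd) {
        if (nd$op == "filter_name") nd$arg else NULL
      }))
      if (length(referents) && !all(referents %in% names_present)) {
        return(FALSE)                                        # rule (a)
      }
    }
    TRUE
  }, logical(1))
  qapairs[keep]
}

#' Rebalance answer frequencies within each question type
#'
#' Within each question type, subsamples so that no single answer exceeds
#' the configured cap fraction of that type's questions (a type whose pool
#' holds only one distinct answer is exempt). Overrepresented answers are
#' down-sampled uniformly without replacement; deterministic given the seed.
#'
#' @param qapairs list of `surgvqa_qa`.
#' @param config a [curation_config()]; `answer_cap` is the fraction.
#' @param seed integer seed.
#' @return the retained `surgvqa_qa` list (original relative order).
#' @export
answer_rebalance <- function(qapairs, config = curation_config(), seed = 1L) {
  if (!length(qapairs)) return(qapairs)
  f <- config$answer_cap
  qtypes <- vapply(qapairs, function(q) q$qtype, character(1))
  answers <- vapply(qapairs, function(q) q$answer, character(1))
  drop <- logical(length(qapairs))
  with_seed(seed, {
    for (qt in sort(unique(qtypes))) {
      pos <- which(qtypes == qt)
      tab <- table(answers[pos])
      if (length(tab) < 2) next
      # repeatedly trim the most frequent answer until every answer holds
      # at most fraction f of the (shrinking) pool
      repeat {
        total <- sum(tab)
        worst <- names(tab)[which.max(tab)]
        if (tab[worst] <= f * total) break
        # largest count satisfying c' <= f * (total - c + c')
        target <- floor(f * (total - tab[worst]) / (1 - f))
        target <- max(target, 1L)
        victims <- pos[answers[pos] == worst & !drop[pos]]
        n_drop <- length(victims) - target
        if (n_drop <= 0) break
        drop[sample(victims, n_drop)] <- TRUE
        tab[worst] <- target
      }
    }
  })
  qapairs[!drop]
}

#' Run the full curation pass over a generated dataset
#'
#' Applies the degenerate filter then answer rebalancing. (Template
#' blocklisting acts earlier, at generation time, via [apply_blocklist()].)
#'
#' @inheritParams degenerate_filter
#' @inheritParams answer_rebalance
#' @return curated `surgvqa_qa` list.
#' @export
curate_dataset <- function(qapairs, graphs, config = curation_config(),
                           seed = 1L, vocab = load_vocab()) {
  out <- degenerate_filter(qapairs, graphs, vocab)
  answer_rebalance(out, config, seed)
}
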
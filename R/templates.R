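# Template loading, slot binding, text realization and per-scene question
# generation.

REL_SURFACE <- c("left of" = "to the left of",
                 "right of" = "to the right of",
                 "above" = "above",
                 "below" = "below")
REL_TOKEN <- stats::setNames(names(REL_SURFACE), REL_SURFACE)

VERB_PAST <- c(grasp = "grasped", retract = "retracted", dissect = "dissected",
               coagulate = "coagulated", clip = "clipped", cut = "cut",
               aspirate = "aspirated", irrigate = "irrigated")

SLOT_KINDS <- c("color", "location", "type", "name", "name_anatomy",
                "name_instrument", "relation", "verb")

# Parameter kind letter (<C>, <L>, <T>, <N>, <R>) for a slot kind.
kind_letter <- function(kind) {
  switch(kind,
         color = "C", location = "L", type = "T",
         name = "N", name_anatomy = "N", name_instrument = "N",
         relation = "R", verb = "R")
}

#' Load the question-template registry
#'
#' Each entry carries a text pattern with typed slots, a functional-program
#' skeleton whose `"<X>"` arguments are filled from the same binding, a
#' question type and a complexity class. The registry is validated on load:
#' slots referenced by the text and the program must correspond one-to-one,
#' and the declared complexity must match [tag_complexity()] of the skeleton.
#'
#' @param path YAML registry file; defaults to the 40-template registry
#'   shipped with the package.
#' @return named list of `surgvqa_template` objects, keyed by template id.
#' @export
load_templates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "templates.yaml", package = "surgvqa")
  raw <- yaml::read_yaml(path)
  out <- list()
  for (tp in raw) {
    slots <- lapply(tp$slots, function(s) {
      list(kind = s$kind,
           optional = isTRUE(s$optional),
           enum = s$enum %||% "attested",
           surface = s$surface %||% "{v}",
           null_text = s$null_text %||% "")
    })
    bad <- vapply(slots, function(s) !s$kind %in% SLOT_KINDS, logical(1))
    if (any(bad)) {
      abort_surgvqa(paste0("template '", tp$id, "': unknown slot kind"),
                    "surgvqa_template_error")
    }
    text_slots <- regmatches(tp$text, gregexpr("<[A-Z][0-9]?>", tp$text))[[1]]
    text_slots <- gsub("[<>]", "", text_slots)
    if (!setequal(text_slots, names(slots))) {
      abort_surgvqa(paste0("template '", tp$id,
                           "': text slots and declared slots differ"),
                    "surgvqa_template_error")
    }
    prog_slots <- unlist(lapply(tp$program, function(nd) {
      a <- nd$arg
      if (!is.null(a) && grepl("^<.+>$", a)) gsub("[<>]", "", a) else NULL
    }))
    extra <- setdiff(prog_slots, names(slots))
    if (length(extra)) {
      abort_surgvqa(paste0("template '", tp$id,
                           "': program references undeclared slots"),
                    "surgvqa_template_error")
    }
    tpl <- structure(list(
      template_id = tp$id, qtype = tp$qtype, complexity = tp$complexity,
      text = tp$text, slots = slots, skeleton = tp$program
    ), class = "surgvqa_template")
    # complexity must be derivable from the skeleton (fill dummy binding)
    dummy <- lapply(slots, function(s) "x")
    chk <- tryCatch(tag_complexity(bind_program(tpl, dummy)),
                    error = function(e) NA_character_)
    if (!identical(chk, tp$complexity)) {
      abort_surgvqa(paste0("template '", tp$id,
                           "': declared complexity does not match skeleton"),
                    "surgvqa_template_error")
    }
    out[[tp$id]] <- tpl
  }
  out
}

# Instantiate a program skeleton under a binding: slot arguments are
# substituted (relation surface forms map back to relation tokens), filter
# nodes whose slot is bound to null are dropped and the chain re-wired.
bind_program <- function(template, binding) {
  nodes <- template$skeleton
  n <- length(nodes)
  keep <- rep(TRUE, n)
  args <- vector("list", n)
  for (i in seq_len(n)) {
    a <- nodes[[i]]$arg
    if (!is.null(a) && grepl("^<.+>$", a)) {
      slot <- gsub("[<>]", "", a)
      v <- binding[[slot]]
      if (is.null(v)) {
        if (!grepl("^filter_", nodes[[i]]$op)) {
          abort_surgvqa(paste0("slot '", slot, "' is required by op ",
                               nodes[[i]]$op), "surgvqa_binding_error")
        }
        keep[i] <- FALSE
      } else {
        kind <- template$slots[[slot]]$kind
        args[[i]] <- if (kind == "relation") unname(REL_TOKEN[v] %||% v) else v
      }
    } else if (!is.null(a)) {
      args[[i]] <- a
    }
  }
  # rewire: a dropped (single-input) filter forwards its own input
  fwd <- seq_len(n)
  for (i in seq_len(n)) {
    if (!keep[i]) fwd[i] <- fwd[nodes[[i]]$inputs %||% (i - 1L)]
  }
  new_idx <- cumsum(keep)
  built <- list()
  for (i in seq_len(n)) {
    if (!keep[i]) next
    nd <- nodes[[i]]
    ins <- nd$inputs %||% if (nd$op == "scene") integer() else (i - 1L)
    ins <- vapply(as.integer(ins), function(j) new_idx[fwd[j]], integer(1))
    built[[length(built) + 1]] <- pnode(nd$op, args[[i]], ins)
  }
  program(built)
}

#' Realize a question string from a template and a slot binding
#'
#' Substitutes slot values into the text pattern (relations keep their
#' surface form such as "to the left of"; verbs surface as past participles),
#' replaces null optional slots by their configured null text (usually
#' dropping them; a null location in counting questions realizes as
#' "in the frame"; a null type as "thing"), collapses repeated whitespace and
#' lowercases the result. Pure function of its arguments.
#'
#' @param template a `surgvqa_template`.
#' @param binding named list slot -> value; NULL marks a null optional slot.
#' @return the question string.
#' @export
#' @examples
#' reg <- load_templates()
#' realize_text(reg$qo1_tool_rcl_t,
#'              list(R = "to the left of", C = "yellow", L = NULL,
#'                   T = "anatomy"))
realize_text <- function(template, binding) {
  txt <- template$text
  for (slot in names(template$slots)) {
    sp <- template$slots[[slot]]
    if (!slot %in% names(binding) || is.null(binding[[slot]])) {
      if (!sp$optional) {
        abort_surgvqa(paste0("missing value for required slot '", slot, "'"),
                      "surgvqa_binding_error")
      }
      piece <- sp$null_text
    } else {
      v <- binding[[slot]]
      if (sp$kind == "verb") v <- unname(VERB_PAST[v] %||% v)
      piece <- gsub("{v}", v, sp$surface, fixed = TRUE)
    }
    txt <- gsub(paste0("<", slot, ">"), piece, txt, fixed = TRUE)
  }
  txt <- gsub("\\s+", " ", txt)
  txt <- gsub("\\s+([?;,.])", "\\1", txt)
  tolower(trimws(txt))
}

# Attested attribute values of a graph, used for candidate enumeration.
graph_attested <- function(graph) {
  objs <- graph$objects
  list(
    name = sort(unique(vapply(objs, function(o) o$name, character(1)))),
    color = sort(unique(vapply(objs, function(o) o$color, character(1)))),
    location = sort(unique(vapply(objs, function(o) o$location, character(1)))),
    type = sort(unique(vapply(objs, function(o) o$category, character(1)))),
    verb = sort(unique(graph$action_edges$verb))
  )
}

slot_candidates <- function(sp, attested, vocab) {
  vals <- switch(sp$kind,
    color = if (sp$enum == "vocab") sort(unique(unname(vocab$colors))) else attested$color,
    location = if (sp$enum == "vocab") vocab$locations else attested$location,
    type = c("instrument", "anatomy"),
    name = if (sp$enum == "vocab") sort(c(vocab$instruments, vocab$anatomies)) else attested$name,
    name_anatomy = if (sp$enum == "vocab") sort(vocab$anatomies)
                   else intersect(attested$name, vocab$anatomies),
    name_instrument = if (sp$enum == "vocab") sort(vocab$instruments)
                      else intersect(attested$name, vocab$instruments),
    relation = unname(REL_SURFACE[vocab$relations]),
    verb = if (sp$enum == "vocab") vocab$verbs else attested$verb
  )
  vals <- as.list(vals)
  if (sp$optional) vals <- c(vals, list(NULL))
  vals
}

binding_key <- function(binding) {
  paste(vapply(names(binding), function(s) {
    paste0(s, "=", binding[[s]] %||% "null")
  }, character(1)), collapse = "|")
}

qa_pair <- function(question, answer, template, binding, prog, frame_id) {
  structure(list(
    question = question, answer = answer,
    template_id = template$template_id,
    binding = binding, program = prog, frame_id = frame_id,
    qtype = template$qtype, complexity = template$complexity
  ), class = "surgvqa_qa")
}

#' Enumerate all valid instantiations of a template on a scene graph
#'
#' Candidate slot bindings are enumerated from the graph's attested
#' attribute values for query templates, and from the full vocabulary for
#' the probe slots of existence/counting templates (so negative answers
#' occur). Each bound program is executed; candidates whose execution
#' returns `QA_INVALID` (which includes every failed `unique()`, i.e. every
#' ambiguous or unmatched referring expression) are discarded, as are counts
#' above the vocabulary's `max_count`. Output order is canonical
#' (binding enumeration order), so the result is deterministic.
#'
#' @param template a `surgvqa_template`.
#' @param graph a `surgvqa_graph`.
#' @param vocab vocabulary config.
#' @return list of `surgvqa_qa` objects (possibly empty).
#' @export
instantiate <- function(template, graph, vocab = load_vocab()) {
  attested <- graph_attested(graph)
  cand <- lapply(template$slots, slot_candidates,
                 attested = attested, vocab = vocab)
  slot_names <- names(template$slots)
  n_per <- vapply(cand, length, integer(1))
  if (any(n_per == 0)) return(list())
  grid_n <- prod(n_per)
  answers_ok <- answer_vocabulary(vocab)
  out <- list()
  idx <- rep(1L, length(n_per))
  for (g in seq_len(grid_n)) {
    binding <- stats::setNames(
      lapply(seq_along(slot_names), function(k) cand[[k]][[idx[k]]]),
      slot_names)
    prog <- bind_program(template, binding)
    ans <- execute_program(prog, graph)
    if (!identical(ans, QA_INVALID) && ans %in% answers_ok) {
      out[[length(out) + 1]] <- qa_pair(
        realize_text(template, binding), ans, template, binding, prog,
        graph$frame_id)
    }
    # odometer increment over the candidate grid
    for (k in seq_along(idx)) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= n_per[k]) break
      idx[k] <- 1L
    }
  }
  out
}

#' Generate a capped, quota-respecting question set for one scene
#'
#' Runs [instantiate()] for every non-blocklisted template, de-duplicates by
#' question text, then samples without replacement up to the per-scene cap.
#' When per-type quotas are configured, each question type contributes at
#' most its quota. Candidates are ordered canonically by
#' (template id, binding) before seeded sampling, so output is deterministic
#' given the seed.
#'
#' @param graph a `surgvqa_graph`.
#' @param config list with `templates` (registry), optional `blocklist`
#'   (template ids), `cap` (default 50) and optional named `quotas`
#'   (qtype -> max count).
#' @param seed integer RNG seed.
#' @param vocab vocabulary config.
#' @return list of `surgvqa_qa`.
#' @export
generate_for_scene <- function(graph, config = list(), seed = 1L,
                               vocab = load_vocab()) {
  templates <- config$templates %||% load_templates()
  templates <- apply_blocklist(templates, config)
  cap <- config$cap %||% 50L
  if (cap <= 0) return(list())
  pool <- list()
  for (tp in templates) {
    pool <- c(pool, instantiate(tp, graph, vocab))
  }
  if (!length(pool)) return(list())
  keys <- vapply(pool, function(q) paste(q$template_id, binding_key(q$binding)),
                 character(1))
  pool <- pool[order(keys)]
  qtext <- vapply(pool, function(q) q$question, character(1))
  pool <- pool[!duplicated(qtext)]
  qtypes <- vapply(pool, function(q) q$qtype, character(1))
  with_seed(seed, {
    chosen <- logical(length(pool))
    quotas <- config$quotas
    if (!is.null(quotas)) {
      for (qt in names(quotas)) {
        pos <- which(qtypes == qt)
        take <- min(length(pos), quotas[[qt]])
        if (take > 0) chosen[sample(pos, take)] <- TRUE
      }
      extra_allowed <- cap - sum(chosen)
      if (extra_allowed > 0) {
        rest <- which(!chosen & !qtypes %in% names(quotas))
        if (length(rest)) {
          chosen[sample(rest, min(length(rest), extra_allowed))] <- TRUE
        }
      } else if (sum(chosen) > cap) {
        keep <- sample(which(chosen), cap)
        chosen <- logical(length(pool)); chosen[keep] <- TRUE
      }
    } else {
      chosen[sample(seq_along(pool), min(length(pool), cap))] <- TRUE
    }
    pool[chosen]
  })
}
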
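# Interchange formats: scene graphs as one JSON document per frame, QA pairs
# as JSONL, detections/triplets/phases as CSV. Structural validation runs on
# both read and write; human-readable JSON Schema documents ship under
# inst/extdata/schemas/.

graph_to_list <- function(g) {
  list(
    frame_id = g$frame_id,
    frame_dims = list(width = g$frame_dims[1], height = g$frame_dims[2]),
    objects = lapply(unname(g$objects), function(o) list(
      object_id = o$object_id, name = o$name, category = o$category,
      color = o$color,
      bbox = list(x1 = unname(o$bbox["x1"]), y1 = unname(o$bbox["y1"]),
                  x2 = unname(o$bbox["x2"]), y2 = unname(o$bbox["y2"])),
      location = o$location)),
    spatial_edges = unname(apply(g$spatial_edges, 1, as.list)),
    action_edges = lapply(seq_len(nrow(g$action_edges)), function(i) list(
      instrument_id = g$action_edges$instrument_id[i],
      verb = g$action_edges$verb[i],
      target_id = g$action_edges$target_id[i]))
  )
}

graph_from_list <- function(x, vocab = load_vocab()) {
  need <- c("frame_id", "frame_dims", "objects", "spatial_edges",
            "action_edges")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_surgvqa(paste("scene-graph document missing fields:",
                        paste(miss, collapse = ", ")),
                  "surgvqa_validation_error")
  }
  dims <- c(x$frame_dims$width, x$frame_dims$height)
  objects <- list()
  for (o in x$objects) {
    b <- bbox(o$bbox$x1, o$bbox$y1, o$bbox$x2, o$bbox$y2, dims)
    so <- scene_object(o$object_id, o$name, b, dims, vocab)
    if (!identical(so$category, o$category) ||
        !identical(so$color, o$color) ||
        !identical(so$location, o$location)) {
      abort_surgvqa(paste0("object '", o$object_id,
                           "' attributes disagree with the vocabulary"),
                    "surgvqa_validation_error")
    }
    objects[[o$object_id]] <- so
  }
  sed <- if (length(x$spatial_edges)) {
    data.frame(
      source = vapply(x$spatial_edges, function(e) e$source %||% e[[1]], character(1)),
      relation = vapply(x$spatial_edges, function(e) e$relation %||% e[[2]], character(1)),
      target = vapply(x$spatial_edges, function(e) e$target %||% e[[3]], character(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), relation = character(),
               target = character(), stringsAsFactors = FALSE)
  }
  aed <- if (length(x$action_edges)) {
    data.frame(
      instrument_id = vapply(x$action_edges, `[[`, character(1), "instrument_id"),
      verb = vapply(x$action_edges, `[[`, character(1), "verb"),
      target_id = vapply(x$action_edges, `[[`, character(1), "target_id"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(instrument_id = character(), verb = character(),
               target_id = character(), stringsAsFactors = FALSE)
  }
  g <- structure(list(frame_id = x$frame_id, frame_dims = as.numeric(dims),
                      objects = objects, spatial_edges = sed,
                      action_edges = aed), class = "surgvqa_graph")
  validate_graph(g, vocab)
  g
}

#' Write scene graphs as one JSON document per frame
#'
#' @param graphs named list of `surgvqa_graph`.
#' @param dir output directory (created if needed); each graph lands in
#'   `<frame_id>.json`.
#' @return invisibly, the written paths.
#' @export
write_scene_graphs <- function(graphs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(graphs, function(g) {
    p <- file.path(dir, paste0(g$frame_id, ".json"))
    jsonlite::write_json(graph_to_list(g), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    p
  }, character(1))
  invisible(paths)
}

#' Read scene graphs from a directory of per-frame JSON documents
#'
#' Every document is validated on read (field presence, vocabulary
#' membership, attribute consistency, no dangling edge endpoints).
#'
#' @param dir directory containing `*.json` graph documents.
#' @param vocab vocabulary config.
#' @return named list of `surgvqa_graph`, keyed by frame id.
#' @export
read_scene_graphs <- function(dir, vocab = load_vocab()) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  out <- list()
  for (f in files) {
    x <- jsonlite::read_json(f)
    g <- tryCatch(graph_from_list(x, vocab), error = function(e) {
      abort_surgvqa(paste0(basename(f), ": ", conditionMessage(e)),
                    "surgvqa_validation_error")
    })
    out[[g$frame_id]] <- g
  }
  out
}

qa_to_list <- function(q) {
  list(
    question = q$question, answer = q$answer, template_id = q$template_id,
    binding = if (length(q$binding)) q$binding else stats::setNames(list(), character()),
    program = if (is.null(q$program)) NULL else lapply(q$program, function(nd) {
      list(op = nd$op, arg = nd$arg, inputs = as.list(nd$inputs))
    }),
    frame_id = q$frame_id, qtype = q$qtype, complexity = q$complexity
  )
}

qa_from_list <- function(x, line = NA) {
  need <- c("question", "answer", "template_id", "frame_id", "qtype",
            "complexity")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_surgvqa(sprintf("QA record%s missing fields: %s",
                          if (is.na(line)) "" else paste0(" (line ", line, ")"),
                          paste(miss, collapse = ", ")),
                  "surgvqa_validation_error")
  }
  prog <- NULL
  if (!is.null(x$program)) {
    prog <- program(lapply(x$program, function(nd) {
      pnode(nd$op, nd$arg, as.integer(unlist(nd$inputs)))
    }))
  }
  binding <- x$binding %||% list()
  structure(list(
    question = x$question, answer = x$answer, template_id = x$template_id,
    binding = binding, program = prog, frame_id = x$frame_id,
    qtype = x$qtype, complexity = x$complexity
  ), class = "surgvqa_qa")
}

#' Write QA pairs as JSONL (one record per line)
#'
#' @param qapairs list of `surgvqa_qa`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_qa <- function(qapairs, path) {
  lines <- vapply(qapairs, function(q) {
    jsonlite::toJSON(qa_to_list(q), auto_unbox = TRUE, digits = NA,
                     null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read QA pairs from JSONL
#'
#' Malformed lines raise a validation error naming the line number.
#'
#' @param path JSONL file.
#' @return list of `surgvqa_qa`.
#' @export
read_qa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) {
                    abort_surgvqa(sprintf("line %d: malformed JSON (%s)",
                                          i, conditionMessage(e)),
                                  "surgvqa_validation_error")
                  })
    out[[i]] <- qa_from_list(x, line = i)
  }
  out
}

#' Read object detections from CSV
#'
#' Expects columns `frame_id`, `class`, `x1`, `y1`, `x2`, `y2`; an optional
#' `score` column defaults to 1.0.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "class", "x1", "y1", "x2", "y2")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort_surgvqa(paste("detections CSV missing columns:",
                        paste(miss, collapse = ", ")),
                  "surgvqa_validation_error")
  }
  if (is.null(d$score)) d$score <- 1.0
  d
}

#' Read action triplets from CSV
#'
#' Expects columns `frame_id`, `instrument_class`, `verb`, `target_class`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_triplets <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "instrument_class", "verb", "target_class")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort_surgvqa(paste("triplets CSV missing columns:",
                        paste(miss, collapse = ", ")),
                  "surgvqa_validation_error")
  }
  d
}

#' Read a frame-to-phase timeline from CSV
#'
#' Expects columns `frame_id`, `phase`; phases must belong to the vocabulary.
#'
#' @param path CSV file.
#' @param vocab vocabulary config.
#' @return data.frame with `frame_id`, `phase`.
#' @export
read_phases <- function(path, vocab = load_vocab()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "phase")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort_surgvqa(paste("phases CSV missing columns:",
                        paste(miss, collapse = ", ")),
                  "surgvqa_validation_error")
  }
  bad <- setdiff(unique(d$phase), vocab$phases)
  if (length(bad)) {
    abort_surgvqa(paste("unknown phase tokens:", paste(bad, collapse = ", ")),
                  "surgvqa_vocab_error")
  }
  d
}

#' Dataset statistics
#'
#' Mirrors the usual VQA dataset summary: question counts, distinct
#' normalized questions (lowercase, collapsed whitespace), mean question
#' length in whitespace tokens, questions per scene, and breakdowns by
#' question type, complexity and answer.
#'
#' @param qapairs list of `surgvqa_qa`.
#' @param scenes list (or count) of scenes the questions were generated from.
#' @return list of class `surgvqa_stats`.
#' @export
compute_stats <- function(qapairs, scenes) {
  n_scenes <- if (is.numeric(scenes)) as.integer(scenes) else length(scenes)
  n_q <- length(qapairs)
  if (n_scenes == 0 && n_q > 0) {
    abort_surgvqa("questions present but zero scenes",
                  "surgvqa_validation_error")
  }
  qs <- vapply(qapairs, function(q) normalize_question(q$question), character(1))
  structure(list(
    n_scenes = n_scenes,
    n_questions = n_q,
    n_unique_questions = length(unique(qs)),
    avg_len_words = if (n_q) mean(lengths(strsplit(qs, " ", fixed = TRUE))) else 0,
    avg_q_per_scene = if (n_scenes) n_q / n_scenes else 0,
    per_qtype = if (n_q) table(vapply(qapairs, function(q) q$qtype, character(1))) else table(character()),
    per_complexity = if (n_q) table(vapply(qapairs, function(q) q$complexity, character(1))) else table(character()),
    answer_histogram = if (n_q) table(vapply(qapairs, function(q) q$answer, character(1))) else table(character())
  ), class = "surgvqa_stats")
}

#' @export
print.surgvqa_stats <- function(x, ...) {
  cat(sprintf(
    "<dataset stats: %d questions over %d scenes>\n  unique questions %d | avg length %.1f words | avg %.1f questions/scene\n",
    x$n_questions, x$n_scenes, x$n_unique_questions, x$avg_len_words,
    x$avg_q_per_scene))
  invisible(x)
}
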
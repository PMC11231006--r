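# Executable functional programs over scene graphs. A program is an ordered
# list of nodes; each node applies a primitive (filter, relate, unique,
# query, exist, count, intersect) to the outputs of earlier nodes. Programs
# are the ground-truth machinery: every emitted question stores the program
# that computes its answer.

#' Sentinel returned when a program has no well-defined answer
#'
#' `INVALID` is a value, not an error: a `unique()` step over a set that is
#' empty or ambiguous, or a verb query on a node with no action edge, yields
#' `QA_INVALID`, and the question engine discards such candidate bindings.
#' @export
QA_INVALID <- "__INVALID__"

PROGRAM_OPS <- c("scene", "filter_name", "filter_color", "filter_location",
                 "filter_type", "relate_spatial", "relate_action", "unique",
                 "query_name", "query_color", "query_location", "query_type",
                 "query_verb", "exist", "count", "intersect")
TERMINAL_OPS <- c("query_name", "query_color", "query_location", "query_type",
                  "query_verb", "exist", "count")
RELATE_OPS <- c("relate_spatial", "relate_action")

#' Construct one program node
#'
#' @param op primitive name (one of the operations above).
#' @param arg literal argument (e.g. a class name for `filter_name`, a
#'   relation token for `relate_spatial`, an optional verb for
#'   `relate_action`); NULL when the op takes none.
#' @param inputs integer indices of earlier nodes feeding this one; defaults
#'   to the immediately preceding node (chain style). `scene` takes none,
#'   `intersect` takes two.
#' @return list of class `surgvqa_pnode`.
#' @export
pnode <- function(op, arg = NULL, inputs = NULL) {
  structure(list(op = op, arg = arg, inputs = inputs),
            class = "surgvqa_pnode")
}

#' Assemble and validate a functional program
#'
#' @param nodes list of `pnode()` values. Omitted `inputs` are wired to the
#'   previous node.
#' @return list of class `surgvqa_program`.
#' @export
#' @examples
#' p <- program(list(pnode("scene"), pnode("filter_name", "liver"),
#'                   pnode("count")))
program <- function(nodes) {
  n <- length(nodes)
  if (!n) abort_surgvqa("empty program", "surgvqa_program_error")
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    nd <- nodes[[i]]
    if (!nd$op %in% PROGRAM_OPS) {
      abort_surgvqa(paste0("unknown program op: '", nd$op, "'"),
                    "surgvqa_program_error")
    }
    want <- switch(nd$op, scene = 0L, intersect = 2L, 1L)
    if (is.null(nd$inputs)) {
      if (want == 1L && i > 1L) {
        nd$inputs <- i - 1L
      } else if (want > 0L) {
        abort_surgvqa(sprintf("node %d (%s) needs explicit inputs", i, nd$op),
                      "surgvqa_program_error")
      } else nd$inputs <- integer()
    }
    nd$inputs <- as.integer(nd$inputs)
    if (length(nd$inputs) != want || any(nd$inputs >= i) || any(nd$inputs < 1)) {
      abort_surgvqa(sprintf("node %d (%s): bad input wiring", i, nd$op),
                    "surgvqa_program_error")
    }
    used[nd$inputs] <- TRUE
    nodes[[i]] <- nd
  }
  if (any(used[n]) || !all(used[-n])) {
    abort_surgvqa("program must have a single terminal node (the last)",
                  "surgvqa_program_error")
  }
  if (!nodes[[n]]$op %in% TERMINAL_OPS) {
    abort_surgvqa("terminal op must be a query, exist or count",
                  "surgvqa_program_error")
  }
  structure(nodes, class = "surgvqa_program")
}

graph_object <- function(graph, id) graph$objects[[id]]

action_partners <- function(graph, id, verb = NULL) {
  ae <- graph$action_edges
  if (!nrow(ae)) return(character())
  if (!is.null(verb)) ae <- ae[ae$verb == verb, , drop = FALSE]
  c(ae$target_id[ae$instrument_id == id], ae$instrument_id[ae$target_id == id])
}

node_verbs <- function(graph, id) {
  ae <- graph$action_edges
  unique(c(ae$verb[ae$instrument_id == id], ae$verb[ae$target_id == id]))
}

#' Execute a functional program on a scene graph
#'
#' Evaluation is deterministic. Intermediate values are sets of object ids;
#' the terminal value is an answer token: an attribute for `query_*`,
#' "yes"/"no" for `exist`, a decimal string for `count`. Whenever a step has
#' no well-defined value (ambiguous `unique`, verb query on an actionless
#' node, or any input already invalid) the result is [QA_INVALID].
#'
#' @param prog a `surgvqa_program`.
#' @param graph a `surgvqa_graph`.
#' @return a single answer token, or `QA_INVALID`.
#' @export
execute_program <- function(prog, graph) {
  if (!inherits(prog, "surgvqa_program")) prog <- program(prog)
  vals <- vector("list", length(prog))
  all_ids <- sort(as.character(names(graph$objects) %||% character()))
  attr_of <- function(id, field) graph_object(graph, id)[[field]]
  filter_by <- function(ids, field, value) {
    ids[vapply(ids, function(i) identical(attr_of(i, field), value), logical(1))]
  }
  for (i in seq_along(prog)) {
    nd <- prog[[i]]
    ins <- lapply(nd$inputs, function(j) vals[[j]])
    if (any(vapply(ins, function(v) identical(v, QA_INVALID), logical(1)))) {
      vals[[i]] <- QA_INVALID
      next
    }
    # list-assignment guards against zero-length results collapsing the slot
    vals[i] <- list(switch(nd$op,
      scene = all_ids,
      filter_name     = filter_by(ins[[1]], "name", nd$arg),
      filter_color    = filter_by(ins[[1]], "color", nd$arg),
      filter_location = filter_by(ins[[1]], "location", nd$arg),
      filter_type     = filter_by(ins[[1]], "category", nd$arg),
      relate_spatial = {
        if (length(ins[[1]]) != 1) QA_INVALID else {
          se <- graph$spatial_edges
          sort(se$source[se$relation == nd$arg & se$target == ins[[1]]])
        }
      },
      relate_action = {
        verb <- if (is.list(nd$arg)) nd$arg$verb else nd$arg
        sort(unique(unlist(lapply(ins[[1]], action_partners,
                                  graph = graph, verb = verb))))
      },
      unique = if (length(ins[[1]]) == 1) ins[[1]] else QA_INVALID,
      query_name     = if (length(ins[[1]]) == 1) attr_of(ins[[1]], "name") else QA_INVALID,
      query_color    = if (length(ins[[1]]) == 1) attr_of(ins[[1]], "color") else QA_INVALID,
      query_location = if (length(ins[[1]]) == 1) attr_of(ins[[1]], "location") else QA_INVALID,
      query_type     = if (length(ins[[1]]) == 1) attr_of(ins[[1]], "category") else QA_INVALID,
      query_verb = {
        if (length(ins[[1]]) != 1) QA_INVALID else {
          v <- node_verbs(graph, ins[[1]])
          if (length(v) == 1) v else QA_INVALID
        }
      },
      exist = if (length(ins[[1]]) > 0) "yes" else "no",
      count = as.character(length(ins[[1]])),
      intersect = sort(intersect(ins[[1]], ins[[2]]))
    ))
  }
  vals[[length(prog)]]
}

#' Complexity class of a program
#'
#' Zero relate steps means the question reasons about zero reference
#' objects (`zero_hop`); one relate step means one reference object
#' (`one_hop`); two relate steps joined by a single `intersect` means two
#' reference objects constraining one queried object (`single_and`).
#'
#' @param prog a `surgvqa_program`.
#' @return one of "zero_hop", "one_hop", "single_and".
#' @export
tag_complexity <- function(prog) {
  if (!inherits(prog, "surgvqa_program")) prog <- program(prog)
  ops <- vapply(prog, function(n) n$op, character(1))
  n_rel <- sum(ops %in% RELATE_OPS)
  n_int <- sum(ops == "intersect")
  if (n_rel == 0 && n_int == 0) return("zero_hop")
  if (n_rel == 1 && n_int == 0) return("one_hop")
  if (n_rel == 2 && n_int == 1) return("single_and")
  abort_surgvqa("program shape outside the supported complexity classes",
                "surgvqa_complexity_error")
}

# Does a counting program count an anatomy class? Used by the degenerate
# filter: anatomies occur at most once per frame, so their counts are
# constant and leak the answer from the question text alone.
counts_anatomy <- function(prog, vocab = load_vocab()) {
  if (!inherits(prog, "surgvqa_program")) prog <- program(prog)
  n <- length(prog)
  if (prog[[n]]$op != "count") return(FALSE)
  for (nd in prog) {
    if (nd$op == "filter_name" && nd$arg %in% vocab$anatomies) return(TRUE)
    if (nd$op == "filter_type" && identical(nd$arg, "anatomy")) return(TRUE)
  }
  FALSE
}
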
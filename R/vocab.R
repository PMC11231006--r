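#' Load an object/relation vocabulary configuration
#'
#' The vocabulary fixes the closed world the whole pipeline operates in:
#' instrument and anatomy class names, the verbs action triplets may use,
#' the per-class colors attributed to scene-graph nodes, surgical phase
#' names and the 3x3 location-grid labels.
#'
#' @param path path to a YAML vocabulary file. Defaults to the vocabulary
#'   shipped with the package (the standard cholecystectomy setup).
#' @return a list of class `surgvqa_vocab` with elements `instruments`,
#'   `anatomies`, `verbs`, `colors` (named class -> color map), `phases`,
#'   `locations`, `relations` and `max_count`.
#' @export
#' @examples
#' v <- load_vocab()
#' v$anatomies
load_vocab <- function(path = NULL) {
  path <- path %||% system.file("extdata", "vocab.yaml", package = "surgvqa")
  raw <- yaml::read_yaml(path)
  need <- c("instruments", "anatomies", "verbs", "colors",
            "grid_rows", "grid_cols", "relations")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_surgvqa(paste("vocabulary file missing fields:",
                        paste(miss, collapse = ", ")), "surgvqa_vocab_error")
  }
  classes <- c(raw$instruments, raw$anatomies)
  if (anyDuplicated(classes)) {
    abort_surgvqa("a class name appears in both instrument and anatomy lists",
                  "surgvqa_vocab_error")
  }
  no_color <- setdiff(classes, names(raw$colors))
  if (length(no_color)) {
    abort_surgvqa(paste("classes without a configured color:",
                        paste(no_color, collapse = ", ")),
                  "surgvqa_vocab_error")
  }
  locations <- as.vector(t(outer(raw$grid_rows, raw$grid_cols, paste, sep = "-")))
  structure(list(
    instruments = raw$instruments,
    anatomies   = raw$anatomies,
    verbs       = raw$verbs,
    colors      = unlist(raw$colors),
    phases      = raw$phases %||% character(),
    grid_rows   = raw$grid_rows,
    grid_cols   = raw$grid_cols,
    locations   = locations,
    relations   = raw$relations,
    max_count   = raw$max_count %||% 6L
  ), class = "surgvqa_vocab")
}

vocab_category <- function(name, vocab) {
  if (name %in% vocab$instruments) return("instrument")
  if (name %in% vocab$anatomies) return("anatomy")
  abort_surgvqa(paste0("unknown class name: '", name, "'"),
                "surgvqa_vocab_error")
}

#' Closed answer vocabulary
#'
#' Every ground-truth answer emitted by the question engine is a member of
#' this set: object names, colors, grid locations, the two object types,
#' verbs, yes/no, and the decimal strings "0" .. `max_count`.
#'
#' @param vocab a `surgvqa_vocab`.
#' @return character vector of legal answer tokens.
#' @export
answer_vocabulary <- function(vocab = load_vocab()) {
  unique(c(vocab$instruments, vocab$anatomies,
           unname(vocab$colors), vocab$locations,
           c("instrument", "anatomy"), vocab$verbs,
           c("yes", "no"), as.character(0:vocab$max_count)))
}
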
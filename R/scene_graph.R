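# Scene graphs: attributed object nodes plus spatial and action edges for a
# single video frame. Coordinates are 0-based, origin top-left, x rightward,
# y downward; boxes are half-open [x1, x2) x [y1, y2) in continuous pixels.

#' Construct a validated bounding box
#'
#' @param x1,y1,x2,y2 box corners in pixels; origin top-left, half-open.
#' @param frame_dims optional `c(width, height)`; when given the box must lie
#'   inside the frame.
#' @return named numeric vector of class `surgvqa_bbox`.
#' @export
#' @examples
#' bbox(0, 0, 10, 10)
bbox <- function(x1, y1, x2, y2, frame_dims = NULL) {
  b <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  if (any(!is.finite(b))) {
    abort_surgvqa("bounding box coordinates must be finite",
                  "surgvqa_validation_error")
  }
  if (b["x2"] <= b["x1"] || b["y2"] <= b["y1"]) {
    abort_surgvqa("bounding box must satisfy x2 > x1 and y2 > y1",
                  "surgvqa_validation_error")
  }
  if (any(b < 0)) {
    abort_surgvqa("bounding box coordinates must be non-negative",
                  "surgvqa_validation_error")
  }
  if (!is.null(frame_dims)) {
    if (b["x2"] > frame_dims[1] || b["y2"] > frame_dims[2]) {
      abort_surgvqa("bounding box extends beyond the frame",
                    "surgvqa_validation_error")
    }
  }
  structure(b, class = "surgvqa_bbox")
}

as_bbox <- function(b, frame_dims = NULL) {
  if (inherits(b, "surgvqa_bbox")) return(b)
  bbox(b[[1]], b[[2]], b[[3]], b[[4]], frame_dims = frame_dims)
}

#' Centroid of a bounding box
#'
#' @param b a bounding box (`bbox()` or any length-4 x1,y1,x2,y2 vector).
#' @return `c(x, y)` in continuous pixel coordinates.
#' @export
#' @examples
#' centroid(bbox(2, 4, 6, 8))  # c(4, 6)
centroid <- function(b) {
  b <- as_bbox(b)
  c(x = unname((b["x1"] + b["x2"]) / 2), y = unname((b["y1"] + b["y2"]) / 2))
}

#' Assign a box to a cell of the 3x3 location grid
#'
#' The frame is partitioned into equal thirds along each axis; the cell
#' containing the box centroid is returned as a hyphenated token such as
#' "top-mid" or "bottom-right". Centroids lying exactly on an interior grid
#' line resolve to the lower-index cell (left/top wins), which keeps the
#' assignment deterministic.
#'
#' @param b a bounding box.
#' @param frame_dims `c(width, height)` in pixels.
#' @param vocab vocabulary supplying the grid row/column labels.
#' @return a location token.
#' @export
#' @examples
#' location_bin(bbox(40, 40, 60, 60), c(100, 100))  # "mid-mid"
location_bin <- function(b, frame_dims, vocab = load_vocab()) {
  ct <- centroid(b)
  w <- frame_dims[1]; h <- frame_dims[2]
  if (ct["x"] < 0 || ct["x"] > w || ct["y"] < 0 || ct["y"] > h) {
    abort_surgvqa("centroid lies outside the frame", "surgvqa_validation_error")
  }
  third_index <- function(coord, extent) {
    if (coord <= 0) return(1L)
    min(as.integer(ceiling(3 * coord / extent)), 3L)
  }
  row <- third_index(ct["y"], h)
  col <- third_index(ct["x"], w)
  paste(vocab$grid_rows[row], vocab$grid_cols[col], sep = "-")
}

#' Construct a scene object node
#'
#' @param object_id unique token within the frame.
#' @param name class label (must be in the vocabulary).
#' @param b bounding box.
#' @param frame_dims `c(width, height)`.
#' @param vocab vocabulary; supplies the category and the per-class color.
#' @return list of class `surgvqa_object`.
#' @export
scene_object <- function(object_id, name, b, frame_dims, vocab = load_vocab()) {
  b <- as_bbox(b, frame_dims)
  category <- vocab_category(name, vocab)
  structure(list(
    object_id = as.character(object_id),
    name = name,
    category = category,
    color = unname(vocab$colors[[name]]),
    bbox = b,
    location = location_bin(b, frame_dims, vocab)
  ), class = "surgvqa_object")
}

#' Pairwise spatial relations from centroid comparison
#'
#' For every ordered pair of distinct objects, emits `(a, "left of", b)` when
#' a's centroid x is strictly smaller than b's, and `(a, "above", b)` when
#' a's centroid y is strictly smaller; converses ("right of", "below") are
#' emitted symmetrically. Exact centroid ties on an axis produce no edge on
#' that axis.
#'
#' @param objects list of `surgvqa_object`.
#' @return data.frame with columns `source`, `relation`, `target`.
#' @export
spatial_relations <- function(objects) {
  empty <- data.frame(source = character(), relation = character(),
                      target = character(), stringsAsFactors = FALSE)
  n <- length(objects)
  if (n < 2) return(empty)
  ids <- vapply(objects, function(o) o$object_id, character(1))
  cx <- vapply(objects, function(o) centroid(o$bbox)["x"], numeric(1))
  cy <- vapply(objects, function(o) centroid(o$bbox)["y"], numeric(1))
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (cx[i] != cx[j]) {
        l <- if (cx[i] < cx[j]) c(i, j) else c(j, i)
        rows[[length(rows) + 1]] <-
          c(ids[l[1]], "left of", ids[l[2]])
        rows[[length(rows) + 1]] <-
          c(ids[l[2]], "right of", ids[l[1]])
      }
      if (cy[i] != cy[j]) {
        u <- if (cy[i] < cy[j]) c(i, j) else c(j, i)
        rows[[length(rows) + 1]] <-
          c(ids[u[1]], "above", ids[u[2]])
        rows[[length(rows) + 1]] <-
          c(ids[u[2]], "below", ids[u[1]])
      }
    }
  }
  if (!length(rows)) return(empty)
  m <- do.call(rbind, rows)
  out <- data.frame(source = m[, 1], relation = m[, 2], target = m[, 3],
                    stringsAsFactors = FALSE)
  out[order(out$source, out$relation, out$target), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Build an attributed scene graph for one frame
#'
#' Nodes carry name, category, per-class color, bounding box and grid
#' location; spatial edges come from centroid comparison and action edges
#' from <instrument, verb, target> triplets. Triplets whose endpoints cannot
#' be resolved to a detection in the frame are dropped with a warning; the
#' frame itself is kept. The build is a pure function of its inputs.
#'
#' @param detections data.frame with columns `class`, `x1`, `y1`, `x2`, `y2`
#'   (optionally `score`); one row per detected object in this frame.
#' @param triplets data.frame with columns `instrument_class`, `verb`,
#'   `target_class`; may be empty.
#' @param frame_dims `c(width, height)` in pixels.
#' @param vocab vocabulary config.
#' @param frame_id token identifying the frame.
#' @return list of class `surgvqa_graph` with `frame_id`, `frame_dims`,
#'   `objects`, `spatial_edges`, `action_edges`.
#' @export
build_scene_graph <- function(detections, triplets = NULL,
                              frame_dims, vocab = load_vocab(),
                              frame_id = "frame-0") {
  objects <- list()
  per_class_idx <- list()
  if (!is.null(detections) && nrow(detections)) {
    ord <- order(detections$class, detections$x1, detections$y1,
                 detections$x2, detections$y2)
    detections <- detections[ord, , drop = FALSE]
    for (i in seq_len(nrow(detections))) {
      cls <- as.character(detections$class[i])
      category <- vocab_category(cls, vocab)  # errors on unknown class
      k <- (per_class_idx[[cls]] %||% 0L) + 1L
      per_class_idx[[cls]] <- k
      if (category == "anatomy" && k > 1L) {
        abort_surgvqa(
          paste0("anatomy class '", cls, "' detected more than once in frame ",
                 frame_id), "surgvqa_validation_error")
      }
      oid <- paste0(cls, "-", k)
      objects[[oid]] <- scene_object(
        oid, cls,
        bbox(detections$x1[i], detections$y1[i],
             detections$x2[i], detections$y2[i], frame_dims),
        frame_dims, vocab)
    }
  }
  names_present <- vapply(objects, function(o) o$name, character(1))

  action_edges <- data.frame(instrument_id = character(), verb = character(),
                             target_id = character(), stringsAsFactors = FALSE)
  if (!is.null(triplets) && nrow(triplets)) {
    for (i in seq_len(nrow(triplets))) {
      icls <- as.character(triplets$instrument_class[i])
      tcls <- as.character(triplets$target_class[i])
      verb <- as.character(triplets$verb[i])
      if (!verb %in% vocab$verbs) {
        abort_surgvqa(paste0("unknown verb: '", verb, "'"),
                      "surgvqa_vocab_error")
      }
      inst <- names(objects)[names_present == icls]
      targ <- names(objects)[names_present == tcls]
      if (!length(inst) || !length(targ)) {
        warning(sprintf(
          "frame %s: triplet <%s, %s, %s> references an absent object; dropped",
          frame_id, icls, verb, tcls), call. = FALSE)
        next
      }
      if (vocab_category(icls, vocab) != "instrument" ||
          vocab_category(tcls, vocab) != "anatomy") {
        warning(sprintf(
          "frame %s: triplet <%s, %s, %s> has wrong endpoint categories; dropped",
          frame_id, icls, verb, tcls), call. = FALSE)
        next
      }
      # lowest-index instance carries the action (deterministic choice)
      action_edges <- rbind(action_edges, data.frame(
        instrument_id = sort(inst)[1], verb = verb, target_id = sort(targ)[1],
        stringsAsFactors = FALSE))
    }
    if (nrow(action_edges)) {
      action_edges <- unique(action_edges)
      action_edges <- action_edges[order(action_edges$instrument_id,
                                         action_edges$verb,
                                         action_edges$target_id), ,
                                   drop = FALSE]
      rownames(action_edges) <- NULL
    }
  }

  structure(list(
    frame_id = as.character(frame_id),
    frame_dims = as.numeric(frame_dims),
    objects = objects,
    spatial_edges = spatial_relations(unname(objects)),
    action_edges = action_edges
  ), class = "surgvqa_graph")
}

#' @export
print.surgvqa_graph <- function(x, ...) {
  cat(sprintf("<surgvqa_graph %s: %d objects, %d spatial edges, %d action edges>\n",
              x$frame_id, length(x$objects), nrow(x$spatial_edges),
              nrow(x$action_edges)))
  invisible(x)
}

# Internal: assert all graph invariants; used by io validation and fixtures.
validate_graph <- function(g, vocab = load_vocab()) {
  ids <- vapply(g$objects, function(o) o$object_id, character(1))
  if (anyDuplicated(ids)) {
    abort_surgvqa("duplicate object ids in graph", "surgvqa_validation_error")
  }
  for (o in g$objects) {
    cat_ok <- vocab_category(o$name, vocab) == o$category
    col_ok <- identical(o$color, unname(vocab$colors[[o$name]]))
    loc_ok <- identical(o$location, location_bin(o$bbox, g$frame_dims, vocab))
    if (!cat_ok || !col_ok || !loc_ok) {
      abort_surgvqa(paste0("object '", o$object_id, "' violates attribute invariants"),
                    "surgvqa_validation_error")
    }
  }
  edge_ids <- unique(c(g$spatial_edges$source, g$spatial_edges$target,
                       g$action_edges$instrument_id, g$action_edges$target_id))
  dangling <- setdiff(edge_ids, ids)
  if (length(dangling)) {
    abort_surgvqa(paste("dangling edge endpoints:",
                        paste(dangling, collapse = ", ")),
                  "surgvqa_validation_error")
  }
  invisible(TRUE)
}
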
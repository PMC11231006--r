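# Independent brute-force oracles and small graph builders used across the
# suite. The oracles deliberately re-derive everything from first principles
# (centroids from box corners, relations by direct comparison, programs by
# naive set enumeration) so they share no code path with the implementation.

VOCAB <- load_vocab()

# Build a graph from a compact spec: data.frame(class, x1, y1, x2, y2),
# optional triplet.
make_graph <- function(det, tri = NULL, dims = c(100, 100), frame_id = "f1") {
  build_scene_graph(det, tri, dims, VOCAB, frame_id = frame_id)
}

# crafted 3-node worked instance: yellow gallbladder at frame centre, hook
# strictly left of it, liver above it
crafted_graph <- function() {
  det <- data.frame(
    class = c("gallbladder", "hook", "liver"),
    x1 = c(40, 5, 42), y1 = c(40, 42, 2),
    x2 = c(60, 25, 62), y2 = c(60, 58, 22))
  make_graph(det, data.frame(frame_id = "f1", instrument_class = "hook",
                             verb = "retract", target_class = "gallbladder"))
}

random_graph <- function(seed, n_max = 6L, dims = c(100, 100)) {
  surgvqa:::with_seed(seed, {
    n_inst <- sample(0:3, 1)
    n_anat <- sample(max(1 - n_inst, 0):3, 1)
    cls <- c(sample(VOCAB$instruments, n_inst, replace = TRUE),
             sample(VOCAB$anatomies, min(n_anat, 3)))
    if (!length(cls)) cls <- "liver"
    cls <- utils::head(cls, n_max)
    boxes <- t(vapply(cls, function(x) {
      w <- runif(1, 5, 40); h <- runif(1, 5, 40)
      x1 <- runif(1, 0, dims[1] - w); y1 <- runif(1, 0, dims[2] - h)
      c(x1, y1, x1 + w, y1 + h)
    }, numeric(4)))
    det <- data.frame(class = cls, x1 = boxes[, 1], y1 = boxes[, 2],
                      x2 = boxes[, 3], y2 = boxes[, 4])
    tri <- NULL
    inst <- intersect(cls, VOCAB$instruments)
    anat <- intersect(cls, VOCAB$anatomies)
    if (length(inst) && length(anat) && runif(1) < 0.8) {
      tri <- data.frame(frame_id = "f1",
                        instrument_class = sample(inst, 1),
                        verb = sample(VOCAB$verbs, 1),
                        target_class = sample(anat, 1))
    }
    make_graph(det, tri)
  })
}

# -- oracle: location bin by explicit point-in-rectangle over the 9 cells ----
oracle_location_bin <- function(cx, cy, dims) {
  labels <- c("left", "mid", "right")
  rows <- c("top", "mid", "bottom")
  w3 <- dims[1] / 3; h3 <- dims[2] / 3
  for (r in 1:3) {
    for (cc in 1:3) {
      # cell (r, cc): x in ((cc-1)*w3, cc*w3], boundary to the lower cell;
      # the first cell additionally includes its left/top edge
      x_lo <- (cc - 1) * w3; x_hi <- cc * w3
      y_lo <- (r - 1) * h3; y_hi <- r * h3
      in_x <- if (cc == 1) cx >= x_lo && cx <= x_hi else cx > x_lo && cx <= x_hi
      in_y <- if (r == 1) cy >= y_lo && cy <= y_hi else cy > y_lo && cy <= y_hi
      if (in_x && in_y) return(paste(rows[r], labels[cc], sep = "-"))
    }
  }
  NA_character_
}

# -- oracle: spatial relations by direct pairwise comparison -----------------
oracle_spatial <- function(graph) {
  objs <- graph$objects
  ids <- names(objs)
  out <- character()
  for (a in ids) {
    for (b in ids) {
      if (a == b) next
      ca <- c((objs[[a]]$bbox[1] + objs[[a]]$bbox[3]) / 2,
              (objs[[a]]$bbox[2] + objs[[a]]$bbox[4]) / 2)
      cb <- c((objs[[b]]$bbox[1] + objs[[b]]$bbox[3]) / 2,
              (objs[[b]]$bbox[2] + objs[[b]]$bbox[4]) / 2)
      if (ca[1] < cb[1]) out <- c(out, paste(a, "left of", b, sep = "|"))
      if (ca[1] > cb[1]) out <- c(out, paste(a, "right of", b, sep = "|"))
      if (ca[2] < cb[2]) out <- c(out, paste(a, "above", b, sep = "|"))
      if (ca[2] > cb[2]) out <- c(out, paste(a, "below", b, sep = "|"))
    }
  }
  sort(out)
}

# -- oracle: naive functional-program evaluator ------------------------------
# Works on an attribute table; relations recomputed from box corners; no code
# shared with execute_program.
oracle_execute <- function(prog, graph) {
  objs <- graph$objects
  ids <- names(objs)
  tab <- data.frame(
    id = ids,
    name = vapply(objs, function(o) o$name, character(1)),
    category = vapply(objs, function(o) o$category, character(1)),
    color = vapply(objs, function(o) o$color, character(1)),
    location = vapply(objs, function(o) o$location, character(1)),
    cx = vapply(objs, function(o) (o$bbox[1] + o$bbox[3]) / 2, numeric(1)),
    cy = vapply(objs, function(o) (o$bbox[2] + o$bbox[4]) / 2, numeric(1)),
    stringsAsFactors = FALSE)
  INV <- "__INVALID__"
  vals <- list()
  for (i in seq_along(prog)) {
    nd <- prog[[i]]
    ins <- lapply(nd$inputs, function(j) vals[[j]])
    if (any(vapply(ins, identical, logical(1), INV))) {
      vals[[i]] <- INV
      next
    }
    res <- switch(nd$op,
      scene = sort(tab$id),
      filter_name = ins[[1]][tab$name[match(ins[[1]], tab$id)] == nd$arg],
      filter_color = ins[[1]][tab$color[match(ins[[1]], tab$id)] == nd$arg],
      filter_location = ins[[1]][tab$location[match(ins[[1]], tab$id)] == nd$arg],
      filter_type = ins[[1]][tab$category[match(ins[[1]], tab$id)] == nd$arg],
      relate_spatial = {
        if (length(ins[[1]]) != 1) INV else {
          ref <- match(ins[[1]], tab$id)
          hit <- vapply(seq_len(nrow(tab)), function(k) {
            if (k == ref) return(FALSE)
            switch(nd$arg,
              "left of" = tab$cx[k] < tab$cx[ref],
              "right of" = tab$cx[k] > tab$cx[ref],
              "above" = tab$cy[k] < tab$cy[ref],
              "below" = tab$cy[k] > tab$cy[ref])
          }, logical(1))
          sort(tab$id[hit])
        }
      },
      relate_action = {
        verb <- if (is.list(nd$arg)) nd$arg$verb else nd$arg
        ae <- graph$action_edges
        if (!is.null(verb)) ae <- ae[ae$verb == verb, , drop = FALSE]
        partners <- character()
        for (x in ins[[1]]) {
          partners <- c(partners, ae$target_id[ae$instrument_id == x],
                        ae$instrument_id[ae$target_id == x])
        }
        sort(unique(partners))
      },
      unique = if (length(ins[[1]]) == 1) ins[[1]] else INV,
      query_name = if (length(ins[[1]]) == 1) tab$name[match(ins[[1]], tab$id)] else INV,
      query_color = if (length(ins[[1]]) == 1) tab$color[match(ins[[1]], tab$id)] else INV,
      query_location = if (length(ins[[1]]) == 1) tab$location[match(ins[[1]], tab$id)] else INV,
      query_type = if (length(ins[[1]]) == 1) tab$category[match(ins[[1]], tab$id)] else INV,
      query_verb = {
        if (length(ins[[1]]) != 1) INV else {
          ae <- graph$action_edges
          vb <- unique(c(ae$verb[ae$instrument_id == ins[[1]]],
                         ae$verb[ae$target_id == ins[[1]]]))
          if (length(vb) == 1) vb else INV
        }
      },
      exist = if (length(ins[[1]])) "yes" else "no",
      count = as.character(length(ins[[1]])),
      intersect = sort(ins[[1]][ins[[1]] %in% ins[[2]]])
    )
    vals[[i]] <- res
  }
  vals[[length(prog)]]
}

# Random well-formed program against a graph's attested / vocabulary values.
random_program <- function(graph, seed) {
  surgvqa:::with_seed(seed, {
    rand_filter <- function() {
      kind <- sample(c("name", "color", "location", "type"), 1)
      arg <- switch(kind,
        name = sample(c(VOCAB$instruments, VOCAB$anatomies), 1),
        color = sample(unname(VOCAB$colors), 1),
        location = sample(VOCAB$locations, 1),
        type = sample(c("instrument", "anatomy"), 1))
      pnode(paste0("filter_", kind), arg)
    }
    ref_chain <- function() {
      c(list(pnode("scene")),
        lapply(seq_len(sample(0:2, 1)), function(i) rand_filter()))
    }
    relate_node <- function() {
      if (runif(1) < 0.8) {
        pnode("relate_spatial", sample(VOCAB$relations, 1))
      } else {
        pnode("relate_action",
              if (runif(1) < 0.5) sample(VOCAB$verbs, 1) else NULL)
      }
    }
    terminal <- function(shape) {
      which_t <- sample(c("exist", "count", "query"), 1)
      if (which_t == "query") {
        c(list(pnode("unique")),
          list(pnode(sample(c("query_name", "query_color", "query_location",
                              "query_type", "query_verb"), 1))))
      } else {
        list(pnode(which_t))
      }
    }
    shape <- sample(c("zero", "one", "and"), 1)
    nodes <- if (shape == "zero") {
      c(ref_chain(), terminal())
    } else if (shape == "one") {
      c(ref_chain(), list(pnode("unique")), list(relate_node()),
        lapply(seq_len(sample(0:1, 1)), function(i) rand_filter()),
        terminal())
    } else {
      a <- c(ref_chain(), list(pnode("unique")), list(relate_node()))
      b <- c(ref_chain(), list(pnode("unique")), list(relate_node()))
      la <- length(a)
      # rewire chain b to start after a, then intersect the two ends
      b_wired <- lapply(seq_along(b), function(k) {
        nd <- b[[k]]
        nd$inputs <- if (nd$op == "scene") integer() else la + k - 1L
        nd
      })
      c(a, b_wired,
        list(pnode("intersect", inputs = c(la, la + length(b)))),
        terminal())
    }
    program(nodes)
  })
}

# -- oracle: attention and bilinear pooling by scalar loops ------------------
oracle_attention <- function(Q, K, V, mask = NULL) {
  n <- nrow(Q); m <- nrow(K)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    s <- numeric(m)
    for (j in seq_len(m)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(K))
    if (!is.null(mask)) s[!mask] <- -Inf
    if (all(!is.finite(s))) next
    e <- exp(s - max(s[is.finite(s)]))
    e[!is.finite(e)] <- 0
    W[i, ] <- e / sum(e)
  }
  list(output = W %*% V, weights = W)
}

oracle_bilinear_point <- function(fm, x, y) {
  H <- nrow(fm); W <- ncol(fm)
  u <- min(max(x - 0.5, 0), W - 1)
  v <- min(max(y - 0.5, 0), H - 1)
  j0 <- floor(u); i0 <- floor(v)
  j1 <- min(j0 + 1, W - 1); i1 <- min(i0 + 1, H - 1)
  fu <- u - j0; fv <- v - i0
  fm[i0 + 1, j0 + 1] * (1 - fu) * (1 - fv) +
    fm[i0 + 1, j1 + 1] * fu * (1 - fv) +
    fm[i1 + 1, j0 + 1] * (1 - fu) * fv +
    fm[i1 + 1, j1 + 1] * fu * fv
}

oracle_roi <- function(fm, box, S, sr = 2) {
  out <- matrix(0, S, S)
  cw <- (box[3] - box[1]) / S
  ch <- (box[4] - box[2]) / S
  for (gy in seq_len(S)) {
    for (gx in seq_len(S)) {
      acc <- 0
      for (sy in seq_len(sr)) {
        for (sx in seq_len(sr)) {
          acc <- acc + oracle_bilinear_point(
            fm,
            box[1] + (gx - 1) * cw + (sx - 0.5) / sr * cw,
            box[2] + (gy - 1) * ch + (sy - 0.5) / sr * ch)
        }
      }
      out[gy, gx] <- acc / sr^2
    }
  }
  out
}
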
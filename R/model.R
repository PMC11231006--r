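# Desk-scale reference implementation of the scene-aware VQA network: a
# scene encoder projecting (class one-hot | normalized box) node features, a
# scene-embedded interaction module (SIM) of stacked cross-attention (scene
# queries attending to text) and self-attention layers, RoIAlign pooling for
# object-wise visual features, and a self-attention fusion transformer over
# the concatenated refined-scene / visual / text sequence with masked
# average pooling and a linear answer head.

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K^T / sqrt(d_k)) V`. Masked keys are excluded from
#' the softmax; rows whose keys are all masked produce a zero output row
#' (reported via a message).
#'
#' @param Q,K,V query/key/value matrices; `K` and `V` share row count, `Q`
#'   and `K` share column count (d_k).
#' @param mask logical vector over keys (TRUE = attend); NULL for none.
#' @return list with `output` (nrow(Q) x ncol(V)) and `weights`
#'   (nrow(Q) x nrow(K); each row sums to 1 over unmasked keys, or is all
#'   zero).
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (nrow(K) != nrow(V)) {
    abort_surgvqa("K and V must have equal sequence length",
                  "surgvqa_shape_error")
  }
  if (ncol(Q) != ncol(K)) {
    abort_surgvqa("Q and K must share the key dimension",
                  "surgvqa_shape_error")
  }
  d_k <- ncol(K)
  scores <- Q %*% t(K) / sqrt(d_k)
  if (!is.null(mask)) scores[, !mask] <- -Inf
  if (!is.null(mask) && !any(mask) && nrow(Q) > 0) {
    message("scaled_dot_attention: all keys masked; emitting zero rows")
  }
  w <- matrix(0, nrow(scores), ncol(scores))
  if (nrow(scores) > 0) {
    mx <- apply(scores, 1, max)
    mx[!is.finite(mx)] <- 0
    e <- exp(scores - mx)
    e[!is.finite(e)] <- 0
    z <- rowSums(e)
    w <- e / ifelse(z > 0, z, 1)
  }
  list(output = w %*% V, weights = w)
}

#' RoIAlign pooling
#'
#' Divides `box` into `output_size` x `output_size` equal cells, samples each
#' cell at `sampling_ratio`^2 regularly spaced sub-points by bilinear
#' interpolation of the four neighbouring grid values (grid value (i, j)
#' sits at continuous coordinate (j - 0.5, i - 0.5); out-of-range points
#' clamp to the border), and averages the sub-points per cell.
#'
#' @param feature_map array `c(channels, height, width)`, or a plain
#'   height x width matrix treated as one channel.
#' @param box `c(x1, y1, x2, y2)` in feature-map coordinates; must have
#'   positive area and lie within the map extent.
#' @param output_size pooled grid side length.
#' @param sampling_ratio sub-points per cell side (default 2).
#' @return array `c(channels, output_size, output_size)`.
#' @export
roi_align <- function(feature_map, box, output_size, sampling_ratio = 2L) {
  if (is.matrix(feature_map)) {
    feature_map <- array(feature_map, c(1, nrow(feature_map), ncol(feature_map)))
  }
  ch <- dim(feature_map)[1]; H <- dim(feature_map)[2]; W <- dim(feature_map)[3]
  x1 <- box[[1]]; y1 <- box[[2]]; x2 <- box[[3]]; y2 <- box[[4]]
  if (x2 <= x1 || y2 <= y1) {
    abort_surgvqa("degenerate (zero-area) box", "surgvqa_validation_error")
  }
  if (x1 < 0 || y1 < 0 || x2 > W || y2 > H) {
    abort_surgvqa("box outside the feature-map extent",
                  "surgvqa_validation_error")
  }
  bilinear <- function(c_idx, x, y) {
    u <- min(max(x - 0.5, 0), W - 1)
    v <- min(max(y - 0.5, 0), H - 1)
    j0 <- floor(u); i0 <- floor(v)
    j1 <- min(j0 + 1, W - 1); i1 <- min(i0 + 1, H - 1)
    fu <- u - j0; fv <- v - i0
    f <- feature_map[c_idx, , ]
    f[i0 + 1, j0 + 1] * (1 - fu) * (1 - fv) +
      f[i0 + 1, j1 + 1] * fu * (1 - fv) +
      f[i1 + 1, j0 + 1] * (1 - fu) * fv +
      f[i1 + 1, j1 + 1] * fu * fv
  }
  out <- array(0, c(ch, output_size, output_size))
  cw <- (x2 - x1) / output_size
  chh <- (y2 - y1) / output_size
  sr <- sampling_ratio
  for (c_idx in seq_len(ch)) {
    for (gy in seq_len(output_size)) {
      for (gx in seq_len(output_size)) {
        acc <- 0
        for (sy in seq_len(sr)) {
          for (sx in seq_len(sr)) {
            px <- x1 + (gx - 1) * cw + (sx - 0.5) / sr * cw
            py <- y1 + (gy - 1) * chh + (sy - 0.5) / sr * chh
            acc <- acc + bilinear(c_idx, px, py)
          }
        }
        out[c_idx, gy, gx] <- acc / sr^2
      }
    }
  }
  out
}

#' Raw scene-node features
#'
#' Per object: the class one-hot (over instruments then anatomies, in
#' vocabulary order) concatenated with the box corners normalized to [0, 1]
#' by the frame dimensions — width `n_classes + 4` before any projection.
#'
#' @param objects list of `surgvqa_object`.
#' @param frame_dims `c(width, height)`.
#' @param vocab vocabulary config.
#' @return N x (n_classes + 4) matrix, rows named by object id.
#' @export
scene_features <- function(objects, frame_dims, vocab = load_vocab()) {
  classes <- c(vocab$instruments, vocab$anatomies)
  n <- length(objects)
  out <- matrix(0, n, length(classes) + 4)
  colnames(out) <- c(classes, "x1", "y1", "x2", "y2")
  rn <- character(n)
  for (i in seq_len(n)) {
    o <- objects[[i]]
    k <- match(o$name, classes)
    if (is.na(k)) {
      abort_surgvqa(paste0("unknown class: '", o$name, "'"),
                    "surgvqa_vocab_error")
    }
    out[i, k] <- 1
    out[i, length(classes) + 1:4] <-
      as.numeric(o$bbox) / c(frame_dims[1], frame_dims[2],
                             frame_dims[1], frame_dims[2])
    rn[i] <- o$object_id
  }
  rownames(out) <- rn
  out
}

#' Deterministic hash-based visual feature provider
#'
#' Stands behind the same interface as a backbone + RoIAlign path: given
#' object names (and an optional per-object texture token), produces a
#' deterministic feature row per object — a pseudo-random class signature
#' plus a strong texture signal in a dedicated block of channels.
#'
#' @param names character vector of object class names.
#' @param textures optional character vector (same length) of texture
#'   tokens; each texture adds a fixed strong pseudo-random pattern
#'   (distinct tokens give near-orthogonal, linearly separable patterns).
#' @param dim feature width (default 16).
#' @return N x dim matrix.
#' @export
visual_provider_hash <- function(names, textures = NULL, dim = 16L) {
  n <- length(names)
  out <- matrix(0, n, dim)
  for (i in seq_len(n)) {
    base <- with_seed(string_hash(paste0("vis:", names[i])) %% 100000L,
                      stats::rnorm(dim, 0, 0.5))
    row <- base
    if (!is.null(textures)) {
      sig <- with_seed(string_hash(paste0("tex:", textures[i])) %% 100000L,
                       sample(c(-2, 2), dim, replace = TRUE))
      row <- row + sig
    }
    out[i, ] <- row
  }
  out
}

# ---- model construction ----------------------------------------------------

#' Configuration for the desk-scale VQA model
#'
#' @param d model (embedding) dimension; default 64 at toy scale.
#' @param ff_mult feed-forward width multiplier.
#' @param sim_layers number of SIM interaction layers (default 2).
#' @param fusion_layers number of fusion transformer layers (default 1).
#' @param visual_dim width of incoming visual features.
#' @param use_sim include the scene branch (scene encoder + SIM) in the
#'   fusion sequence; when FALSE the model sees only visual and text
#'   streams, mirroring the no-scene-knowledge ablation.
#' @param use_visual include object-wise visual embeddings in the fusion
#'   sequence (ablation knob).
#' @param text_vocab character vector of question tokens.
#' @param answer_vocab character vector: the predefined answer set.
#' @param n_scene_features width of raw scene-node features
#'   (n_classes + 4).
#' @return config list.
#' @export
vqa_config <- function(d = 64L, ff_mult = 2L, sim_layers = 2L,
                       fusion_layers = 1L, visual_dim = 16L,
                       use_sim = TRUE, use_visual = TRUE,
                       text_vocab, answer_vocab, n_scene_features) {
  list(d = d, ff_mult = ff_mult, sim_layers = sim_layers,
       fusion_layers = fusion_layers, visual_dim = visual_dim,
       use_sim = use_sim, use_visual = use_visual,
       text_vocab = text_vocab, answer_vocab = answer_vocab,
       n_scene_features = n_scene_features)
}

new_linear <- function(n_in, n_out, sd = 0.08) {
  ad_param(matrix(stats::rnorm(n_in * n_out, 0, sd), n_in, n_out))
}
new_bias <- function(n_out) ad_param(matrix(0, 1, n_out))
new_ln <- function(d) list(g = ad_param(matrix(1, 1, d)),
                           b = ad_param(matrix(0, 1, d)))

new_attention_params <- function(d) {
  list(Wq = new_linear(d, d), Wk = new_linear(d, d),
       Wv = new_linear(d, d), Wo = new_linear(d, d))
}

new_block <- function(d, ff_mult, cross = FALSE) {
  b <- list(self = new_attention_params(d),
            ff_W1 = new_linear(d, d * ff_mult), ff_b1 = new_bias(d * ff_mult),
            ff_W2 = new_linear(d * ff_mult, d), ff_b2 = new_bias(d),
            ln_att = new_ln(d), ln_ff = new_ln(d))
  if (cross) {
    b$cross <- new_attention_params(d)
    b$ln_cross <- new_ln(d)
  }
  b
}

#' Initialize a VQA model with random weights
#'
#' Single-head attention throughout; residual connections and layer
#' normalization wrap every attention and feed-forward sub-layer.
#'
#' @param config from [vqa_config()].
#' @param seed integer seed for weight initialization.
#' @return list of class `surgvqa_model`.
#' @export
vqa_model <- function(config, seed = 1L) {
  with_seed(seed, {
    d <- config$d
    m <- list(config = config)
    m$tok_emb <- new_linear(length(config$text_vocab), d, sd = 0.3)
    m$scene_W <- new_linear(config$n_scene_features, d)
    m$scene_b <- new_bias(d)
    m$vis_W <- new_linear(config$visual_dim, d)
    m$vis_b <- new_bias(d)
    m$sim <- lapply(seq_len(config$sim_layers), function(i) {
      new_block(d, config$ff_mult, cross = TRUE)
    })
    m$fusion <- lapply(seq_len(config$fusion_layers), function(i) {
      new_block(d, config$ff_mult)
    })
    m$cls_W <- new_linear(d, length(config$answer_vocab))
    m$cls_b <- new_bias(length(config$answer_vocab))
    structure(m, class = "surgvqa_model")
  })
}

model_params <- function(m) {
  flat <- function(x) {
    if (ad_is_node(x)) return(list(x))
    if (is.list(x)) return(unlist(lapply(x, flat), recursive = FALSE))
    list()
  }
  flat(m[setdiff(names(m), "config")])
}

# attention sub-layer on ad nodes; single head
att_apply <- function(p, Q, KV, key_mask = NULL) {
  q <- ad_matmul(Q, p$Wq)
  k <- ad_matmul(KV, p$Wk)
  v <- ad_matmul(KV, p$Wv)
  scores <- ad_scale(ad_matmul_t(q, k), 1 / sqrt(ncol(q$val)))
  w <- ad_softmax_rows(scores, key_mask)
  ad_matmul(ad_matmul(w, v), p$Wo)
}

ff_apply <- function(b, X) {
  h <- ad_relu(ad_add_rowvec(ad_matmul(X, b$ff_W1), b$ff_b1))
  ad_add_rowvec(ad_matmul(h, b$ff_W2), b$ff_b2)
}

res_ln <- function(ln, X, sub) ad_layernorm(ad_add(X, sub), ln$g, ln$b)

sim_apply <- function(m, S, T, scene_mask = NULL, text_mask = NULL) {
  for (b in m$sim) {
    S <- res_ln(b$ln_cross, S, att_apply(b$cross, S, T, text_mask))
    S <- res_ln(b$ln_att, S, att_apply(b$self, S, S, scene_mask))
    S <- res_ln(b$ln_ff, S, ff_apply(b, S))
  }
  S
}

# Full forward pass on one sample (ad nodes). sample fields: tokens (int
# indices into text_vocab), scene (N x n_scene_features), visual
# (N x visual_dim), optional scene_mask / text_mask logical vectors.
forward_sample <- function(m, sample) {
  cfg <- m$config
  Tn <- ad_embed(m$tok_emb, sample$tokens)
  text_mask <- sample$text_mask %||% rep(TRUE, length(sample$tokens))
  N <- nrow(sample$scene)
  scene_mask <- sample$scene_mask %||% rep(TRUE, N)
  seqs <- list()
  masks <- list()
  if (N > 0) {
    if (cfg$use_sim) {
      S <- ad_add_rowvec(ad_matmul(ad_const(sample$scene), m$scene_W),
                         m$scene_b)
      S <- sim_apply(m, S, Tn, scene_mask, text_mask)
      seqs <- c(seqs, list(S)); masks <- c(masks, list(scene_mask))
    }
    if (cfg$use_visual) {
      V <- ad_add_rowvec(ad_matmul(ad_const(sample$visual), m$vis_W), m$vis_b)
      seqs <- c(seqs, list(V)); masks <- c(masks, list(scene_mask))
    }
  }
  seqs <- c(seqs, list(Tn)); masks <- c(masks, list(text_mask))
  X <- ad_rbind(seqs)
  keep <- unlist(masks)
  for (b in m$fusion) {
    X <- res_ln(b$ln_att, X, att_apply(b$self, X, X, keep))
    X <- res_ln(b$ln_ff, X, ff_apply(b, X))
  }
  pooled <- ad_mean_rows(X, keep)
  ad_add_rowvec(ad_matmul(pooled, m$cls_W), m$cls_b)
}

#' Scene encoder: project raw node features to model dimension
#'
#' @param model a `surgvqa_model`.
#' @param objects list of `surgvqa_object` (order preserved).
#' @param frame_dims `c(width, height)`.
#' @param vocab vocabulary config.
#' @return N x d matrix of scene embeddings (N = 0 gives a 0 x d matrix).
#' @export
scene_encode <- function(model, objects, frame_dims, vocab = load_vocab()) {
  if (!length(objects)) return(matrix(0, 0, model$config$d))
  feats <- scene_features(objects, frame_dims, vocab)
  sweep(feats %*% model$scene_W$val, 2, as.numeric(model$scene_b$val), "+")
}

#' Scene-embedded interaction module forward pass
#'
#' Each interaction layer applies cross-attention with the scene sequence as
#' query and the text sequence as key/value, then self-attention over the
#' scene sequence, then a feed-forward sub-layer; residual connections and
#' layer normalization wrap each sub-layer. Scene nodes carry no positional
#' encoding, so the module is permutation-equivariant in object order.
#'
#' @param model a `surgvqa_model`.
#' @param S N x d scene embeddings.
#' @param T_emb K x d text embeddings.
#' @param scene_mask,text_mask logical masks (TRUE = real position).
#' @return N x d refined scene embeddings.
#' @export
sim_forward <- function(model, S, T_emb, scene_mask = NULL, text_mask = NULL) {
  if (nrow(S) == 0) return(S)
  if (ncol(S) != model$config$d || ncol(T_emb) != model$config$d) {
    abort_surgvqa("embedding dimension mismatch", "surgvqa_shape_error")
  }
  sim_apply(model, ad_const(S), ad_const(T_emb), scene_mask, text_mask)$val
}

#' Fusion transformer and answer head
#'
#' Concatenates refined scene, visual and text sequences along the sequence
#' axis, applies the self-attention fusion layer(s), masked-average-pools
#' over real positions and maps to answer logits.
#'
#' @param model a `surgvqa_model`.
#' @param S_r N x d refined scene embeddings (may have 0 rows).
#' @param V N x d visual embeddings (same row count as `S_r`; ignored when
#'   the model was configured without the visual stream).
#' @param T_emb K x d text embeddings.
#' @param scene_mask,text_mask logical masks.
#' @return named numeric vector of answer logits.
#' @export
fuse_and_classify <- function(model, S_r, V, T_emb,
                              scene_mask = NULL, text_mask = NULL) {
  cfg <- model$config
  N <- nrow(S_r)
  scene_mask <- scene_mask %||% rep(TRUE, N)
  text_mask <- text_mask %||% rep(TRUE, nrow(T_emb))
  seqs <- list(); masks <- list()
  if (N > 0) {
    seqs <- c(seqs, list(ad_const(S_r))); masks <- c(masks, list(scene_mask))
    if (cfg$use_visual) {
      seqs <- c(seqs, list(ad_const(V))); masks <- c(masks, list(scene_mask))
    }
  }
  seqs <- c(seqs, list(ad_const(T_emb))); masks <- c(masks, list(text_mask))
  X <- ad_rbind(seqs)
  keep <- unlist(masks)
  if (!any(keep)) abort_surgvqa("empty total sequence", "surgvqa_shape_error")
  for (b in model$fusion) {
    X <- res_ln(b$ln_att, X, att_apply(b$self, X, X, keep))
    X <- res_ln(b$ln_ff, X, ff_apply(b, X))
  }
  pooled <- ad_mean_rows(X, keep)
  logits <- ad_add_rowvec(ad_matmul(pooled, model$cls_W), model$cls_b)
  stats::setNames(as.numeric(logits$val), cfg$answer_vocab)
}

#' Predict answers for a list of samples
#'
#' @param model a `surgvqa_model`.
#' @param samples list of samples (`tokens`, `scene`, `visual`).
#' @return character vector of predicted answer tokens.
#' @export
vqa_predict <- function(model, samples) {
  vapply(samples, function(s) {
    lg <- forward_sample(model, s)$val
    model$config$answer_vocab[which.max(lg)]
  }, character(1))
}

model_accuracy <- function(model, samples) {
  truth <- vapply(samples, function(s) s$answer, character(1))
  mean(vqa_predict(model, samples) == truth)
}

#' Train the model on a synthetic dataset
#'
#' Full-batch Adam minimizing cross-entropy over the answer set;
#' seed-deterministic. Records train (and optional validation) accuracy per
#' epoch and aborts with diagnostics if the loss turns non-finite. Training
#' stops early once `target_acc` is reached on the training split.
#'
#' @param model a `surgvqa_model` (updated in place: parameters are
#'   reference objects).
#' @param train list of samples with an `answer` field.
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param val optional validation sample list.
#' @param target_acc optional early-stop train accuracy.
#' @param seed integer seed (reserved for stochastic extensions; the loop
#'   itself is deterministic).
#' @param verbose print per-epoch progress.
#' @return list with `model`, `trace` (data.frame epoch, loss, train_acc,
#'   val_acc).
#' @export
toy_train <- function(model, train, epochs = 200L, lr = 3e-3, val = NULL,
                      target_acc = NULL, seed = 1L, verbose = FALSE) {
  params <- model_params(model)
  answers <- vapply(train, function(s) s$answer, character(1))
  tidx <- match(answers, model$config$answer_vocab)
  if (anyNA(tidx)) {
    abort_surgvqa("training answer outside the answer vocabulary",
                  "surgvqa_config_error")
  }
  trace <- data.frame(epoch = integer(), loss = numeric(),
                      train_acc = numeric(), val_acc = numeric())
  step <- 0L
  for (ep in seq_len(epochs)) {
    ad_begin()
    losses <- vector("list", length(train))
    correct <- 0L
    for (i in seq_along(train)) {
      logits <- forward_sample(model, train[[i]])
      if (which.max(logits$val) == tidx[i]) correct <- correct + 1L
      losses[[i]] <- ad_ce_loss(logits, tidx[i])
    }
    loss <- ad_scale(ad_sum_nodes(losses), 1 / length(train))
    if (!is.finite(loss$val[1])) {
      ad_end()
      abort_surgvqa(sprintf("training diverged at epoch %d (loss %g)",
                            ep, loss$val[1]), "surgvqa_training_error")
    }
    ad_zero_grads(params)
    ad_backward(loss)
    step <- step + 1L
    adam_step(params, lr, step)
    ad_end()
    tr_acc <- correct / length(train)
    va_acc <- if (is.null(val)) NA_real_ else model_accuracy(model, val)
    trace <- rbind(trace, data.frame(epoch = ep, loss = loss$val[1],
                                     train_acc = tr_acc, val_acc = va_acc))
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  train %.3f  val %s\n", ep,
                  loss$val[1], tr_acc,
                  if (is.na(va_acc)) "-" else sprintf("%.3f", va_acc)))
    }
    if (!is.null(target_acc) && tr_acc >= target_acc) break
  }
  list(model = model, trace = trace)
}

#' Build a deterministic toy VQA dataset for capacity and ablation checks
#'
#' Each sample holds a small synthetic scene (one instrument, two
#' anatomies) and one question from three families that tie the answer to
#' one input stream each: "what is the location of the instrument?" is
#' answerable only from the scene branch (the 3x3 bin is a function of the
#' box coordinates, which neither the text nor the hash-based visual
#' features contain; instrument centroids stay well inside their bin so the
#' mapping is cleanly learnable); "what is the texture of the instrument?"
#' is answerable only from the visual features (the texture token exists
#' solely as a signal block there); "what is the color of the <name>?" is
#' answerable from the question text alone (colors are class constants).
#' Removing a stream therefore imposes a chance-level ceiling on its
#' question family, which is what the ablation checks exploit.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param vocab vocabulary config.
#' @return list with `samples`, `text_vocab`, `answer_vocab`,
#'   `n_scene_features`.
#' @export
toy_vqa_dataset <- function(n, seed = 1L, vocab = load_vocab()) {
  textures <- c("smooth", "rough", "ridged")
  text_vocab <- sort(unique(c("what", "is", "the", "color", "texture",
                              "location", "of", "instrument",
                              vocab$instruments, vocab$anatomies)))
  answer_vocab <- sort(unique(c(unname(vocab$colors), textures,
                                vocab$locations)))
  dims <- c(854, 480)
  # a box whose centroid sits in the middle 60% of a chosen grid cell
  box_in_bin <- function(row, col) {
    w3 <- dims[1] / 3; h3 <- dims[2] / 3
    cx <- (col - 1) * w3 + stats::runif(1, 0.2, 0.8) * w3
    cy <- (row - 1) * h3 + stats::runif(1, 0.2, 0.8) * h3
    w <- stats::runif(1, 60, min(110, 2 * cx, 2 * (dims[1] - cx)))
    h <- stats::runif(1, 40, min(80, 2 * cy, 2 * (dims[2] - cy)))
    c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  }
  with_seed(seed, {
    samples <- lapply(seq_len(n), function(i) {
      inst <- sample(vocab$instruments, 1)
      anas <- sample(vocab$anatomies, 2)
      cls <- c(inst, anas)
      diag_bin <- sample(3, 1)  # instrument sits on the grid diagonal, so
                                # the location family is a clean 3-way task
      boxes <- c(list(box_in_bin(diag_bin, diag_bin)),
                 lapply(1:2, function(k) sample_box(dims, c(120, 280),
                                                    c(90, 220))))
      objs <- lapply(seq_along(cls), function(k) {
        b <- boxes[[k]]
        scene_object(paste0(cls[k], "-1"), cls[k],
                     bbox(b[1], b[2], b[3], b[4]), dims, vocab)
      })
      tex <- sample(textures, length(cls), replace = TRUE)
      fam <- sample(c("location", "texture", "color"), 1)
      if (fam == "location") {
        q <- c("what", "is", "the", "location", "of", "the", "instrument")
        ans <- objs[[1]]$location
      } else if (fam == "texture") {
        q <- c("what", "is", "the", "texture", "of", "the", "instrument")
        ans <- tex[1]
      } else {
        target <- sample(cls, 1)
        q <- c("what", "is", "the", "color", "of", "the", target)
        ans <- unname(vocab$colors[[target]])
      }
      list(tokens = match(q, text_vocab),
           scene = scene_features(objs, dims, vocab),
           visual = visual_provider_hash(cls, tex),
           answer = ans)
    })
    list(samples = samples, text_vocab = text_vocab,
         answer_vocab = answer_vocab,
         n_scene_features = length(c(vocab$instruments, vocab$anatomies)) + 4L)
  })
}
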
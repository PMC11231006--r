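# Minimal reverse-mode automatic differentiation over dense matrices: a
# creation-order tape of nodes, each knowing how to push its output gradient
# into its parents. Sized for desk-scale models (tens of thousands of tape
# nodes per step); everything is plain base-R matrix arithmetic.

.ad <- new.env(parent = emptyenv())
.ad$recording <- FALSE
.ad$tape <- list()

ad_begin <- function() {
  .ad$recording <- TRUE
  .ad$tape <- list()
  invisible(NULL)
}

ad_end <- function() {
  .ad$recording <- FALSE
  .ad$tape <- list()
  invisible(NULL)
}

ad_node <- function(val, parents = list(), bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$bw <- bw
  class(n) <- "adnode"
  if (isTRUE(.ad$recording) && length(parents)) {
    .ad$tape[[length(.ad$tape) + 1]] <- n
  }
  n
}

ad_is_node <- function(x) inherits(x, "adnode")

ad_const <- function(x) ad_node(as.matrix(x))

# Trainable parameter: carries an accumulated gradient plus Adam moments.
ad_param <- function(x) {
  n <- ad_node(as.matrix(x))
  n$is_param <- TRUE
  n$m <- matrix(0, nrow(n$val), ncol(n$val))
  n$v <- matrix(0, nrow(n$val), ncol(n$val))
  n
}

acc_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

ad_backward <- function(loss) {
  loss$grad <- matrix(1, nrow(loss$val), ncol(loss$val))
  tape <- .ad$tape
  for (i in rev(seq_along(tape))) {
    n <- tape[[i]]
    if (is.null(n$grad) || is.null(n$bw)) next
    gs <- n$bw(n$grad)
    for (k in seq_along(n$parents)) {
      if (!is.null(gs[[k]])) acc_grad(n$parents[[k]], gs[[k]])
    }
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$val %*% b$val, list(a, b), function(g) {
    list(g %*% t(b$val), t(a$val) %*% g)
  })
}

# a %*% t(b)
ad_matmul_t <- function(a, b) {
  ad_node(a$val %*% t(b$val), list(a, b), function(g) {
    list(g %*% b$val, t(g) %*% a$val)
  })
}

ad_add <- function(a, b) {
  ad_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

# add a 1 x d row vector (e.g. a bias) to every row of a
ad_add_rowvec <- function(a, v) {
  ad_node(sweep(a$val, 2, as.numeric(v$val), "+"), list(a, v), function(g) {
    list(g, matrix(colSums(g), 1))
  })
}

ad_scale <- function(a, s) {
  ad_node(a$val * s, list(a), function(g) list(g * s))
}

ad_relu <- function(a) {
  keep <- a$val > 0
  ad_node(a$val * keep, list(a), function(g) list(g * keep))
}

# row-wise softmax; mask is a logical vector over columns (keys), FALSE =
# excluded. Rows with no unmasked key become all-zero.
ad_softmax_rows <- function(a, mask = NULL) {
  x <- a$val
  if (!is.null(mask)) x[, !mask] <- -Inf
  mx <- apply(x, 1, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(x - mx)
  e[!is.finite(e)] <- 0
  z <- rowSums(e)
  p <- e / ifelse(z > 0, z, 1)
  ad_node(p, list(a), function(g) {
    dot <- rowSums(g * p)
    list((g - dot) * p)
  })
}

# gamma, beta: 1 x d parameters; per-row layer normalization
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gm <- as.numeric(gamma$val)
  y <- sweep(xhat, 2, gm, "*")
  y <- sweep(y, 2, as.numeric(beta$val), "+")
  ad_node(y, list(a, gamma, beta), function(g) {
    dxhat <- sweep(g, 2, gm, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - m1 - xhat * m2) * inv
    list(dx, matrix(colSums(g * xhat), 1), matrix(colSums(g), 1))
  })
}

ad_rbind <- function(nodes) {
  nodes <- nodes[vapply(nodes, function(n) nrow(n$val) > 0, logical(1))]
  if (!length(nodes)) abort_surgvqa("empty sequence", "surgvqa_shape_error")
  rows <- vapply(nodes, function(n) nrow(n$val), integer(1))
  ad_node(do.call(rbind, lapply(nodes, function(n) n$val)), nodes,
          function(g) {
            out <- vector("list", length(nodes))
            at <- 0L
            for (k in seq_along(nodes)) {
              out[[k]] <- g[at + seq_len(rows[k]), , drop = FALSE]
              at <- at + rows[k]
            }
            out
          })
}

# masked average pooling over rows -> 1 x d; divides by the number of kept
# rows
ad_mean_rows <- function(a, keep = NULL) {
  keep <- keep %||% rep(TRUE, nrow(a$val))
  nk <- sum(keep)
  if (nk == 0) abort_surgvqa("all rows masked in pooling", "surgvqa_shape_error")
  ad_node(matrix(colSums(a$val[keep, , drop = FALSE]) / nk, 1), list(a),
          function(g) {
            out <- matrix(0, nrow(a$val), ncol(a$val))
            out[keep, ] <- rep(as.numeric(g) / nk, each = nk)
            list(out)
          })
}

# softmax cross-entropy against a single target class; logits are 1 x A
ad_ce_loss <- function(logits, target_idx) {
  x <- as.numeric(logits$val)
  p <- exp(x - max(x))
  p <- p / sum(p)
  loss <- -log(max(p[target_idx], 1e-12))
  ad_node(matrix(loss, 1, 1), list(logits), function(g) {
    d <- p
    d[target_idx] <- d[target_idx] - 1
    list(matrix(d, 1) * as.numeric(g))
  })
}

# embedding lookup: rows `idx` of table E (V x d)
ad_embed <- function(E, idx) {
  ad_node(E$val[idx, , drop = FALSE], list(E), function(g) {
    out <- matrix(0, nrow(E$val), ncol(E$val))
    for (k in seq_along(idx)) {
      out[idx[k], ] <- out[idx[k], ] + g[k, ]
    }
    list(out)
  })
}

ad_sum_nodes <- function(nodes) {
  ad_node(Reduce(`+`, lapply(nodes, function(n) n$val)), nodes,
          function(g) rep(list(g), length(nodes)))
}

# One Adam step over a parameter list; grads must already be accumulated.
adam_step <- function(params, lr, step, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^step)
    vhat <- p$v / (1 - beta2^step)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}
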
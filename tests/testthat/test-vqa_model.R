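test_that("attention: singleton key returns the value, identical keys the mean", {
  out1 <- scaled_dot_attention(matrix(c(1, 2), 1, 2),
                               matrix(c(3, 1), 1, 2),
                               matrix(c(7, -2, 4), 1, 3))
  expect_equal(out1$output, matrix(c(7, -2, 4), 1, 3))
  expect_equal(out1$weights, matrix(1, 1, 1))

  K <- matrix(rep(c(1, 2), each = 3), 3, 2)  # three identical keys
  V <- matrix(c(0, 3, 6, 1, 1, 1), 3, 2)
  out2 <- scaled_dot_attention(matrix(c(5, -1), 1, 2), K, V)
  expect_equal(out2$output, matrix(colMeans(V), 1), tolerance = 1e-12)
})

test_that("attention matches the brute-force oracle and rows are stochastic", {
  set.seed(3)
  for (i in 1:20) {
    nq <- sample(1:4, 1); nk <- sample(1:6, 1); dk <- sample(2:5, 1)
    Q <- matrix(sample(-3:3, nq * dk, TRUE), nq, dk)
    K <- matrix(sample(-3:3, nk * dk, TRUE), nk, dk)
    V <- matrix(rnorm(nk * 3), nk, 3)
    mask <- if (i %% 2 == 0) runif(nk) > 0.3 else NULL
    if (!is.null(mask) && !any(mask)) mask[1] <- TRUE
    got <- scaled_dot_attention(Q, K, V, mask)
    want <- oracle_attention(Q, K, V, mask)
    expect_equal(got$output, want$output, tolerance = 1e-9)
    expect_equal(got$weights, want$weights, tolerance = 1e-9)
    expect_equal(rowSums(got$weights), rep(1, nq), tolerance = 1e-6)
    if (!is.null(mask)) expect_true(all(got$weights[, !mask] == 0))
  }
  # all keys masked: zero rows, reported
  expect_message(
    z <- scaled_dot_attention(matrix(1, 2, 2), matrix(1, 3, 2),
                              matrix(1, 3, 2), mask = rep(FALSE, 3)),
    "all keys masked")
  expect_equal(z$output, matrix(0, 2, 2))
})

test_that("roi_align: constants, exact cell alignment, degenerate boxes", {
  const <- roi_align(matrix(3.25, 6, 6), c(0.4, 1.1, 5.3, 5.9), 3)
  expect_equal(as.numeric(const), rep(3.25, 9), tolerance = 1e-12)

  # box covering the full 4x4 map, pooled 2x2 with 2x2 sub-points: each cell
  # average equals the mean of its 2x2 pixel block
  fm <- matrix(1:16, 4, 4, byrow = TRUE)
  got <- roi_align(fm, c(0, 0, 4, 4), 2)
  want <- matrix(c(mean(fm[1:2, 1:2]), mean(fm[1:2, 3:4]),
                   mean(fm[3:4, 1:2]), mean(fm[3:4, 3:4])), 2, 2,
                 byrow = TRUE)
  expect_equal(got[1, , ], want, tolerance = 1e-12)

  expect_error(roi_align(fm, c(2, 2, 2, 3), 2),
               class = "surgvqa_validation_error")
  expect_error(roi_align(fm, c(0, 0, 9, 4), 2),
               class = "surgvqa_validation_error")
})

test_that("roi_align matches the brute-force bilinear oracle", {
  set.seed(5)
  for (i in 1:40) {
    fm <- matrix(runif(64), 8, 8)
    x1 <- runif(1, 0, 5); y1 <- runif(1, 0, 5)
    box <- c(x1, y1, x1 + runif(1, 0.5, 3), y1 + runif(1, 0.5, 3))
    got <- roi_align(fm, box, 2)
    expect_equal(got[1, , ], oracle_roi(fm, box, 2), tolerance = 1e-6)
  }
})

test_that("scene features: width, normalization endpoints, empty scene", {
  vocab <- load_vocab()
  dims <- c(200, 100)
  full <- scene_object("liver-1", "liver", bbox(0, 0, 200, 100), dims, vocab)
  fe <- scene_features(list(full), dims, vocab)
  n_cls <- length(c(vocab$instruments, vocab$anatomies))
  expect_equal(ncol(fe), n_cls + 4)
  expect_equal(unname(fe[1, n_cls + 1:4]), c(0, 0, 1, 1))
  expect_equal(sum(fe[1, seq_len(n_cls)]), 1)

  ds <- toy_vqa_dataset(2, seed = 1)
  cfg <- vqa_config(d = 16, text_vocab = ds$text_vocab,
                    answer_vocab = ds$answer_vocab,
                    n_scene_features = ds$n_scene_features)
  m <- vqa_model(cfg, seed = 1)
  expect_equal(dim(scene_encode(m, list(), dims)), c(0, 16))
  enc <- scene_encode(m, list(full), dims, vocab)
  expect_equal(dim(enc), c(1, 16))
})

make_test_model <- function(d = 16, seed = 1, ...) {
  ds <- toy_vqa_dataset(2, seed = 99)
  cfg <- vqa_config(d = d, text_vocab = ds$text_vocab,
                    answer_vocab = ds$answer_vocab,
                    n_scene_features = ds$n_scene_features, ...)
  vqa_model(cfg, seed = seed)
}

test_that("SIM: shape contract and empty scenes", {
  m <- make_test_model()
  expect_equal(nrow(sim_forward(m, matrix(0, 0, 16), matrix(rnorm(48), 3, 16))), 0)
  set.seed(2)
  for (i in 1:6) {
    N <- sample(1:8, 1); K <- sample(1:12, 1)
    S <- matrix(rnorm(N * 16), N, 16)
    T_emb <- matrix(rnorm(K * 16), K, 16)
    out <- sim_forward(m, S, T_emb)
    expect_equal(dim(out), c(N, 16))
  }
  expect_error(sim_forward(m, matrix(0, 2, 8), matrix(0, 3, 16)),
               class = "surgvqa_shape_error")
})

test_that("SIM is permutation-equivariant in scene-object order", {
  m <- make_test_model(seed = 7)
  set.seed(11)
  S <- matrix(rnorm(5 * 16), 5, 16)
  T_emb <- matrix(rnorm(4 * 16), 4, 16)
  base <- sim_forward(m, S, T_emb)
  for (i in 1:5) {
    perm <- sample(5)
    expect_equal(sim_forward(m, S[perm, , drop = FALSE], T_emb),
                 base[perm, , drop = FALSE], tolerance = 1e-10)
  }
})

test_that("fusion: logits length, permutation invariance, determinism", {
  m <- make_test_model(seed = 5)
  set.seed(4)
  S_r <- matrix(rnorm(3 * 16), 3, 16)
  V <- matrix(rnorm(3 * 16), 3, 16)
  T_emb <- matrix(rnorm(6 * 16), 6, 16)
  lg <- fuse_and_classify(m, S_r, V, T_emb)
  expect_equal(length(lg), length(m$config$answer_vocab))
  expect_identical(lg, fuse_and_classify(m, S_r, V, T_emb))
  # permuting scene objects (same permutation for S_r and V) leaves the
  # pooled answer unchanged
  perm <- c(3, 1, 2)
  expect_equal(unname(fuse_and_classify(m, S_r[perm, ], V[perm, ], T_emb)),
               unname(lg), tolerance = 1e-10)
  expect_error(fuse_and_classify(m, matrix(0, 0, 16), matrix(0, 0, 16),
                                 matrix(0, 0, 16)),
               class = "surgvqa_shape_error")
})

test_that("padding-only positions do not change the logits", {
  m <- make_test_model(seed = 9)
  set.seed(6)
  S_r <- matrix(rnorm(2 * 16), 2, 16)
  V <- matrix(rnorm(2 * 16), 2, 16)
  T_emb <- matrix(rnorm(5 * 16), 5, 16)
  base <- fuse_and_classify(m, S_r, V, T_emb)
  padded <- fuse_and_classify(
    m,
    rbind(S_r, matrix(99, 2, 16)), rbind(V, matrix(-99, 2, 16)),
    rbind(T_emb, matrix(42, 3, 16)),
    scene_mask = c(TRUE, TRUE, FALSE, FALSE),
    text_mask = c(rep(TRUE, 5), FALSE, FALSE, FALSE))
  expect_equal(padded, base, tolerance = 1e-8)
})

test_that("toy training: zero learning rate freezes the trace; seeds reproduce", {
  ds <- toy_vqa_dataset(12, seed = 3)
  cfg <- vqa_config(d = 16, text_vocab = ds$text_vocab,
                    answer_vocab = ds$answer_vocab,
                    n_scene_features = ds$n_scene_features)
  m0 <- vqa_model(cfg, seed = 2)
  r0 <- toy_train(m0, ds$samples, epochs = 3, lr = 0)
  expect_equal(length(unique(r0$trace$train_acc)), 1)
  expect_equal(length(unique(round(r0$trace$loss, 12))), 1)

  r1 <- toy_train(vqa_model(cfg, seed = 2), ds$samples, epochs = 4, lr = 5e-3)
  r2 <- toy_train(vqa_model(cfg, seed = 2), ds$samples, epochs = 4, lr = 5e-3)
  expect_identical(r1$trace, r2$trace)
  expect_lt(r1$trace$loss[4], r1$trace$loss[1])
})
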
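# Encoder shapes and determinism, embedding layers, fusion, the Siamese
# weight-sharing contract, checkpoints, and a finite-difference check of
# the compiled backward pass.

test_that("encoder output shape follows blocks x filters; features nonnegative", {
  m <- tiny_model()
  seg <- matrix(rnorm(5 * 90), 5, 90)
  f <- encode(seg, m)
  expect_equal(dim(f), c(2 * 2, 1))   # nblk * n_filters
  expect_true(all(f >= 0))            # global max of post-ReLU activations
  # batch of segments
  f3 <- encode(list(seg, seg * 2, seg * 0), m)
  expect_equal(dim(f3), c(4, 3))
  # all-zero segments encode identically (pure function in inference mode)
  expect_equal(f3[, 3], encode(matrix(0, 5, 90), m)[, 1], tolerance = 0)
  # inference determinism is bit-exact
  expect_identical(encode(seg, m), encode(seg, m))
  expect_error(encode(matrix(0, 3, 90), m),
               class = "alarmsieve_validation_error")
})

test_that("conv stride/padding arithmetic gives ceil(T/stride) per layer", {
  # kernels larger than a stride-5 'same' output still work: T = 2500 -> 500
  # -> 100 positions before pooling, independent of kernel size
  s <- model_structure(n_filters = 3L, kernels = c(50L, 400L), stride = 5L)
  m <- init_model(s, rng_seed = 2)
  f <- encode(matrix(rnorm(5 * 2500), 5, 2500), m)
  expect_equal(nrow(f), 6)
  # odd lengths round up
  s2 <- model_structure(n_filters = 2L, kernels = 7L, stride = 3L)
  m2 <- init_model(s2, rng_seed = 2)
  expect_equal(nrow(encode(matrix(rnorm(5 * 11), 5, 11), m2)), 2)
})

test_that("alarm and rule embeddings follow their defining algebra", {
  set.seed(3)
  W_a <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(embed_alarm(c(0, 0, 1, 0, 0), W_a), W_a[3, ])
  expect_error(embed_alarm(c(0.5, 0.5, 0, 0, 0), W_a),
               class = "alarmsieve_validation_error")
  W_r <- rnorm(6)
  expect_equal(embed_rule(0, W_r), rep(0, 6))
  expect_equal(embed_rule(1, W_r), W_r)
  expect_equal(embed_rule(0.5, W_r), 0.5 * W_r)
  expect_error(embed_rule(1.2, W_r), class = "alarmsieve_validation_error")
})

test_that("fused classifier is a sigmoid over the concatenation", {
  expect_equal(fuse_and_classify(c(1, 2), c(3), c(4), W_c = rep(0, 4)), 0.5)
  expect_gt(fuse_and_classify(c(10), NULL, NULL, W_c = c(1)), 0.9999)
  # permuting inputs together with weights leaves the output unchanged
  set.seed(4)
  E <- rnorm(7); W <- rnorm(7); p <- sample(7)
  expect_equal(fuse_and_classify(E, NULL, NULL, W, 0.3),
               fuse_and_classify(E[p], NULL, NULL, W[p], 0.3))
  expect_error(fuse_and_classify(c(1, 2), NULL, NULL, W_c = rep(1, 5)),
               class = "alarmsieve_validation_error")
})

test_that("Siamese weight sharing and baseline invariance", {
  m <- tiny_model()
  seg <- matrix(rnorm(5 * 80), 5, 80)
  pair <- list(alarm_segment = seg, baseline_segment = seg,
               baseline_start = 0L, label = "true_alarm",
               alarm_onehot = c(1, 0, 0, 0, 0), rule_score = 0.9)
  class(pair) <- "segment_pair"
  out <- forward_pair(pair, m)
  expect_identical(out$f_A, out$f_R)   # same params, same input, same output
  expect_true(out$O > 0 && out$O < 1)
  # classification ignores the baseline segment entirely
  pair2 <- pair
  pair2$baseline_segment <- matrix(rnorm(5 * 80), 5, 80)
  out2 <- forward_pair(pair2, m)
  expect_identical(out2$O, out$O)
  expect_false(identical(out2$f_R, out$f_R))
})

test_that("checkpoints round-trip bit-exactly", {
  m <- tiny_model(seed = 9)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_equal(unclass(back$structure), unclass(m$structure),
               ignore_attr = TRUE)
  seg <- matrix(rnorm(5 * 60), 5, 60)
  expect_identical(encode(seg, back), encode(seg, m))
})

test_that("compiled gradients agree with finite differences", {
  s <- model_structure(n_filters = 2L, kernels = c(4L, 7L), stride = 2L,
                       Sa = 3L, Sr = 3L)
  model <- init_model(s, rng_seed = 5)
  set.seed(3)
  B <- 4; Tlen <- 40
  xA <- array(rnorm(5 * Tlen * B), c(5, Tlen, B))
  xR <- array(rnorm(5 * Tlen * B), c(5, Tlen, B))
  types <- c(1L, 3L, 5L, 2L)
  rule <- c(0.1, 0.9, 0.5, 0.9)
  y <- c(0, 1, 1, 0)
  stepf <- function(params)
    alarmsieve:::cpp_siamese_step(xA, xR, types, rule, y, params, unclass(s),
                                  1.5, 1.5, 0.0, 11L, TRUE, TRUE, TRUE)
  st <- stepf(model$params)
  # loss head agrees with the pure-R loss functions
  featA <- encode(lapply(seq_len(B), function(i) xA[, , i]), model,
                  training = TRUE)
  featR <- encode(lapply(seq_len(B), function(i) xR[, , i]), model,
                  training = TRUE)
  C_ref <- batch_constraint(lapply(seq_len(B), function(i)
    list(f_A = featA[, i], f_R = featR[, i], label = y[i])))
  expect_equal(st$loss_constraint, C_ref, tolerance = 1e-4)
  expect_equal(st$loss_total, st$loss_bce + 1.5 * st$loss_constraint,
               tolerance = 1e-6)
  # finite differences on sampled coordinates (conv biases excluded: batch
  # norm provably cancels them, their true gradient is zero)
  paths <- list(list("blocks", 1, "W1"), list("blocks", 1, "g1"),
                list("blocks", 1, "be1"), list("blocks", 2, "W2"),
                list("blocks", 2, "g2"), list("Wa"), list("Wr"),
                list("Wc"), list("bc"))
  for (pa in paths) {
    th <- alarmsieve:::get_path(model$params, pa)
    an <- alarmsieve:::get_path(st$grads, pa)
    for (k in sample(length(th), min(3, length(th)))) {
      h <- 1e-3
      p1 <- model$params; v <- alarmsieve:::get_path(p1, pa)
      v[k] <- v[k] + h; p1 <- alarmsieve:::set_path(p1, pa, v)
      p2 <- model$params; v <- alarmsieve:::get_path(p2, pa)
      v[k] <- v[k] - h; p2 <- alarmsieve:::set_path(p2, pa, v)
      num <- (stepf(p1)$loss_total - stepf(p2)$loss_total) / (2 * h)
      # robust relative error; the floor absorbs float32 fd noise
      err <- abs(num - an[k]) / max(0.02, abs(num) + abs(an[k]))
      expect_lt(err, 0.05,
                label = paste("grad err", paste(unlist(pa), collapse = "/"), k))
    }
  }
  # conv bias gradient is (near) zero because of batch norm
  expect_lt(max(abs(alarmsieve:::get_path(st$grads,
                                          list("blocks", 1, "b1")))), 1e-4)
})
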
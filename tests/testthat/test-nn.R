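test_that("attention weights are a row-stochastic softmax of scaled scores", {
  # single token: softmax of a scalar is 1, output is v exactly
  out <- scaled_dot_product_attention(matrix(1), matrix(2), matrix(5))
  expect_equal(as.numeric(out), 5)
  expect_equal(as.numeric(attr(out, "weights")), 1)

  # identical keys: uniform weights, output = mean of value rows
  q <- matrix(rnorm(2), 1, 2)
  k <- rbind(c(1, 1), c(1, 1))
  v <- rbind(c(3, 0), c(5, 4))
  out <- scaled_dot_product_attention(q, k, v)
  expect_equal(as.numeric(out), c(4, 2))

  # hand-rolled softmax oracle
  q <- matrix(c(1, 0), 1, 2)
  k <- rbind(c(1, 0), c(0, 1))
  v <- matrix(c(1, 0), 2, 1)
  out <- scaled_dot_product_attention(q, k, v, d_k = 2)
  s <- c(1, 0) / sqrt(2)
  w <- exp(s) / sum(exp(s))
  expect_equal(as.numeric(out), sum(w * c(1, 0)), tolerance = 1e-12)

  # rows sum to one on random draws
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    d <- sample(1:5, 1)
    w <- attr(scaled_dot_product_attention(
      matrix(rnorm(n * d), n, d), matrix(rnorm(n * d), n, d),
      matrix(rnorm(n * 2), n, 2)
    ), "weights")
    expect_equal(rowSums(w), rep(1, n), tolerance = 1e-6)
  }
  expect_error(scaled_dot_product_attention(q, k, v, d_k = 0), "positive")
  expect_error(scaled_dot_product_attention(matrix(1, 1, 2), matrix(1, 1, 3), v))
})

test_that("the model's scalar-projection attention matches the generic op", {
  set.seed(5)
  x <- matrix(rnorm(3 * 384), 3, 384)
  att <- c(0.5, 0.1, -0.4, 0.2, 1.1, -0.3)
  got <- distaff:::cpp_model_attention(x, att)
  for (b in 1:3) {
    xi <- x[b, ]
    want <- scaled_dot_product_attention(
      matrix(att[1] * xi + att[2]), matrix(att[3] * xi + att[4]),
      matrix(att[5] * xi + att[6]), d_k = 1
    )
    expect_equal(got[b, ], as.numeric(want), tolerance = 1e-10)
  }
})

test_that("log-cosh loss matches its closed form and quadratic limit", {
  expect_equal(log_cosh_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(log_cosh_loss(1, 0), log(cosh(1)), tolerance = 1e-12)
  expect_equal(log_cosh_loss(1, 0), 0.4337808, tolerance = 1e-6)
  e <- 1e-3
  expect_equal(log_cosh_loss(e, 0), e^2 / 2, tolerance = 1e-6)
  # overflow-safe for large errors
  expect_equal(log_cosh_loss(1000, 0), 1000 - log(2), tolerance = 1e-9)
  expect_error(log_cosh_loss(numeric(), numeric()), "non-empty")
  expect_error(log_cosh_loss(1:3, 1:2), "equal length")
})

test_that("kd to pKd conversion is exact", {
  expect_identical(pkd_from_kd(1e-9), 9)
  expect_equal(pkd_from_kd(c(1e-3, 1e-12)), c(3, 12))
  rec <- affinity_records("c1", kd = 1e-6)
  expect_equal(rec$pkd, 6)
  expect_error(affinity_records("c1", kd = 1e-6, pkd = 5), "inconsistent")
})

test_that("a CNN branch maps any valid sequence to a 128-vector", {
  set.seed(11)
  w <- init_branch_weights()
  seq <- matrix(rnorm(40 * 128), 40, 128)
  out <- cnn_branch(seq, w)
  expect_length(out, 128L)
  expect_true(all(is.finite(out)))
  # all-zero input stays exactly zero through the bias-free stack
  expect_equal(cnn_branch(matrix(0, 40, 128), w), rep(0, 128))
  # too-short input violates the contract
  expect_error(cnn_branch(seq[1:2, ], w), "shorter")
  # SMILES-branch kernel lengths
  ws <- init_branch_weights(kernels = c(4L, 6L, 8L))
  expect_length(cnn_branch(matrix(rnorm(24 * 128), 24, 128), ws, c(4, 6, 8)), 128L)
})

test_that("embedding maps shapes correctly and pads to zero vectors", {
  cfg <- model_config(seed = 2)
  w <- init_affinity_model(cfg)
  pocket <- c(rep(5L, 10), rep(0L, 990))
  protein <- matrix(0, 500, 58)
  protein[1:4, ] <- rnorm(4 * 58)
  smiles <- c(1L, 64L, rep(0L, 148))
  e <- embed_inputs(pocket, protein, smiles, w)
  expect_equal(dim(e$pocket), c(1000L, 128L))
  expect_equal(dim(e$protein), c(500L, 128L))
  expect_equal(dim(e$smiles), c(150L, 128L))
  expect_true(all(e$pocket[11:1000, ] == 0)) # pad code 0 -> zero vector
  expect_true(all(e$protein[5:500, ] == 0)) # bias-free projection
  expect_equal(embed_inputs(rep(0L, 1000), matrix(0, 500, 58),
    rep(0L, 150), w
  )$pocket, matrix(0, 1000, 128))
  # distinct non-pad codes embed to distinct rows at seeded init
  expect_false(isTRUE(all.equal(w$emb_pocket[2, ], w$emb_pocket[3, ])))
  expect_false(isTRUE(all.equal(w$emb_smiles[10, ], w$emb_smiles[11, ])))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(3)
  cfg <- model_config(seed = 3)
  w <- init_affinity_model(cfg)
  B <- 2
  data <- list(
    pocket = matrix(sample(0:41, B * 12, TRUE), B, 12),
    protein = matrix(rnorm(B * 8 * 58, sd = 0.5), B * 8, 58),
    smiles = matrix(sample(0:64, B * 8, TRUE), B, 8),
    y = c(5, 7)
  )
  lg <- distaff:::cpp_loss_grad(w, data, cfg)
  eps <- 1e-6
  for (nm in c("Wproj", "pkW1", "smW2", "att", "Wf2", "Wo", "bo")) {
    idx <- sample(length(w[[nm]]), min(2L, length(w[[nm]])))
    for (i in idx) {
      wp <- w
      wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w
      wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (distaff:::cpp_loss(wp, data, cfg) -
        distaff:::cpp_loss(wm, data, cfg)) / (2 * eps)
      expect_equal(lg$grad[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("trailing-padding crop leaves model output bit-identical", {
  cfg <- model_config(seed = 5)
  w <- init_affinity_model(cfg)
  g <- generate_dataset(10, synthetic_complex_spec(seed = 9))
  ds <- featurize_synthetic(g)
  full <- distaff:::dataset_tensors(
    ds, list(pocket = 1000L, protein = 500L, smiles = 150L)
  )
  crop <- distaff:::dataset_tensors(ds)
  expect_lt(ncol(crop$pocket), 1000L)
  expect_equal(
    distaff:::cpp_predict(w, crop, cfg),
    distaff:::cpp_predict(w, full, cfg),
    tolerance = 1e-12
  )
})

test_that("forward pass is deterministic and batch independent", {
  cfg <- model_config(seed = 6)
  w <- init_affinity_model(cfg)
  g <- generate_dataset(6, synthetic_complex_spec(seed = 13))
  ds <- featurize_synthetic(g)
  tens <- distaff:::dataset_tensors(ds)
  p1 <- distaff:::cpp_predict(w, tens, cfg)
  p2 <- distaff:::cpp_predict(w, tens, cfg)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  # per-item outputs do not depend on batch composition
  half <- distaff:::dataset_tensors(distaff:::subset_dataset(ds, 1:3),
    lengths = distaff:::crop_lengths(ds)
  )
  expect_equal(distaff:::cpp_predict(w, half, cfg), p1[1:3], tolerance = 1e-12)
})

test_that("the concatenated representation entering attention is 384-wide", {
  cfg <- model_config()
  expect_equal(3L * cfg$cnn_filters[3], 384L)
  w <- init_affinity_model(cfg)
  expect_equal(nrow(w$Wf1), 384L)
  expect_equal(ncol(w$Wf1), 256L)
  expect_equal(dim(w$Wf2), c(256L, 128L))
})
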
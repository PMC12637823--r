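# Encoder and heads: shape contracts, masking, equivariance, closed-form
# degenerate cases, and the training loss.

test_that("input MLP is row-wise and degenerates to bias-only rows", {
  fx <- tiny_fitted(2)
  X <- matrix(rnorm(3 * 5), 3)
  H <- embed_inputs(X, fx$params)
  expect_equal(dim(H), c(3L, 8L))
  # permuting rows permutes outputs identically
  perm <- c(3L, 1L, 2L)
  expect_identical(embed_inputs(X[perm, ], fx$params), H[perm, ])
  # zero weights: every row is the output bias
  p0 <- fx$params
  p0[["mlp.W1"]][] <- 0; p0[["mlp.W2"]][] <- 0
  p0[["mlp.b2"]] <- rnorm(8)
  H0 <- embed_inputs(X, p0)
  expect_equal(H0, matrix(p0[["mlp.b2"]], 3, 8, byrow = TRUE))
  expect_error(embed_inputs(matrix(0, 2, 7), fx$params), "dimension")
})

test_that("attention logits follow the additive form with masked diagonal", {
  Z <- rbind(c(1, 2), c(3, 4))
  E <- attention_logits(Z, a_src = c(1, 0), a_dst = c(0, 1))
  expect_identical(E[1, 2], 5)   # LeakyReLU(1 + 4)
  expect_identical(E[2, 1], 5)   # LeakyReLU(3 + 2)
  expect_identical(diag(E), c(-Inf, -Inf))
  # negative pre-activation goes through the leaky slope
  En <- attention_logits(-Z, a_src = c(1, 0), a_dst = c(0, 1))
  expect_equal(En[1, 2], 0.2 * (-5))
  # zero attention vectors give all-zero valid logits
  E0 <- attention_logits(Z, a_src = c(0, 0), a_dst = c(0, 0))
  expect_identical(E0[1, 2], 0)
  # invalid destination columns are -Inf for every source
  Em <- attention_logits(rbind(Z, c(9, 9)), a_src = c(1, 0), a_dst = c(0, 1),
                         mask = c(TRUE, TRUE, FALSE))
  expect_true(all(Em[, 3] == -Inf))
  expect_error(attention_logits(Z, c(1, 0), c(0, 1), mask = c(FALSE, FALSE)),
               "valid")
})

test_that("attention weights are row-stochastic over valid neighbors", {
  E <- matrix(c(-Inf, 0, 0, -Inf), 2, 2, byrow = TRUE)
  A <- attention_weights(E)
  expect_identical(A[1, 2], 1)
  # equal logits share mass equally; closed-form softmax
  E3 <- rbind(c(-Inf, 0, 0), c(0, -Inf, log(3)), c(0, 0, -Inf))
  A3 <- attention_weights(E3)
  expect_equal(A3[1, 2:3], c(0.5, 0.5))
  expect_equal(A3[2, c(1, 3)], c(0.25, 0.75))
  expect_equal(rowSums(A3), rep(1, 3), tolerance = 1e-6)
  # no valid neighbor: exact zero row, no error
  A1 <- attention_weights(matrix(-Inf, 1, 1))
  expect_identical(A1[1, 1], 0)
})

test_that("single-subunit complexes flow through the residual path", {
  fx <- tiny_fitted(3)
  X <- matrix(rnorm(5), 1)
  H0 <- embed_inputs(X, fx$params)
  H1 <- gat_layer(H0, mask = TRUE, fx$params, fx$config, layer = 1L)
  # aggregated neighbor feature is zero, so output = ELU(Wo %*% 0 + bo) + h
  lp <- fx$params
  expected <- ifelse(lp[["gat1.bo"]] > 0, lp[["gat1.bo"]],
                     exp(lp[["gat1.bo"]]) - 1) + H0[1, ]
  expect_equal(drop(H1), expected, tolerance = 1e-12)
})

test_that("encoder is permutation equivariant and deterministic", {
  fx <- tiny_fitted(4)
  for (C in c(2L, 4L, 6L)) {
    X <- matrix(rnorm(C * 5), C)
    mask <- rep(TRUE, C)
    H <- encode(X, mask, fx$params, fx$config)
    perm <- sample.int(C)
    Hp <- encode(X[perm, , drop = FALSE], mask, fx$params, fx$config)
    expect_equal(Hp, H[perm, , drop = FALSE], tolerance = 1e-5)
    # eval mode is deterministic
    expect_identical(encode(X, mask, fx$params, fx$config), H)
  }
})

test_that("valid outputs are bit-for-bit independent of padded rows", {
  fx <- tiny_fitted(5)
  X <- matrix(rnorm(4 * 5), 4)
  mask <- c(TRUE, TRUE, FALSE, TRUE)
  H <- encode(X, mask, fx$params, fx$config)
  X2 <- X
  X2[3, ] <- rnorm(5) * 100
  H2 <- encode(X2, mask, fx$params, fx$config)
  expect_identical(H2[mask, ], H[mask, ])
  P <- local_head(H, mask, fx$params)
  P2 <- local_head(H2, mask, fx$params)
  expect_identical(P2[mask, ], P[mask, ])
  g <- global_head(H, mask, fx$params, fx$config, fx$vocab)
  g2 <- global_head(H2, mask, fx$params, fx$config, fx$vocab)
  expect_identical(g, g2)
})

test_that("disabling attention removes all cross-chain information flow", {
  fx <- tiny_fitted(6)
  cfg <- tiny_config(use_gat = FALSE)
  X <- matrix(rnorm(3 * 5), 3)
  H <- encode(X, rep(TRUE, 3), fx$params, cfg)
  # replace other chains entirely: row 1 unchanged
  X2 <- X; X2[2:3, ] <- rnorm(10)
  H2 <- encode(X2, rep(TRUE, 3), fx$params, cfg)
  expect_identical(H2[1, ], H[1, ])
  P <- local_head(H, rep(TRUE, 3), fx$params)
  P2 <- local_head(H2, rep(TRUE, 3), fx$params)
  expect_identical(P2[1, ], P[1, ])
})

test_that("local head yields valid distributions, uniform at zero weights", {
  fx <- tiny_fitted(7)
  X <- matrix(rnorm(3 * 5), 3)
  H <- encode(X, rep(TRUE, 3), fx$params, fx$config)
  P <- local_head(H, rep(TRUE, 3), fx$params)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-6)
  expect_true(all(P >= 0))
  p0 <- fx$params; p0[["local.W"]][] <- 0; p0[["local.b"]][] <- 0
  P0 <- local_head(H, rep(TRUE, 3), p0)
  expect_equal(P0, matrix(1 / 4, 3, 4))
  # identical rows give identical distributions
  Hd <- rbind(H[1, ], H[1, ])
  Pd <- local_head(Hd, rep(TRUE, 2), fx$params)
  expect_identical(Pd[1, ], Pd[2, ])
})

test_that("global head is permutation invariant and routes by count", {
  fx <- tiny_fitted(8)
  X <- matrix(rnorm(3 * 5), 3)
  mask <- rep(TRUE, 3)
  H <- encode(X, mask, fx$params, fx$config)
  g <- global_head(H, mask, fx$params, fx$config, fx$vocab)
  expect_equal(sum(g), 1, tolerance = 1e-6)
  expect_identical(names(g)[length(g)], "other")
  perm <- c(2L, 3L, 1L)
  Hp <- encode(X[perm, ], mask, fx$params, fx$config)
  gp <- global_head(Hp, mask, fx$params, fx$config, fx$vocab)
  expect_equal(gp, g, tolerance = 1e-5)
  # a count with no dedicated expert routes to the shared expert alone
  X6 <- matrix(rnorm(6 * 5), 6)
  H6 <- encode(X6, rep(TRUE, 6), fx$params, fx$config)
  g6 <- global_head(H6, rep(TRUE, 6), fx$params, fx$config, fx$vocab)
  expect_identical(names(g6), "other")
  expect_identical(sum(g6), 1)
})

test_that("loss matches cross-entropy closed forms and is order invariant", {
  fx <- tiny_fitted(9)
  # uniform local predictions: loss = ln K_max (zero-weight everything)
  p0 <- fx$params
  for (nm in names(p0)) p0[[nm]][] <- 0
  cfg_noglob <- tiny_config(lambda_g = 0)
  homos <- lapply(1:3, function(i) random_instance(1L, id = paste0("h", i)))
  l <- model_loss(homos, p0, cfg_noglob, fx$vocab)$loss
  expect_equal(l, log(4), tolerance = 1e-10)
  # entity-order invariance of the full loss
  inst <- random_instance(3L, id = "perm")
  perm <- c(3L, 1L, 2L)
  inst_p <- complex_instance("perm", inst$entity_ids[perm],
                             inst$embeddings[perm, ],
                             true_copies = inst$true_copies[perm])
  l1 <- model_loss(list(inst), fx$params, fx$config, fx$vocab)$loss
  l2 <- model_loss(list(inst_p), fx$params, fx$config, fx$vocab)$loss
  expect_equal(l1, l2, tolerance = 1e-8)
  # missing truth errors
  no_truth <- complex_instance("nt", "e1", matrix(0, 1, 5))
  expect_error(model_loss(list(no_truth), fx$params, fx$config, fx$vocab),
               "true stoichiometry")
})

test_that("analytic gradients match central finite differences", {
  set.seed(21)
  fx <- tiny_fitted(10)
  batch <- list(random_instance(1L), random_instance(2L),
                random_instance(3L), random_instance(2L))
  err <- gradient_check(batch, fx$params, fx$config, fx$vocab, eps = 1e-5)
  expect_lt(err, 1e-4)
})

test_that("training is seed-reproducible and learns the planted signal", {
  cfg <- synth_config(300, d_in = 8L, max_entities = 2L, K_max = 4L,
                      noise_sd = 0.5, seed = 5L)
  ds <- generate_dataset(cfg)
  sp <- make_splits(ds, c(0.7, 0.15, 0.15), seed = 5L)
  mc <- model_config(d_in = 8L, d_model = 16L, n_layers = 1L, n_heads = 2L,
                     K_max = 4L, dropout_rate = 0.1, expert_counts = 2:3)
  m1 <- train_model(sp$train, mc, valid = sp$valid, seed = 9L, epochs = 2L,
                    batch_size = 32L, min_count = 5L)
  m2 <- train_model(sp$train, mc, valid = sp$valid, seed = 9L, epochs = 2L,
                    batch_size = 32L, min_count = 5L)
  expect_identical(m1$history$loss[1], m2$history$loss[1])
  expect_identical(m1$params, m2$params)
  # a few more epochs beat the frequency baseline on this separable task
  m3 <- train_model(sp$train, mc, valid = sp$valid, seed = 9L, epochs = 8L,
                    batch_size = 32L, min_count = 5L)
  test_truth <- vapply(sp$test, function(x) format_stoich(x$true_copies),
                       character(1))
  preds <- predict_many(sp$test, m3, n_out = 1L)
  acc <- top_n_accuracy(preds, test_truth, 1L)
  tab <- build_frequency_table(lapply(sp$train, function(x) x$true_copies))
  naive <- naive_evaluate(test_truth, tab, n_values = 1L, n_runs = 20L,
                          seed = 1L)$mean_top_n[["top1"]]
  expect_gt(acc, naive)
})

test_that("instances beyond the copy-number class space are excluded", {
  fx <- tiny_fitted(11)
  big <- complex_instance("big", "e1", matrix(rnorm(5), 1),
                          true_copies = 9L)  # K_max = 4
  expect_warning(
    m <- train_model(c(fx$train[1:4], list(big)), fx$config, seed = 1L,
                     epochs = 1L, min_count = 1L),
    "exceed K_max"
  )
  expect_error(model_loss(list(big), fx$params, fx$config, fx$vocab),
               "K_max")
})
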
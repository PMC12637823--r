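# Candidate ranking: chain probabilities, beam search vs exhaustive
# enumeration, the weighted score combination, and end-to-end prediction.

test_that("chain probability is the product over chains", {
  D <- rbind(c(0.6, 0.4), c(0.5, 0.5))
  expect_equal(chain_probability(c(1L, 2L), D), 0.3)
  # one-hot certainty
  expect_identical(chain_probability(c(2L, 1L), rbind(c(0, 1), c(1, 0))), 1)
  # single chain reduces to that chain's class probability
  expect_identical(chain_probability(2L, matrix(c(0.3, 0.7), 1)), 0.7)
  expect_error(chain_probability(c(1L, 3L), D), "class range")
})

test_that("beam search equals exhaustive enumeration with exact tie-breaks", {
  set.seed(31)
  for (r in 1:100) {
    C <- sample.int(3L, 1L)
    K <- sample.int(4L, 1L)
    D <- random_distribution_matrix(C, K)
    n_states <- K^C
    bc <- beam_candidates(D, n_out = n_states, beam_width = 64L)
    oracle <- brute_force_ranking(D)
    expect_identical(bc$stoichiometry, oracle$stoichiometry)
    expect_identical(bc$chain_prob, oracle$chain_prob)
  }
})

test_that("beam search hand fixtures, ties, and argmax case", {
  D <- rbind(c(0.6, 0.4), c(0.5, 0.5))
  bc <- beam_candidates(D, n_out = 4L)
  expect_identical(bc$stoichiometry, c("A1B1", "A1B2", "A2B1", "A2B2"))
  expect_equal(bc$chain_prob, c(0.3, 0.3, 0.2, 0.2))
  onehot <- rbind(c(0, 1, 0), c(1, 0, 0))
  expect_identical(beam_candidates(onehot, n_out = 1L)$stoichiometry, "A2B1")
  expect_error(beam_candidates(D, n_out = 5L, beam_width = 2L), "beam_width")
})

test_that("beam probabilities agree with chain_probability bit for bit", {
  set.seed(32)
  D <- random_distribution_matrix(3L, 4L)
  bc <- beam_candidates(D, n_out = 10L)
  for (i in seq_len(nrow(bc))) {
    expect_identical(bc$chain_prob[i],
                     chain_probability(parse_stoich(bc$stoichiometry[i]), D))
  }
})

test_that("score combination follows the weighted sum and its limits", {
  cands <- data.frame(stoichiometry = c("A1B1", "A2B3"),
                      chain_prob = c(0.5, 0.4), stringsAsFactors = FALSE)
  gdist <- c("1-1" = 0.2, "3-2" = 0.7, other = 0.1)
  out <- combine_scores(cands, gdist, alpha = 0.7)
  expect_equal(out$score[out$stoichiometry == "A1B1"],
               0.7 * 0.2 + 0.3 * 0.5)  # 0.29
  expect_equal(out$score[out$stoichiometry == "A2B3"],
               0.7 * 0.7 + 0.3 * 0.4)
  set.seed(33)
  for (r in 1:100) {
    n <- sample(2:6, 1)
    # distinct random candidate states over 2 chains
    sts <- unique(replicate(n, format_stoich(sample.int(4L, 2L, TRUE))))
    cd <- data.frame(stoichiometry = sts, chain_prob = runif(length(sts)),
                     stringsAsFactors = FALSE)
    gd <- c("2-1" = 0.4, "3-3" = 0.3, other = 0.3)
    # alpha = 0: pure chain ranking
    o0 <- combine_scores(cd, gd, alpha = 0)
    expect_identical(
      o0$stoichiometry,
      cd$stoichiometry[order(-cd$chain_prob, cd$stoichiometry,
                             method = "radix")]
    )
    # alpha = 1: pure global ranking
    o1 <- combine_scores(cd, gd, alpha = 1)
    expect_identical(
      o1$stoichiometry,
      o1$stoichiometry[order(-o1$global_prob, o1$stoichiometry,
                             method = "radix")]
    )
  }
})

test_that("unlisted compositions split the 'other' mass without recounting", {
  cands <- data.frame(stoichiometry = c("A1B1", "A4B4", "A4B3"),
                      chain_prob = c(0.5, 0.1, 0.1), stringsAsFactors = FALSE)
  gdist <- c("1-1" = 0.6, other = 0.4)
  out <- combine_scores(cands, gdist, alpha = 1)
  unl <- out$global_prob[out$stoichiometry != "A1B1"]
  expect_equal(unl, c(0.2, 0.2))
  expect_lte(sum(out$global_prob), 1 + 1e-12)
})

test_that("combined score is monotone in both probabilities", {
  set.seed(34)
  for (r in 1:30) {
    g <- runif(1); cp <- runif(1); a <- runif(1)
    s0 <- a * g + (1 - a) * cp
    expect_gte(a * (g + runif(1) * (1 - g)) + (1 - a) * cp, s0)
    expect_gte(a * g + (1 - a) * (cp + runif(1) * (1 - cp)), s0)
  }
})

test_that("prediction handles homomers, ablations, and entity relabeling", {
  fx <- tiny_fitted(12)
  set.seed(41)
  homo <- random_instance(1L, id = "homo")
  rp <- predict_stoichiometry(homo, fx$model, n_out = 3L)
  H <- encode(homo$embeddings, TRUE, fx$params, fx$config)
  dist <- drop(local_head(H, TRUE, fx$params))
  expect_identical(rp$stoichiometry[1], paste0("A", which.max(dist)))
  expect_true(all(diff(rp$score) <= 0))
  expect_true(all(rp$score >= 0 & rp$score <= 1))

  het <- random_instance(2L, id = "het")
  # alpha = 0 reproduces the pure beam ranking
  rp0 <- predict_stoichiometry(het, fx$model, n_out = 4L, alpha = 0)
  Hh <- encode(het$embeddings, rep(TRUE, 2), fx$params, fx$config)
  Dh <- local_head(Hh, rep(TRUE, 2), fx$params)
  bc <- beam_candidates(Dh, n_out = 4L)
  expect_identical(rp0$stoichiometry, bc$stoichiometry)
  # noGlob config forces alpha to zero
  m_noglob <- fx$model
  m_noglob$config <- tiny_config(use_global = FALSE)
  rpng <- predict_stoichiometry(het, m_noglob, n_out = 4L, alpha = 0.5)
  expect_identical(rpng$stoichiometry, bc$stoichiometry)
  # relabeling entities relabels the predicted states correspondingly
  rp1 <- predict_stoichiometry(het, fx$model, n_out = 4L)
  swapped <- complex_instance("het", het$entity_ids[2:1],
                              het$embeddings[2:1, ],
                              true_copies = het$true_copies[2:1])
  rp2 <- predict_stoichiometry(swapped, fx$model, n_out = 4L)
  relabel <- vapply(rp1$stoichiometry, function(s) {
    format_stoich(parse_stoich(s)[2:1])
  }, character(1))
  expect_setequal(rp2$stoichiometry, unname(relabel))
  expect_equal(rp2$score[match(relabel, rp2$stoichiometry)], rp1$score,
               tolerance = 1e-6)
  # missing embedding is a named error
  bad <- het; bad$embeddings[1, 1] <- NA
  expect_error(predict_stoichiometry(bad, fx$model), "het")
})

test_that("alpha selection returns a grid value maximizing validation top-N", {
  fx <- tiny_fitted(15)
  set.seed(43)
  valid <- lapply(1:10, function(i) random_instance(2L))
  a <- select_alpha(fx$model, valid, n_out = 3L, grid = c(0, 0.5, 1))
  expect_true(a %in% c(0, 0.5, 1))
  acc_at <- function(alpha) {
    mean(vapply(valid, function(x) {
      rp <- predict_stoichiometry(x, fx$model, n_out = 3L, alpha = alpha)
      format_stoich(x$true_copies) %in% rp$stoichiometry
    }, logical(1)))
  }
  expect_equal(acc_at(a), max(vapply(c(0, 0.5, 1), acc_at, numeric(1))))
})

test_that("top-N accuracy of predictions is non-decreasing in N", {
  fx <- tiny_fitted(13)
  set.seed(42)
  insts <- lapply(1:12, function(i) random_instance(sample(1:3, 1)))
  preds <- predict_many(insts, fx$model, n_out = 8L)
  truths <- vapply(insts, function(x) format_stoich(x$true_copies),
                   character(1))
  accs <- vapply(1:8, function(N) top_n_accuracy(preds, truths, N),
                 numeric(1))
  expect_true(all(diff(accs) >= 0))
})
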
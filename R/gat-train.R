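# Cross-entropy loss with analytic gradients and the Adam training loop.
#
# Gradients are hand-derived (reverse-mode) for every parameter: the linear
# heads, the mean-pooled mixture-of-experts branch, each attention layer
# (softmax-over-valid-neighbors, additive logits, LeakyReLU, ELU, dropout,
# residual), and the input MLP.  Correctness is guarded by a central
# finite-difference check (see gradient_check()).

local_targets <- function(instances) {
  unlist(lapply(instances, function(x) x$true_copies), use.names = FALSE)
}

global_target_index <- function(instance, vocab) {
  labels <- vocab_labels(vocab, n_entities(instance))
  lab <- composition_label(instance$true_copies)
  i <- match(lab, labels)
  if (is.na(i)) length(labels) else i
}

make_drop_masks <- function(config, N) {
  p <- config$dropout_rate
  if (p <= 0) return(NULL)
  lapply(seq_len(config$n_layers), function(l) {
    matrix(stats::rbinom(N * config$d_model, 1L, 1 - p) / (1 - p),
           N, config$d_model)
  })
}

#' Training loss of the model on a batch of complexes
#'
#' Mean over complexes of the per-chain cross-entropy of the local head
#' (averaged over each complex's subunits), plus `lambda_g` times the mean
#' global cross-entropy over the heteromeric complexes whose subunit count
#' has a dedicated expert.  Every instance must carry `true_copies`;
#' instances with a copy number above `K_max` are rejected (the training
#' loop filters them out beforehand).
#'
#' @param instances List of [complex_instance()] objects with truth.
#' @param params,config,vocab Model parameters, configuration, vocabulary.
#' @param drop_masks Optional per-layer dropout masks (training mode);
#'   `NULL` for deterministic evaluation.
#' @param want_grad If `TRUE`, also return analytic gradients.
#' @return List with `loss` (scalar) and, if requested, `grads` (named list
#'   matching `params`).
#' @export
model_loss <- function(instances, params, config, vocab = NULL,
                       drop_masks = NULL, want_grad = FALSE) {
  if (!length(instances)) stop("empty batch")
  for (x in instances) {
    if (is.null(x$true_copies)) {
      stop("instance ", x$complex_id, " has no true stoichiometry")
    }
  }
  batch <- stack_batch(instances)
  tloc <- local_targets(instances)
  if (any(tloc > config$K_max)) {
    stop("copy number exceeds K_max; filter such instances before training")
  }
  cache <- batch_forward(batch, params, config, vocab, drop_masks)
  B <- length(instances)
  N <- batch$N
  P <- cache$local_probs
  idx <- cbind(seq_len(N), tloc)
  w_row <- 1 / (B * batch$Cs[batch$group])
  loss_local <- sum(-log(pmax(P[idx], 1e-300)) * w_row)

  # global term over qualifying heteromers
  qual <- which(!vapply(cache$global, is.null, logical(1)))
  loss_global <- 0
  gtargets <- integer(0)
  if (length(qual) && !is.null(vocab)) {
    gtargets <- vapply(instances[qual], global_target_index, integer(1),
                       vocab = vocab)
    pg <- vapply(seq_along(qual), function(i) {
      cache$global[[qual[i]]]$probs[gtargets[i]]
    }, numeric(1))
    loss_global <- mean(-log(pmax(pg, 1e-300)))
  }
  loss <- loss_local + config$lambda_g * loss_global
  if (!is.finite(loss)) stop("non-finite training loss")
  if (!want_grad) return(list(loss = loss))

  grads <- zero_like(params)
  # local head backward
  dL <- P
  dL[idx] <- dL[idx] - 1
  dL <- dL * w_row
  grads[["local.W"]] <- t(cache$H) %*% dL
  grads[["local.b"]] <- colSums(dL)
  dH <- dL %*% t(params[["local.W"]])

  # global head backward
  if (length(qual) && !is.null(vocab)) {
    wq <- config$lambda_g / length(qual)
    dpooled <- matrix(0, B, config$d_model)
    for (i in seq_along(qual)) {
      b <- qual[i]
      C <- batch$Cs[b]
      g <- cache$global[[b]]
      m <- length(g$probs)
      dlog <- g$probs
      dlog[gtargets[i]] <- dlog[gtargets[i]] - 1
      dlog <- dlog * wq
      nmW <- sprintf("expert%d.W", C); nmb <- sprintf("expert%d.b", C)
      grads[[nmW]] <- grads[[nmW]] +
        outer(cache$pooled[b, ], dlog[seq_len(m - 1L)])
      grads[[nmb]] <- grads[[nmb]] + dlog[seq_len(m - 1L)]
      grads[["shared.W"]] <- grads[["shared.W"]] + cache$pooled[b, ] * dlog[m]
      grads[["shared.b"]] <- grads[["shared.b"]] + dlog[m]
      dpooled[b, ] <- drop(params[[nmW]] %*% dlog[seq_len(m - 1L)]) +
        params[["shared.W"]] * dlog[m]
    }
    dH <- dH + dpooled[batch$group, , drop = FALSE] / batch$Cs[batch$group]
  }

  # attention layers backward (reverse order)
  if (config$use_gat) {
    for (l in rev(seq_len(config$n_layers))) {
      cl <- cache$layers[[l]]
      dD <- dH
      dV <- if (is.null(cl$drop_mask)) dD else dD * cl$drop_mask
      dU <- dV * delu(cl$U)
      grads[[sprintf("gat%d.bo", l)]] <- colSums(dU)
      grads[[sprintf("gat%d.Wo", l)]] <- t(cl$G) %*% dU
      Wo <- params[[sprintf("gat%d.Wo", l)]]
      dG <- dU %*% t(Wo)
      dH_in <- dH  # residual path
      for (h in seq_len(config$n_heads)) {
        cols <- ((h - 1L) * config$d_h + 1L):(h * config$d_h)
        dAgg <- dG[, cols, drop = FALSE]
        hd <- cl$heads[[h]]
        W <- params[[sprintf("gat%d.h%d.W", l, h)]]
        a_src <- params[[sprintf("gat%d.h%d.a_src", l, h)]]
        a_dst <- params[[sprintf("gat%d.h%d.a_dst", l, h)]]
        dA <- dAgg %*% t(hd$Z)
        dZ <- t(hd$A) %*% dAgg
        r <- rowSums(dA * hd$A)
        dE <- hd$A * (dA - r)
        dEraw <- dE * dleaky_relu(hd$Eraw)
        ds <- rowSums(dEraw)
        dt <- colSums(dEraw)
        dZ <- dZ + outer(ds, a_src) + outer(dt, a_dst)
        grads[[sprintf("gat%d.h%d.a_src", l, h)]] <- drop(t(hd$Z) %*% ds)
        grads[[sprintf("gat%d.h%d.a_dst", l, h)]] <- drop(t(hd$Z) %*% dt)
        grads[[sprintf("gat%d.h%d.W", l, h)]] <- t(cl$H_in) %*% dZ
        dH_in <- dH_in + dZ %*% t(W)
      }
      dH <- dH_in
    }
  }

  # input MLP backward (re-derive cheap intermediates)
  A1 <- sweep(batch$X %*% params[["mlp.W1"]], 2L, params[["mlp.b1"]], "+")
  R1 <- pmax(A1, 0)
  grads[["mlp.W2"]] <- t(R1) %*% dH
  grads[["mlp.b2"]] <- colSums(dH)
  dR1 <- dH %*% t(params[["mlp.W2"]])
  dA1 <- dR1 * (A1 > 0)
  grads[["mlp.W1"]] <- t(batch$X) %*% dA1
  grads[["mlp.b1"]] <- colSums(dA1)

  list(loss = loss, grads = grads)
}

#' Compare analytic and finite-difference gradients
#'
#' Central finite differences of [model_loss()] with respect to every
#' parameter entry, compared against the analytic gradient.  Intended for
#' tiny models (every entry costs two forward passes).
#'
#' @inheritParams model_loss
#' @param eps Finite-difference step.
#' @return Maximum relative error
#'   `|g_fd - g_an| / max(1e-8, |g_fd| + |g_an|)` over all entries.
#' @export
gradient_check <- function(instances, params, config, vocab = NULL,
                           eps = 1e-5) {
  an <- model_loss(instances, params, config, vocab, want_grad = TRUE)
  g_an <- flatten_params(an$grads)
  theta <- flatten_params(params)
  g_fd <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- theta[i] + eps
    lp <- model_loss(instances, unflatten_params(tp, params), config, vocab)$loss
    tm <- theta; tm[i] <- theta[i] - eps
    lm <- model_loss(instances, unflatten_params(tm, params), config, vocab)$loss
    g_fd[i] <- (lp - lm) / (2 * eps)
  }
  max(abs(g_fd - g_an) / pmax(1e-8, abs(g_fd) + abs(g_an)))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the stoichiometry model
#'
#' Minibatch Adam on the joint local + global cross-entropy.  All
#' randomness (initialization, shuffling, dropout) derives from `seed`, so
#' repeated runs are bit-for-bit reproducible.  With a validation set,
#' training keeps the parameters with the best validation top-1 accuracy
#' and stops early after `patience` epochs without improvement.
#'
#' @param train List of [complex_instance()] objects with truth.
#' @param config A [model_config()].
#' @param valid Optional validation list for early stopping.
#' @param vocab Optional [build_global_vocab()]; built from `train` when
#'   `NULL` and the config uses the global head.
#' @param seed Integer seed.
#' @param epochs Maximum training epochs.
#' @param batch_size Complexes per minibatch.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience (epochs).
#' @param min_count Vocabulary threshold when building `vocab` internally.
#' @param verbose Print per-epoch progress.
#' @return A list of class `"stoich_model"` with elements `params`,
#'   `config`, `vocab`, and `history` (per-epoch loss and validation
#'   accuracy).
#' @export
train_model <- function(train, config, valid = NULL, vocab = NULL,
                        seed = 1L, epochs = 30L, batch_size = 32L,
                        lr = 1e-3, patience = 5L, min_count = 10L,
                        verbose = FALSE) {
  if (!length(train)) stop("empty training set")
  over <- vapply(train, function(x) any(x$true_copies > config$K_max),
                 logical(1))
  if (any(over)) {
    warning(sum(over), " training complexes exceed K_max and were excluded")
    train <- train[!over]
  }
  if (!length(train)) stop("no trainable instances after K_max filtering")
  if (is.null(vocab) && config$use_global) {
    vocab <- build_global_vocab(train, config$expert_counts, min_count)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  params <- init_params(config, vocab, seed = stats::runif(1) * 1e6)
  state <- list(m = zero_like(params), v = zero_like(params), t = 0L)
  n <- length(train)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_top1 = numeric(0))
  stale <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1L, n)]
      binst <- train[ids]
      Ntot <- sum(vapply(binst, n_entities, integer(1)))
      dm <- make_drop_masks(config, Ntot)
      res <- model_loss(binst, params, config, vocab, drop_masks = dm,
                        want_grad = TRUE)
      upd <- adam_step(params, res$grads, state, lr)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + res$loss
      nb <- nb + 1L
    }
    val_acc <- NA_real_
    if (!is.null(valid) && length(valid)) {
      model_now <- structure(list(params = params, config = config,
                                  vocab = vocab), class = "stoich_model")
      val_acc <- top1_accuracy(model_now, valid)
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, params = params, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                         val_top1 = val_acc))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  val top-1 %s", ep, ep_loss / nb,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
    if (!is.null(valid) && stale >= patience) break
  }
  if (!is.null(valid) && is.finite(best$acc)) params <- best$params
  structure(list(params = params, config = config, vocab = vocab,
                 history = history),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> d_model =", x$config$d_model,
      ", layers =", x$config$n_layers,
      ", heads =", x$config$n_heads,
      ", K_max =", x$config$K_max,
      ifelse(x$config$use_gat, "", ", noGAT"),
      ifelse(x$config$use_global, "", ", noGlob"), "\n")
  invisible(x)
}

# top-1 accuracy of a model on labelled instances (used for early stopping)
top1_accuracy <- function(model, instances, n_out = 1L) {
  hits <- vapply(instances, function(x) {
    rp <- predict_stoichiometry(x, model, n_out = n_out)
    truth <- format_stoich(x$true_copies)
    truth %in% rp$stoichiometry[seq_len(min(n_out, nrow(rp)))]
  }, logical(1))
  mean(hits)
}
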
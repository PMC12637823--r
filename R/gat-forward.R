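# Forward pass of the graph-attention encoder and its two heads.
#
# All computations run on a "stacked" layout: the subunit rows of every
# complex in a batch are stacked into one N x d matrix, `group` maps each
# row to its complex, and `valid` flags real (non-padded) rows.  Attention
# is restricted to pairs (i, j) with group[i] == group[j], i != j, both
# valid; everything else is masked to -Inf before the softmax, so a row's
# output can never depend on padded rows or on other complexes.

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
dleaky_relu <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
delu <- function(x) ifelse(x > 0, 1, exp(x))

softmax_rows <- function(L) {
  m <- apply(L, 1L, max)
  m[!is.finite(m)] <- 0
  E <- exp(L - m)
  E / rowSums(E)
}

# row softmax where -Inf entries are excluded; rows with no finite entry
# become exact zero rows (the C = 1 / empty-neighborhood convention)
masked_softmax_rows <- function(E) {
  N <- nrow(E)
  m <- apply(E, 1L, max)
  empty <- !is.finite(m)
  m[empty] <- 0
  W <- exp(E - m)
  W[E == -Inf] <- 0
  rs <- rowSums(W)
  W / ifelse(rs > 0, rs, 1)
}

# pairwise validity mask: same complex, distinct rows, both valid
pair_mask <- function(group, valid) {
  same <- outer(group, group, "==")
  vv <- outer(valid, valid, "&")
  m <- same & vv
  diag(m) <- FALSE
  m
}

#' Row-wise input MLP
#'
#' Transforms each subunit embedding independently with a two-layer
#' perceptron (ReLU hidden layer), producing the initial node
#' representation of the attention encoder.  Because the map is applied row
#' by row, output row `c` depends only on input row `c`.
#'
#' @param X Numeric matrix, one row per subunit (C x d_in).
#' @param params Parameter list from [init_params()].
#' @return C x d_model matrix.
#' @export
embed_inputs <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(params[["mlp.W1"]])) {
    stop("input dimension ", ncol(X), " does not match model d_in ",
         nrow(params[["mlp.W1"]]))
  }
  A1 <- sweep(X %*% params[["mlp.W1"]], 2L, params[["mlp.b1"]], "+")
  R1 <- pmax(A1, 0)
  sweep(R1 %*% params[["mlp.W2"]], 2L, params[["mlp.b2"]], "+")
}

#' Additive attention logits for one head
#'
#' Computes `e[c, c'] = LeakyReLU(a_src . z_c + a_dst . z_c')` for every
#' subunit pair, then masks self-pairs and pairs involving invalid
#' (padded) subunits to `-Inf` so they are excluded from the softmax.
#'
#' @param Z C x d_h matrix of per-head projected node features.
#' @param a_src,a_dst Length-d_h attention vectors for the source and
#'   destination roles.
#' @param mask Logical length-C vector flagging valid subunits.
#' @return C x C matrix of masked attention logits.
#' @export
attention_logits <- function(Z, a_src, a_dst, mask = rep(TRUE, nrow(Z))) {
  Z <- as.matrix(Z)
  if (!any(mask)) stop("at least one subunit must be valid")
  s <- drop(Z %*% a_src)
  t <- drop(Z %*% a_dst)
  E <- leaky_relu(outer(s, rep(1, length(t))) + outer(rep(1, length(s)), t))
  pm <- pair_mask(rep(1L, nrow(Z)), mask)
  E[!pm] <- -Inf
  E
}

#' Normalize attention logits into weights
#'
#' Row-wise softmax over the valid neighbors only.  A row with no valid
#' neighbor (a single-subunit complex, or a padded row) becomes an exact
#' zero row, so the aggregated neighbor feature is the zero vector and the
#' node flows through the residual path untouched by attention.
#'
#' @param logits Masked logits from [attention_logits()].
#' @return Row-stochastic (or zero-row) C x C matrix.
#' @export
attention_weights <- function(logits) {
  masked_softmax_rows(as.matrix(logits))
}

# one attention layer on the stacked layout; returns output and cache
gat_layer_forward <- function(H, pm, valid, layer_params, config,
                              drop_mask = NULL) {
  N <- nrow(H)
  heads <- vector("list", config$n_heads)
  G <- matrix(0, N, config$d_model)
  for (h in seq_len(config$n_heads)) {
    W <- layer_params[[sprintf("h%d.W", h)]]
    a_src <- layer_params[[sprintf("h%d.a_src", h)]]
    a_dst <- layer_params[[sprintf("h%d.a_dst", h)]]
    Z <- H %*% W
    s <- drop(Z %*% a_src)
    t <- drop(Z %*% a_dst)
    Eraw <- matrix(s, N, N) + matrix(t, N, N, byrow = TRUE)
    E <- leaky_relu(Eraw)
    E[!pm] <- -Inf
    A <- masked_softmax_rows(E)
    Agg <- A %*% Z
    cols <- ((h - 1L) * config$d_h + 1L):(h * config$d_h)
    G[, cols] <- Agg
    heads[[h]] <- list(Z = Z, Eraw = Eraw, A = A)
  }
  U <- sweep(G %*% layer_params[["Wo"]], 2L, layer_params[["bo"]], "+")
  V <- elu(U)
  D <- if (is.null(drop_mask)) V else V * drop_mask
  Hout <- D + H
  Hout[!valid, ] <- H[!valid, , drop = FALSE]
  list(H = Hout, G = G, U = U, heads = heads, H_in = H)
}

#' Apply one graph-attention layer
#'
#' Per head, neighbor features are aggregated with softmax-normalized
#' additive attention weights; head outputs are concatenated, linearly
#' projected, passed through ELU (and dropout during training), and added
#' to the input through a residual connection.  Padded rows pass through
#' unchanged.
#'
#' @param H C x d_model input representations.
#' @param mask Logical validity vector of length C.
#' @param params Full parameter list.
#' @param config [model_config()].
#' @param layer Layer index (1-based), selecting the layer's parameters.
#' @param drop_mask Optional dropout mask (same shape as `H`), already
#'   scaled by `1 / (1 - dropout_rate)`; `NULL` means evaluation mode.
#' @return C x d_model output representations.
#' @export
gat_layer <- function(H, mask, params, config, layer = 1L, drop_mask = NULL) {
  lp <- layer_param_view(params, layer)
  pm <- pair_mask(rep(1L, nrow(H)), mask)
  out <- gat_layer_forward(as.matrix(H), pm, mask, lp, config, drop_mask)
  if (any(!is.finite(out$H[mask, ]))) {
    stop("non-finite activations in attention layer ", layer)
  }
  out$H
}

layer_param_view <- function(params, l) {
  pref <- sprintf("gat%d.", l)
  sel <- startsWith(names(params), pref)
  v <- params[sel]
  names(v) <- substring(names(v), nchar(pref) + 1L)
  v
}

#' Encode a complex's subunits
#'
#' Runs the input MLP and the stack of attention layers in evaluation mode
#' (no dropout).  With `config$use_gat = FALSE` the attention layers are
#' skipped and each subunit is encoded independently of the others.
#'
#' @inheritParams gat_layer
#' @param X C x d_in embedding matrix.
#' @return C x d_model matrix of final subunit representations.
#' @export
encode <- function(X, mask, params, config) {
  H <- embed_inputs(X, params)
  if (config$use_gat) {
    for (l in seq_len(config$n_layers)) {
      H <- gat_layer(H, mask, params, config, layer = l)
    }
  }
  H
}

#' Local copy-number head
#'
#' Linear classification layer plus softmax, giving each subunit a
#' probability distribution over copy numbers `1..K_max`.
#'
#' @inheritParams gat_layer
#' @param H Encoded representations from [encode()].
#' @return C x K_max row-stochastic matrix.
#' @export
local_head <- function(H, mask, params) {
  L <- sweep(as.matrix(H) %*% params[["local.W"]], 2L, params[["local.b"]], "+")
  softmax_rows(L)
}

#' Global composition head (conditional mixture of experts)
#'
#' Subunit representations are mean-pooled over the valid rows (a symmetric
#' operation, so the output is invariant to subunit order) and routed to
#' the expert dedicated to the complex's subunit count C.  The expert's
#' logits over the known compositions for that count are joined with the
#' shared expert's logit for the `"other"` class in a single softmax.  When
#' no dedicated expert exists for C, the shared expert alone produces the
#' distribution, which then consists of the single `"other"` class.
#'
#' @inheritParams gat_layer
#' @param H Encoded representations.
#' @param vocab A [build_global_vocab()] result.
#' @return Named probability vector over `vocab` labels for C (with
#'   `"other"` last).
#' @export
global_head <- function(H, mask, params, config, vocab) {
  C <- sum(mask)
  labels <- vocab_labels(vocab, C)
  pooled <- colMeans(as.matrix(H)[mask, , drop = FALSE])
  shared_logit <- drop(pooled %*% params[["shared.W"]]) + params[["shared.b"]]
  if (!has_expert(config, vocab, C)) {
    p <- 1
    names(p) <- "other"
    return(p)
  }
  W <- params[[sprintf("expert%d.W", C)]]
  b <- params[[sprintf("expert%d.b", C)]]
  logits <- c(drop(pooled %*% W) + b, shared_logit)
  p <- drop(softmax_rows(matrix(logits, 1L)))
  names(p) <- labels
  p
}

# ---- batched forward over a list of instances ------------------------------

# stacks instances into the flat layout used by training and prediction
stack_batch <- function(instances) {
  Cs <- vapply(instances, n_entities, integer(1))
  group <- rep(seq_along(instances), Cs)
  X <- do.call(rbind, lapply(instances, function(x) x$embeddings))
  list(X = X, group = group, Cs = Cs, N = nrow(X))
}

batch_forward <- function(batch, params, config, vocab, drop_masks = NULL) {
  X <- batch$X
  H <- embed_inputs(X, params)
  cache <- list(X = X, H0 = H, layers = list())
  valid <- rep(TRUE, batch$N)
  pm <- pair_mask(batch$group, valid)
  if (config$use_gat) {
    for (l in seq_len(config$n_layers)) {
      lp <- layer_param_view(params, l)
      dm <- if (is.null(drop_masks)) NULL else drop_masks[[l]]
      out <- gat_layer_forward(H, pm, valid, lp, config, dm)
      out$drop_mask <- dm
      cache$layers[[l]] <- out
      H <- out$H
    }
  }
  cache$H <- H
  # local head
  L <- sweep(H %*% params[["local.W"]], 2L, params[["local.b"]], "+")
  cache$local_logits <- L
  cache$local_probs <- softmax_rows(L)
  # pooled per complex
  pooled <- rowsum(H, batch$group, reorder = TRUE) / batch$Cs
  cache$pooled <- pooled
  # global logits for complexes with a dedicated expert
  glob <- vector("list", length(batch$Cs))
  if (!is.null(vocab)) {
    for (b in seq_along(batch$Cs)) {
      C <- batch$Cs[b]
      if (!has_expert(config, vocab, C)) next
      W <- params[[sprintf("expert%d.W", C)]]
      bb <- params[[sprintf("expert%d.b", C)]]
      logits <- c(drop(pooled[b, ] %*% W) + bb,
                  drop(pooled[b, ] %*% params[["shared.W"]]) + params[["shared.b"]])
      glob[[b]] <- list(logits = logits,
                        probs = drop(softmax_rows(matrix(logits, 1L))))
    }
  }
  cache$global <- glob
  cache
}
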
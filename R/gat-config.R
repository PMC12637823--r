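#' Model configuration
#'
#' Hyperparameters of the graph-attention stoichiometry model.  The encoder
#' is an input MLP followed by `n_layers` masked multi-head additive
#' attention layers over the subunits of a complex; `d_model` must be
#' divisible by `n_heads` and each head works in `d_h = d_model / n_heads`
#' dimensions.  `use_gat = FALSE` disables the attention layers (each
#' subunit is then encoded independently) and `use_global = FALSE` disables
#' the global composition head at prediction time; these two switches
#' realize the model's ablation variants.
#'
#' @param d_in Input embedding dimension.
#' @param d_model Hidden dimension of the encoder.
#' @param n_layers Number of attention layers (>= 1).
#' @param n_heads Attention heads per layer.
#' @param K_max Number of local copy-number classes (copy numbers 1..K_max).
#' @param dropout_rate Dropout probability applied inside each layer during
#'   training.
#' @param max_chains Padding size for fixed-width batch layouts.
#' @param use_gat Enable inter-subunit attention.
#' @param use_global Enable the global composition head at inference.
#' @param alpha Weight of the global probability in the combined score,
#'   in `[0, 1]`.
#' @param expert_counts Subunit counts with a dedicated global expert.
#' @param lambda_g Weight of the global cross-entropy term in the loss.
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(d_in,
                         d_model = 256L,
                         n_layers = 3L,
                         n_heads = 4L,
                         K_max = 12L,
                         dropout_rate = 0.1,
                         max_chains = 16L,
                         use_gat = TRUE,
                         use_global = TRUE,
                         alpha = 0.5,
                         expert_counts = 2:5,
                         lambda_g = 1.0) {
  d_in <- as.integer(d_in); d_model <- as.integer(d_model)
  n_layers <- as.integer(n_layers); n_heads <- as.integer(n_heads)
  K_max <- as.integer(K_max); max_chains <- as.integer(max_chains)
  if (d_in < 1L || d_model < 1L) stop("dimensions must be >= 1")
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  if (K_max < 1L) stop("K_max must be >= 1")
  if (max_chains < 1L) stop("max_chains must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(
    list(
      d_in = d_in, d_model = d_model, n_layers = n_layers,
      n_heads = n_heads, d_h = d_model %/% n_heads, K_max = K_max,
      dropout_rate = dropout_rate, max_chains = max_chains,
      use_gat = isTRUE(use_gat), use_global = isTRUE(use_global),
      alpha = alpha, expert_counts = as.integer(expert_counts),
      lambda_g = lambda_g
    ),
    class = "model_config"
  )
}

#' Build the global composition vocabulary from training data
#'
#' For each subunit count `C` in `expert_counts`, the dedicated global
#' expert classifies over the compositions observed at least `min_count`
#' times among the training complexes with that count, plus a trailing
#' `"other"` class that absorbs rarer or unseen compositions.
#'
#' @param instances List of [complex_instance()] objects with `true_copies`.
#' @param expert_counts Subunit counts that get a dedicated expert.
#' @param min_count Minimum training occurrences for a composition to get
#'   its own class.
#' @return A list of class `"global_vocab"`: per count, the ordered label
#'   vector (most frequent first, `"other"` last).
#' @export
build_global_vocab <- function(instances, expert_counts = 2:5, min_count = 10L) {
  labs <- list()
  for (C in expert_counts) {
    comps <- vapply(
      Filter(function(x) !is.null(x$true_copies) && n_entities(x) == C, instances),
      function(x) composition_label(x$true_copies), character(1)
    )
    if (length(comps)) {
      tab <- sort(table(comps), decreasing = TRUE)
      keep <- names(tab)[tab >= min_count]
      # deterministic order: frequency desc, then label
      ord <- order(-as.integer(tab[keep]), keep, method = "radix")
      labs[[as.character(C)]] <- c(keep[ord], "other")
    } else {
      labs[[as.character(C)]] <- "other"
    }
  }
  structure(list(labels = labs, min_count = as.integer(min_count)),
            class = "global_vocab")
}

vocab_labels <- function(vocab, C) {
  if (is.null(vocab)) return(NULL)
  vocab$labels[[as.character(C)]]
}

has_expert <- function(config, vocab, C) {
  C %in% config$expert_counts &&
    !is.null(vocab_labels(vocab, C)) &&
    length(vocab_labels(vocab, C)) > 1L
}

glorot <- function(n_in, n_out, rng_scale = 1) {
  lim <- sqrt(6 / (n_in + n_out)) * rng_scale
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model parameters
#'
#' Weights use Glorot-uniform initialization; biases start at zero.  The
#' parameter set is a flat named list of matrices/vectors so that generic
#' routines (optimizer updates, flattening for gradient checks) can walk it.
#'
#' @param config A [model_config()].
#' @param vocab A [build_global_vocab()] result (or `NULL` for a model
#'   without a global head).
#' @param seed Integer seed controlling the initialization.
#' @return Named list of parameter arrays.
#' @export
init_params <- function(config, vocab = NULL, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p <- list()
  d <- config$d_model
  p[["mlp.W1"]] <- glorot(config$d_in, d)
  p[["mlp.b1"]] <- numeric(d)
  p[["mlp.W2"]] <- glorot(d, d)
  p[["mlp.b2"]] <- numeric(d)
  for (l in seq_len(config$n_layers)) {
    for (h in seq_len(config$n_heads)) {
      p[[sprintf("gat%d.h%d.W", l, h)]] <- glorot(d, config$d_h)
      p[[sprintf("gat%d.h%d.a_src", l, h)]] <-
        stats::runif(config$d_h, -0.3, 0.3)
      p[[sprintf("gat%d.h%d.a_dst", l, h)]] <-
        stats::runif(config$d_h, -0.3, 0.3)
    }
    p[[sprintf("gat%d.Wo", l)]] <- glorot(d, d)
    p[[sprintf("gat%d.bo", l)]] <- numeric(d)
  }
  p[["local.W"]] <- glorot(d, config$K_max)
  p[["local.b"]] <- numeric(config$K_max)
  if (!is.null(vocab)) {
    for (C in config$expert_counts) {
      nlab <- length(vocab_labels(vocab, C))
      if (is.null(nlab) || nlab <= 1L) next
      p[[sprintf("expert%d.W", C)]] <- glorot(d, nlab - 1L)
      p[[sprintf("expert%d.b", C)]] <- numeric(nlab - 1L)
    }
    p[["shared.W"]] <- glorot(d, 1L)
    p[["shared.b"]] <- numeric(1L)
  }
  p
}

# save/restore the global RNG stream so that seeded helpers do not disturb
# the caller's random state
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(theta, template) {
  out <- template
  i <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    vals <- theta[(i + 1L):(i + n)]
    if (is.matrix(template[[nm]])) {
      out[[nm]] <- matrix(vals, nrow(template[[nm]]), ncol(template[[nm]]))
    } else {
      out[[nm]] <- vals
    }
    i <- i + n
  }
  out
}

zero_like <- function(params) {
  lapply(params, function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  })
}
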
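# Ranking candidate stoichiometries: product of chain-level probabilities,
# beam search, and the weighted local/global score combination.

#' Chain-level probability of a stoichiometry state
#'
#' The product over chains of the local head's probability for each chain's
#' copy number.
#'
#' @param copies Integer copy-number vector (length C).
#' @param local_dists C x K matrix of per-chain copy-number distributions.
#' @return The product probability.
#' @export
chain_probability <- function(copies, local_dists) {
  local_dists <- as.matrix(local_dists)
  copies <- as.integer(copies)
  if (length(copies) != nrow(local_dists)) {
    stop("one copy number per chain required")
  }
  if (any(copies < 1L) || any(copies > ncol(local_dists))) {
    stop("copy number outside the class range 1..", ncol(local_dists))
  }
  # left-to-right accumulation in double precision, matching the stepwise
  # products of beam_candidates() bit for bit
  Reduce(`*`, local_dists[cbind(seq_along(copies), copies)])
}

#' Beam search over per-chain copy-number distributions
#'
#' Finds the `n_out` stoichiometry states with the highest product of
#' chain-level probabilities.  Chains are processed left to right keeping
#' the `beam_width` best partial assignments; whenever
#' `beam_width >= n_out` and the beam is at least as wide as needed, the
#' result matches exhaustive enumeration.  Ties are broken by the
#' lexicographically smaller notation string.
#'
#' @param local_dists C x K matrix of per-chain distributions.
#' @param n_out Number of states to return.
#' @param beam_width Beam width (>= n_out).
#' @return `data.frame` with columns `stoichiometry` and `chain_prob`,
#'   sorted by probability (non-increasing).
#' @export
beam_candidates <- function(local_dists, n_out = 5L,
                            beam_width = max(50L, 10L * n_out)) {
  local_dists <- as.matrix(local_dists)
  C <- nrow(local_dists)
  K <- ncol(local_dists)
  if (beam_width < n_out) stop("beam_width must be >= n_out")
  states <- matrix(seq_len(K), ncol = 1L)
  probs <- local_dists[1L, ]
  keep_top <- function(states, probs, width) {
    if (length(probs) <= width) return(list(states = states, probs = probs))
    key <- apply(states, 1L, function(cp) format_stoich(cp))
    ord <- order(-probs, key, method = "radix")[seq_len(width)]
    list(states = states[ord, , drop = FALSE], probs = probs[ord])
  }
  kept <- keep_top(states, probs, beam_width)
  if (C > 1L) {
    for (cc in 2L:C) {
      nb <- length(kept$probs)
      # extend every kept partial state with every copy number for chain cc
      states <- cbind(kept$states[rep(seq_len(nb), each = K), , drop = FALSE],
                      rep(seq_len(K), times = nb))
      probs <- rep(kept$probs, each = K) * rep(local_dists[cc, ], times = nb)
      kept <- keep_top(states, probs, beam_width)
    }
  }
  key <- apply(kept$states, 1L, format_stoich)
  ord <- order(-kept$probs, key, method = "radix")[seq_len(min(n_out, length(key)))]
  data.frame(stoichiometry = key[ord], chain_prob = kept$probs[ord],
             stringsAsFactors = FALSE)
}

#' Combine chain-level and global probabilities into final scores
#'
#' Each candidate's score is the convex combination
#' `alpha * global_prob + (1 - alpha) * chain_prob`.  The global
#' probability of a candidate is the global head's probability of its
#' composition; candidates whose composition is not in the vocabulary share
#' the `"other"` probability equally, so that mass is not counted more than
#' once.
#'
#' @param candidates `data.frame` from [beam_candidates()].
#' @param global_dist Named probability vector over composition labels
#'   (with `"other"`), as returned by [global_head()].
#' @param alpha Weight of the global probability, in `[0, 1]`.
#' @return `data.frame` with columns `stoichiometry`, `chain_prob`,
#'   `global_prob`, `score`, re-sorted by score.
#' @export
combine_scores <- function(candidates, global_dist, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  labs <- vapply(candidates$stoichiometry,
                 function(s) composition_label(parse_stoich(s)), character(1))
  known <- labs %in% setdiff(names(global_dist), "other")
  gp <- numeric(length(labs))
  gp[known] <- global_dist[labs[known]]
  n_unlisted <- sum(!known)
  if (n_unlisted > 0) {
    other <- if ("other" %in% names(global_dist)) {
      unname(global_dist[["other"]])
    } else 0
    gp[!known] <- other / n_unlisted
  }
  score <- alpha * gp + (1 - alpha) * candidates$chain_prob
  ord <- order(-score, candidates$stoichiometry, method = "radix")
  out <- data.frame(stoichiometry = candidates$stoichiometry[ord],
                    chain_prob = candidates$chain_prob[ord],
                    global_prob = gp[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Predict the stoichiometry of a complex
#'
#' For a homomer (one unique entity) the ranking is the local head's
#' copy-number distribution, since the global composition carries no extra
#' information.  For heteromers, beam search over the product of chain
#' distributions proposes candidates, which are re-scored by the weighted
#' combination with the global composition distribution.  With
#' `use_global = FALSE` in the model config (or `alpha = 0`), the ranking
#' is the pure chain-probability ranking.
#'
#' @param instance A [complex_instance()] (embeddings required).
#' @param model A `"stoich_model"` from [train_model()].
#' @param n_out Number of ranked states to return.
#' @param alpha Override of the combination weight (default: the model
#'   config's).
#' @param beam_width Beam width for candidate generation.
#' @return A [ranked_prediction()] table.
#' @export
predict_stoichiometry <- function(instance, model, n_out = 5L, alpha = NULL,
                                  beam_width = max(50L, 10L * n_out)) {
  config <- model$config
  if (is.null(instance$embeddings) || anyNA(instance$embeddings)) {
    stop("missing embedding for complex ", instance$complex_id)
  }
  if (ncol(instance$embeddings) != config$d_in) {
    stop("embedding dimension ", ncol(instance$embeddings),
         " does not match model d_in ", config$d_in, " for complex ",
         instance$complex_id)
  }
  C <- n_entities(instance)
  mask <- rep(TRUE, C)
  H <- encode(instance$embeddings, mask, model$params, config)
  dists <- local_head(H, mask, model$params)
  if (C == 1L) {
    n <- min(n_out, config$K_max)
    rp <- ranked_prediction(paste0("A", seq_len(config$K_max)), drop(dists))
    return(rp[seq_len(n), , drop = FALSE])
  }
  cands <- beam_candidates(dists, n_out = min(beam_width, n_out * 5L),
                           beam_width = beam_width)
  if (is.null(alpha)) alpha <- config$alpha
  if (!config$use_global || !has_expert(config, model$vocab, C)) alpha <- 0
  if (alpha > 0) {
    gdist <- global_head(H, mask, model$params, config, model$vocab)
    cands <- combine_scores(cands, gdist, alpha)
    score <- cands$score
  } else {
    score <- cands$chain_prob
  }
  rp <- ranked_prediction(cands$stoichiometry, score)
  rp[seq_len(min(n_out, nrow(rp))), , drop = FALSE]
}

#' Predict for a list of complexes
#'
#' @inheritParams predict_stoichiometry
#' @param instances List of [complex_instance()] objects.
#' @return Named list of [ranked_prediction()] tables (by complex id).
#' @export
predict_many <- function(instances, model, n_out = 5L, alpha = NULL,
                         beam_width = max(50L, 10L * n_out)) {
  out <- lapply(instances, predict_stoichiometry, model = model,
                n_out = n_out, alpha = alpha, beam_width = beam_width)
  names(out) <- vapply(instances, function(x) x$complex_id, character(1))
  out
}

#' Select the combination weight alpha on validation data
#'
#' Grid search maximizing validation top-`n_out` accuracy; ties prefer the
#' smaller alpha.
#'
#' @param model A trained `"stoich_model"`.
#' @param valid Labelled validation instances.
#' @param n_out Top-N used as the selection criterion.
#' @param grid Candidate alpha values.
#' @return The selected alpha (scalar).
#' @export
select_alpha <- function(model, valid, n_out = 5L, grid = seq(0, 1, by = 0.1)) {
  accs <- vapply(grid, function(a) {
    hits <- vapply(valid, function(x) {
      rp <- predict_stoichiometry(x, model, n_out = n_out, alpha = a)
      format_stoich(x$true_copies) %in% rp$stoichiometry
    }, logical(1))
    mean(hits)
  }, numeric(1))
  grid[which.max(accs)]
}
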
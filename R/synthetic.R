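# Synthetic complexes with a planted copy-number signal, standing in for
# protein language model embeddings so that the model, baselines, and
# ablations are trainable and testable at desk scale.
#
# Standard mode: each copy number k has a fixed random centroid mu_k in
# R^d_in; an entity with k copies gets embedding mu_k + Gaussian noise, so
# each chain's copy number is decodable from its own embedding.
# Dependency mode: complexes are entity pairs; each entity's embedding
# encodes only its own latent key, while its TRUE copy number equals the
# PARTNER's key — decodable only by passing messages between chains, which
# is what the attention ablation probes.

#' Synthetic dataset configuration
#'
#' @param n_complexes Number of complexes to generate.
#' @param d_in Embedding dimension.
#' @param max_entities Largest number of unique entities per complex.
#' @param K_max Largest copy number generated.
#' @param noise_sd Standard deviation of the isotropic Gaussian noise added
#'   to each centroid (> 0).
#' @param dependency_mode Plant the cross-chain signal described above.
#' @param composition_prior Optional list keyed by entity count (as
#'   character): each element a `data.frame(composition, prob)` over
#'   composition labels (e.g. `"2-1"`).  `NULL` uses a default prior in
#'   which small complexes and small copy numbers dominate, qualitatively
#'   mimicking the imbalance of structural databases.
#' @param seed Integer seed.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(n_complexes, d_in = 32L, max_entities = 4L,
                         K_max = 6L, noise_sd = 1.0,
                         dependency_mode = FALSE,
                         composition_prior = NULL, seed = 1L) {
  n_complexes <- as.integer(n_complexes)
  if (n_complexes < 1L || d_in < 1L || max_entities < 1L || K_max < 1L) {
    stop("all sizes must be >= 1")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(composition_prior)) {
    composition_prior <- default_composition_prior(max_entities, K_max)
  }
  for (df in composition_prior) {
    if (abs(sum(df$prob) - 1) > 1e-8) {
      stop("composition prior probabilities must sum to 1 per entity count")
    }
  }
  structure(
    list(n_complexes = n_complexes, d_in = as.integer(d_in),
         max_entities = as.integer(max_entities), K_max = as.integer(K_max),
         noise_sd = noise_sd, dependency_mode = isTRUE(dependency_mode),
         composition_prior = composition_prior, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# all multisets of size C drawn from 1..K, as non-increasing vectors
enumerate_compositions <- function(C, K) {
  if (C == 1L) return(lapply(seq_len(K), identity))
  out <- list()
  rec <- function(prefix, maxv, left) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(maxv)) rec(c(prefix, v), v, left - 1L)
  }
  rec(integer(0), K, C)
  out
}

#' Default composition prior of the generator
#'
#' Entity counts are weighted `2^-(C-1)` and, within a count, each
#' composition is weighted by the product of `2^-k` over its copy numbers,
#' so monomers/dimers and low copy numbers dominate.
#'
#' @param max_entities,K_max As in [synth_config()].
#' @return List keyed by entity count of `data.frame(composition, prob,
#'   p_count)`.
#' @export
default_composition_prior <- function(max_entities = 4L, K_max = 6L) {
  wC <- 2^(-(seq_len(max_entities) - 1))
  wC <- wC / sum(wC)
  prior <- list()
  for (C in seq_len(max_entities)) {
    comps <- enumerate_compositions(C, K_max)
    w <- vapply(comps, function(cp) prod(2^(-cp)), numeric(1))
    prior[[as.character(C)]] <- data.frame(
      composition = vapply(comps, function(cp) paste(cp, collapse = "-"),
                           character(1)),
      prob = w / sum(w),
      p_count = wC[C],
      stringsAsFactors = FALSE
    )
  }
  prior
}

#' Symmetric ("rare composition") prior for the global-head benchmark
#'
#' A two-entity prior supported only on the symmetric compositions
#' `1-1, 2-2, ..., n_comps-n_comps` (uniform).  Per-chain marginals are
#' broad while the joint is tightly constrained, so ranking by the product
#' of per-chain distributions proposes many compositions that never occur;
#' the global composition head can veto them.  Used with a high noise level
#' (the benchmark uses `noise_sd = 3.5`) so that local predictions are
#' genuinely uncertain.
#'
#' @param n_comps Number of symmetric compositions (copy numbers `1..n_comps`).
#' @return A composition prior for [synth_config()] (entity count 2).
#' @export
rare_composition_prior <- function(n_comps = 4L) {
  list("2" = data.frame(
    composition = paste(seq_len(n_comps), seq_len(n_comps), sep = "-"),
    prob = rep(1 / n_comps, n_comps),
    p_count = 1,
    stringsAsFactors = FALSE
  ))
}

random_sequence <- function(len = 50L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

#' Generate a synthetic dataset
#'
#' @param config A [synth_config()].
#' @return List of [complex_instance()] objects with `true_copies` set.
#'   The copy-number centroids are attached as attributes `"centroids"`
#'   (standard signal) and `"key_centroids"` (dependency mode), enabling
#'   oracle classifiers in tests.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config")) stop("invalid config")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  mu <- matrix(stats::rnorm(config$K_max * config$d_in), config$K_max)
  nu <- matrix(stats::rnorm(config$K_max * config$d_in), config$K_max)
  counts_p <- vapply(seq_len(config$max_entities), function(C) {
    df <- config$composition_prior[[as.character(C)]]
    if (is.null(df)) 0 else df$p_count[1L]
  }, numeric(1))
  if (sum(counts_p) <= 0) counts_p <- rep(1, config$max_entities)
  counts_p <- counts_p / sum(counts_p)
  out <- vector("list", config$n_complexes)
  for (i in seq_len(config$n_complexes)) {
    id <- sprintf("synth%05d", i)
    if (config$dependency_mode) {
      C <- 2L
      keys <- sample.int(config$K_max, C, replace = TRUE)
      copies <- keys[c(2L, 1L)]  # copy number = partner's key
      E <- nu[keys, , drop = FALSE] +
        matrix(stats::rnorm(C * config$d_in, sd = config$noise_sd), C)
    } else {
      C <- sample.int(config$max_entities, 1L, prob = counts_p)
      df <- config$composition_prior[[as.character(C)]]
      lab <- df$composition[sample.int(nrow(df), 1L, prob = df$prob)]
      copies <- composition_to_state(lab, perm = sample.int(C))
      E <- mu[copies, , drop = FALSE] +
        matrix(stats::rnorm(C * config$d_in, sd = config$noise_sd), C)
    }
    out[[i]] <- complex_instance(
      complex_id = id,
      entity_ids = sprintf("%s|e%d", id, seq_len(C)),
      embeddings = E,
      true_copies = copies,
      sequences = vapply(seq_len(C), function(j) random_sequence(),
                         character(1))
    )
  }
  attr(out, "centroids") <- mu
  attr(out, "key_centroids") <- nu
  out
}

#' Split a dataset into train/validation/test
#'
#' Seeded shuffle, then a disjoint and exhaustive partition with sizes
#' proportional to `fractions`.
#'
#' @param dataset List of instances.
#' @param fractions Length-3 non-negative vector summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `valid`, `test`.
#' @export
make_splits <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be 3 non-negative values summing to 1")
  }
  n <- length(dataset)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  bounds <- round(cumsum(fractions) * n)
  starts <- c(0, bounds[1:2])
  take <- function(k) {
    if (bounds[k] > starts[k]) dataset[ord[(starts[k] + 1L):bounds[k]]]
    else list()
  }
  list(train = take(1L), valid = take(2L), test = take(3L))
}
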
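# Shared fixtures: tiny models and random complexes built in code.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(d_in = 5L, d_model = 8L, n_layers = 2L, n_heads = 2L,
                   K_max = 4L, dropout_rate = 0, expert_counts = 2:3)
  do.call(model_config, utils::modifyList(defaults, args))
}

random_instance <- function(C, d_in = 5L, K_max = 4L, id = NULL) {
  if (is.null(id)) id <- paste0("cx", paste(sample(letters, 8, TRUE), collapse = ""))
  complex_instance(
    complex_id = id,
    entity_ids = paste0("e", seq_len(C)),
    embeddings = matrix(stats::rnorm(C * d_in), C),
    true_copies = sample.int(K_max, C, replace = TRUE)
  )
}

# a small labelled training set covering several subunit counts
random_training_set <- function(n = 40L, d_in = 5L, K_max = 4L,
                                counts = c(1L, 2L, 2L, 3L)) {
  lapply(seq_len(n), function(i) {
    random_instance(counts[1L + (i - 1L) %% length(counts)], d_in, K_max,
                    id = sprintf("tr%03d", i))
  })
}

tiny_fitted <- function(seed = 1L) {
  set.seed(seed)
  cfg <- tiny_config()
  train <- random_training_set(40L)
  vocab <- build_global_vocab(train, cfg$expert_counts, min_count = 1L)
  params <- init_params(cfg, vocab, seed = seed)
  list(config = cfg, vocab = vocab, params = params, train = train,
       model = structure(list(params = params, config = cfg, vocab = vocab),
                         class = "stoich_model"))
}

# exhaustive ranking oracle over all K^C states, multiplying probabilities
# left-to-right exactly like the beam does
brute_force_ranking <- function(local_dists) {
  C <- nrow(local_dists); K <- ncol(local_dists)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), C)))
  pr <- rep(1, nrow(grid))
  for (cc in seq_len(C)) pr <- pr * local_dists[cc, grid[, cc]]
  key <- apply(grid, 1L, format_stoich)
  ord <- order(-pr, key, method = "radix")
  data.frame(stoichiometry = key[ord], chain_prob = unname(pr[ord]),
             stringsAsFactors = FALSE)
}

random_distribution_matrix <- function(C, K) {
  D <- matrix(stats::rexp(C * K), C)
  D / rowSums(D)
}

# minimal assembly metadata table builder (one row per entity)
assembly_rows <- function(assembly_id, date, seqs, copies,
                          polymer = "polypeptide(L)", support = TRUE) {
  data.frame(
    assembly_id = assembly_id, date = date,
    entity_id = paste0(assembly_id, "_e", seq_along(seqs)),
    polymer_type = rep_len(polymer, length(seqs)),
    sequence = seqs, copies = copies,
    experimental_support = support,
    stringsAsFactors = FALSE
  )
}
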
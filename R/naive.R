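# Frequency baseline: rank compositions by their training-set frequency
# within each subunit count, with random assignment of copy numbers to
# chains (shuffle-and-average evaluation protocol).

#' Build a composition frequency table from training stoichiometries
#'
#' Counts, for each subunit count C, how often each composition (the
#' entity-agnostic multiset of copy numbers) occurs among the training
#' complexes with that count; the frequency of composition S is
#' `N_S / N_C`.
#'
#' @param training_states List (or character vector) of stoichiometry
#'   states: copy-number vectors or notation strings.
#' @return A list of class `"frequency_table"`: per count C, a
#'   `data.frame(composition, count, freq)` sorted by frequency
#'   (decreasing, ties by label).
#' @export
build_frequency_table <- function(training_states) {
  if (!length(training_states)) stop("empty training list")
  if (is.character(training_states)) {
    training_states <- lapply(training_states, parse_stoich)
  }
  comps <- vapply(training_states, composition_label, character(1))
  Cs <- vapply(training_states, length, integer(1))
  tab <- list()
  for (C in sort(unique(Cs))) {
    t0 <- table(comps[Cs == C])
    df <- data.frame(composition = names(t0), count = as.integer(t0),
                     stringsAsFactors = FALSE)
    df$freq <- df$count / sum(df$count)
    df <- df[order(-df$freq, df$composition, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    tab[[as.character(C)]] <- df
  }
  structure(list(by_count = tab), class = "frequency_table")
}

# instantiate a composition as a concrete state for C entities, assigning
# the copy numbers to entity slots in the given order
composition_to_state <- function(label, perm = NULL) {
  copies <- as.integer(strsplit(label, "-", fixed = TRUE)[[1]])
  if (!is.null(perm)) copies <- copies[perm]
  copies
}

#' Frequency-baseline prediction for a complex with C subunits
#'
#' The top compositions by training frequency are each instantiated as a
#' concrete state by assigning the copy numbers to the entities uniformly
#' at random (homomers need no shuffle).  A subunit count never seen in
#' training yields the all-ones state (one copy per chain).
#'
#' @param C Number of unique subunits.
#' @param table A [build_frequency_table()] result.
#' @param n_out Number of ranked states.
#' @param seed Integer seed for the random assignment.
#' @return A [ranked_prediction()] table (scores are the frequencies).
#' @export
naive_predict <- function(C, table, n_out = 5L, seed = 1L) {
  C <- as.integer(C)
  if (C < 1L) stop("C must be >= 1")
  df <- table$by_count[[as.character(C)]]
  if (is.null(df)) {
    return(ranked_prediction(format_stoich(rep(1L, C)), 1))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- min(n_out, nrow(df))
  states <- character(n)
  for (i in seq_len(n)) {
    perm <- if (C > 1L) sample.int(C) else 1L
    states[i] <- format_stoich(composition_to_state(df$composition[i], perm))
  }
  # distinct compositions can collide as states only if C > 1 and two
  # shuffled compositions coincide -- impossible, compositions differ as
  # multisets; so states are pairwise distinct
  out <- data.frame(stoichiometry = states, score = df$freq[seq_len(n)],
                    rank = seq_len(n), stringsAsFactors = FALSE)
  out
}

#' Shuffle-and-average evaluation of the frequency baseline
#'
#' Repeats the evaluation `n_runs` times with fresh random assignments of
#' composition copy numbers to chains, and reports the mean top-N accuracy
#' for each requested N.  Homomer-only test sets have zero variance across
#' runs since no shuffling applies.
#'
#' @param test_states List (or character vector) of true stoichiometry
#'   states of the test complexes.
#' @param table A [build_frequency_table()] result.
#' @param n_values Integer vector of N values to report.
#' @param n_runs Number of shuffle runs to average over.
#' @param seed Integer seed.
#' @return A list with `mean_top_n` (named by N), `per_run` (matrix runs x
#'   N), and `n_runs`.
#' @export
naive_evaluate <- function(test_states, table, n_values = c(1L, 5L),
                           n_runs = 1000L, seed = 1L) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (is.character(test_states)) {
    test_states <- lapply(test_states, parse_stoich)
  }
  truths <- vapply(test_states, format_stoich, character(1))
  Cs <- vapply(test_states, length, integer(1))
  n_max <- max(n_values)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max, n_runs * length(truths))
  per_run <- matrix(0, n_runs, length(n_values),
                    dimnames = list(NULL, paste0("top", n_values)))
  for (r in seq_len(n_runs)) {
    ranks <- vapply(seq_along(truths), function(i) {
      rp <- naive_predict(Cs[i], table, n_out = n_max,
                          seed = run_seeds[(r - 1L) * length(truths) + i])
      pos <- match(truths[i], rp$stoichiometry)
      if (is.na(pos)) Inf else pos
    }, numeric(1))
    per_run[r, ] <- vapply(n_values, function(N) mean(ranks <= N), numeric(1))
  }
  list(mean_top_n = colMeans(per_run), per_run = per_run, n_runs = n_runs)
}
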
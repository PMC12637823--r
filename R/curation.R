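# Dataset curation: entity filtering, composition deduplication, time
# splits, and redundancy filtering against reference sets using an optimal
# (maximum-total-identity) one-to-one chain mapping.
#
# Assembly records are rows of a metadata table (one row per entity):
# assembly_id, date, entity_id, polymer_type, sequence, copies,
# experimental_support.

#' Read an assembly metadata table
#'
#' @param path TSV with columns `assembly_id`, `date`, `entity_id`,
#'   `polymer_type`, `sequence`, `copies`, `experimental_support`.
#' @return `data.frame` with `date` parsed as `Date`.
#' @export
read_assembly_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("assembly_id", "date", "entity_id", "polymer_type", "sequence",
            "copies", "experimental_support")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- tryCatch(as.Date(df$date), error = function(e) NA)
  if (anyNA(d)) stop("unparseable deposition date(s)")
  df$date <- d
  df
}

assembly_split <- function(records) {
  split(records, records$assembly_id)
}

#' Keep only all-polypeptide assemblies
#'
#' Removes every assembly containing at least one chain whose polymer type
#' is not `"polypeptide(L)"` (protein-only complexes).
#'
#' @param records Assembly metadata `data.frame`.
#' @return Filtered `data.frame`.
#' @export
filter_polypeptide <- function(records) {
  if (!nrow(records)) return(records)
  bad <- unique(records$assembly_id[records$polymer_type != "polypeptide(L)"])
  records[!(records$assembly_id %in% bad), , drop = FALSE]
}

composition_key <- function(rec) {
  ord <- order(rec$sequence, rec$copies, method = "radix")
  paste(paste(rec$sequence[ord], rec$copies[ord], sep = ":"), collapse = "|")
}

#' Deduplicate assemblies by subunit composition and stoichiometry
#'
#' Assemblies with an identical multiset of (sequence, copy number) pairs
#' are redundant; one representative is kept — the earliest deposition
#' date, ties broken by assembly id.
#'
#' @param records Assembly metadata `data.frame`.
#' @return Filtered `data.frame`.
#' @export
dedupe_compositions <- function(records) {
  if (!nrow(records)) return(records)
  byasm <- assembly_split(records)
  keys <- vapply(byasm, composition_key, character(1))
  dates <- as.Date(vapply(byasm, function(r) as.character(min(r$date)),
                          character(1)))
  ids <- names(byasm)
  keep <- character(0)
  for (k in unique(keys)) {
    in_k <- which(keys == k)
    ord <- in_k[order(dates[in_k], ids[in_k], method = "radix")]
    keep <- c(keep, ids[ord[1L]])
  }
  records[records$assembly_id %in% keep, , drop = FALSE]
}

#' Time-based train/validation/test split
#'
#' Assemblies deposited before `train_cutoff` form the training set; those
#' deposited from `train_cutoff` through `valid_cutoff` (inclusive) the
#' validation set; later depositions form the test set, which additionally
#' requires experimental support (unsupported late assemblies are dropped
#' entirely).
#'
#' @param records Assembly metadata `data.frame`.
#' @param train_cutoff,valid_cutoff `Date` (or parseable) cutoffs,
#'   `train_cutoff < valid_cutoff`.
#' @return List with `train`, `valid`, `test` data frames.
#' @export
time_split <- function(records, train_cutoff = "2023-10-01",
                       valid_cutoff = "2024-05-01") {
  train_cutoff <- as.Date(train_cutoff)
  valid_cutoff <- as.Date(valid_cutoff)
  if (is.na(train_cutoff) || is.na(valid_cutoff)) stop("unparseable cutoff")
  if (!(train_cutoff < valid_cutoff)) {
    stop("train_cutoff must precede valid_cutoff")
  }
  d <- tryCatch(as.Date(records$date), error = function(e) NA)
  if (anyNA(d)) stop("unparseable deposition date(s)")
  tr <- records[d < train_cutoff, , drop = FALSE]
  va <- records[d >= train_cutoff & d <= valid_cutoff, , drop = FALSE]
  te <- records[d > valid_cutoff, , drop = FALSE]
  if (nrow(te)) {
    supported <- unique(te$assembly_id[as.logical(te$experimental_support)])
    te <- te[te$assembly_id %in% supported, , drop = FALSE]
  }
  list(train = tr, valid = va, test = te)
}

# Hungarian algorithm (Kuhn-Munkres, potentials formulation) minimizing the
# total cost of a square assignment; O(n^3).
hungarian_min <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                # columns are 1-indexed with a virtual column 1
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_col <- integer(n)  # assign_col[i] = column given to row i
  for (j in 2L:(n + 1L)) assign_col[p[j]] <- j - 1L
  assign_col
}

#' Optimal one-to-one chain mapping by identity
#'
#' Maximum-total-identity assignment of test chains to reference chains
#' (global, not greedy).  When the reference complex has fewer chains than
#' the test complex, the surplus test chains remain unmapped.
#'
#' @param identity Matrix of pairwise identities in `[0, 1]`; rows are test
#'   chains, columns reference chains.
#' @return List with `assignment` (per test chain: reference column index
#'   or `NA` if unmapped), `identities` (per test chain: identity of its
#'   pairing, `NA` if unmapped), and `total`.
#' @export
optimal_chain_mapping <- function(identity) {
  identity <- as.matrix(identity)
  if (any(identity < 0 | identity > 1)) stop("identities must be in [0, 1]")
  nr <- nrow(identity); nc <- ncol(identity)
  n <- max(nr, nc)
  # pad to square with zero-identity dummies; maximize by minimizing 1 - id
  cost <- matrix(1, n, n)
  cost[seq_len(nr), seq_len(nc)] <- 1 - identity
  cols <- hungarian_min(cost)
  assignment <- rep(NA_integer_, nr)
  ids <- rep(NA_real_, nr)
  for (i in seq_len(nr)) {
    j <- cols[i]
    if (j <= nc) {
      assignment[i] <- j
      ids[i] <- identity[i, j]
    }
  }
  list(assignment = assignment, identities = ids,
       total = sum(ids, na.rm = TRUE))
}

#' Redundancy filter for test complexes
#'
#' A test complex is removed when some reference complex covers it: the
#' optimal chain mapping pairs every test chain with a reference chain at
#' identity strictly greater than `threshold`.  Complexes with at least one
#' unmapped or low-identity chain are retained.
#'
#' @param test_seqs List of character vectors: the entity sequences of each
#'   test complex.
#' @param ref_seqs List of character vectors: entity sequences of the
#'   reference (training + validation) complexes.
#' @param identity_fn Function `(seq_a, seq_b) -> identity in [0, 1]`,
#'   typically a lookup into an externally computed identity table.
#' @param threshold Removal threshold (strict inequality), default 0.8.
#' @return Logical vector: `TRUE` where the test complex is retained.
#' @export
redundancy_filter <- function(test_seqs, ref_seqs, identity_fn,
                              threshold = 0.8) {
  vapply(test_seqs, function(tch) {
    for (rch in ref_seqs) {
      M <- outer(tch, rch, Vectorize(identity_fn))
      m <- optimal_chain_mapping(M)
      if (!anyNA(m$identities) && all(m$identities > threshold)) {
        return(FALSE)  # fully covered: redundant
      }
    }
    TRUE
  }, logical(1))
}

#' Size filters for structure-prediction benchmarking subsets
#'
#' Keeps assemblies with total amino-acid length (over all chains,
#' counting copies) strictly below `max_total`, maximum single-chain
#' length strictly below `max_chain`, and no more than `max_copies` copies
#' per subunit.
#'
#' @param records Assembly metadata `data.frame`.
#' @param max_total Total length bound (strict), default 4200.
#' @param max_chain Single-chain length bound (strict), default 500.
#' @param max_copies Per-subunit copy bound (inclusive), default 8.
#' @return Filtered `data.frame`.
#' @export
af3_subset_filter <- function(records, max_total = 4200L, max_chain = 500L,
                              max_copies = 8L) {
  if (!nrow(records)) return(records)
  byasm <- assembly_split(records)
  ok <- vapply(byasm, function(r) {
    total <- sum(nchar(r$sequence) * r$copies)
    total < max_total &&
      max(nchar(r$sequence)) < max_chain &&
      max(r$copies) <= max_copies
  }, logical(1))
  keep <- names(byasm)[ok]
  records[records$assembly_id %in% keep, , drop = FALSE]
}
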
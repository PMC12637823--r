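# Alignment-based stoichiometry prediction: candidate copy numbers are
# scored per chain by bitscore-and-similarity weighted voting over template
# hits, then assembled into complex-level rankings with the same product +
# beam-search scheme used for the deep model's local distributions.

#' Construct template hit records for one query chain
#'
#' @param bitscore Numeric vector of alignment bitscores (>= 0).
#' @param similarity Numeric vector in `[0, 1]` (sequence identity, or
#'   TM-score in structure mode; normalized by the larger chain length
#'   upstream).
#' @param template_copies Integer vector: copies of each template subunit in
#'   its source assembly.
#' @param template_chain Optional template identifiers.
#' @return `data.frame` of hits sorted by bitscore (decreasing).
#' @export
hit_records <- function(bitscore, similarity, template_copies,
                        template_chain = NULL) {
  if (any(bitscore < 0)) stop("bitscores must be >= 0")
  if (any(similarity < 0 | similarity > 1)) {
    stop("similarity must be in [0, 1]")
  }
  template_copies <- as.integer(template_copies)
  if (any(template_copies < 1L)) stop("template copies must be >= 1")
  out <- data.frame(
    template_chain = if (is.null(template_chain)) {
      rep(NA_character_, length(bitscore))
    } else as.character(template_chain),
    bitscore = as.numeric(bitscore),
    similarity = as.numeric(similarity),
    template_copies = template_copies,
    stringsAsFactors = FALSE
  )
  out[order(-out$bitscore), , drop = FALSE]
}

#' Copy-number scores for one chain from template hits
#'
#' Weighted vote over the top `top_k` hits (by bitscore): the score of copy
#' number `y` is the sum of `bitscore * similarity` over hits whose template
#' has `y` copies, normalized by the total over all counted hits — so the
#' scores form a distribution and are invariant to a uniform rescaling of
#' all bitscores.  A chain with no hits (or zero total weight) falls back
#' to a one-hot distribution at one copy.
#'
#' @param hits `data.frame` from [hit_records()] (may have zero rows).
#' @param top_k Number of top hits to count.
#' @return Named numeric vector: probability per observed copy number (names
#'   are the copy numbers).
#' @export
chain_copy_scores <- function(hits, top_k = 30L) {
  if (top_k < 1L) stop("top_k must be >= 1")
  if (is.null(hits) || nrow(hits) == 0L) {
    return(c("1" = 1))
  }
  if (any(hits$bitscore < 0)) stop("bitscores must be >= 0")
  hits <- hits[order(-hits$bitscore), , drop = FALSE]
  hits <- hits[seq_len(min(nrow(hits), top_k)), , drop = FALSE]
  w <- hits$bitscore * hits$similarity
  denom <- sum(w)
  if (denom <= 0) return(c("1" = 1))
  s <- rowsum(w, hits$template_copies)
  p <- drop(s) / denom
  names(p) <- rownames(s)
  p[order(as.integer(names(p)))]
}

# expand a sparse named distribution over copy numbers into a dense 1..K row
dense_copy_row <- function(p, K) {
  row <- numeric(K)
  ks <- as.integer(names(p))
  row[ks[ks <= K]] <- p[ks <= K]
  row
}

#' Template-based complex stoichiometry prediction
#'
#' Builds a per-chain copy-number distribution with [chain_copy_scores()]
#' for every query chain, then ranks complex states by the product of the
#' chain distributions via beam search (no global term).
#'
#' @param per_chain_hits Named list of hit tables, one per query chain, in
#'   the complex's entity order.
#' @param n_out Number of ranked states to return.
#' @param top_k Hits counted per chain.
#' @param K_max Largest candidate copy number considered.
#' @return A [ranked_prediction()] table.
#' @export
template_predict <- function(per_chain_hits, n_out = 5L, top_k = 30L,
                             K_max = 12L) {
  dists <- lapply(per_chain_hits, chain_copy_scores, top_k = top_k)
  kmax <- max(K_max, max(vapply(dists, function(p) {
    max(as.integer(names(p)))
  }, integer(1))))
  M <- do.call(rbind, lapply(dists, dense_copy_row, K = kmax))
  cands <- beam_candidates(M, n_out = n_out)
  ranked_prediction(cands$stoichiometry, cands$chain_prob)
}

#' Parse a 12-column tabular alignment hit file
#'
#' Reads the standard tab-separated search output (query, target, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, tstart,
#' tend, e-value, bitscore) and joins each hit's template copy number from
#' a template database table.  In sequence mode, similarity is
#' `pident / 100`; in structure mode a 13th column carrying a `[0, 1]`
#' similarity (e.g. TM-score) is used instead.
#'
#' @param path Path to the hit file.
#' @param template_db `data.frame` with columns `chain_id` and `copies`
#'   (see [read_template_db()]).
#' @param mode `"seq"` or `"struct"`.
#' @return Named list of hit tables keyed by query chain id.
#' @export
parse_hit_table <- function(path, template_db, mode = c("seq", "struct")) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    need <- if (mode == "seq") 12L else 13L
    if (length(f) < need) {
      stop("malformed hit line ", i, ": expected >= ", need, " columns")
    }
    query <- f[1]; target <- f[2]
    bits <- suppressWarnings(as.numeric(f[12]))
    sim <- if (mode == "seq") {
      suppressWarnings(as.numeric(f[3])) / 100
    } else {
      suppressWarnings(as.numeric(f[13]))
    }
    if (is.na(bits) || is.na(sim)) {
      stop("malformed hit line ", i, ": non-numeric score fields")
    }
    j <- match(target, template_db$chain_id)
    if (is.na(j)) {
      warning("unknown template id '", target, "' at line ", i, "; skipped")
      next
    }
    rec <- data.frame(template_chain = target, bitscore = bits,
                      similarity = sim,
                      template_copies = as.integer(template_db$copies[j]),
                      stringsAsFactors = FALSE)
    out[[query]] <- rbind(out[[query]], rec)
  }
  lapply(out, function(h) h[order(-h$bitscore), , drop = FALSE])
}

#' Read a template database table
#'
#' Tab-separated with columns `chain_id`, `copies`, and optionally
#' `stoichiometry` (the source assembly's state string).
#'
#' @param path Path to the TSV file.
#' @return `data.frame`.
#' @export
read_template_db <- function(path) {
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chain_id", "copies") %in% names(db))) {
    stop("template database needs columns 'chain_id' and 'copies'")
  }
  if (anyDuplicated(db$chain_id)) stop("duplicate template chain ids")
  if (any(db$copies < 1L)) stop("template copies must be >= 1")
  db
}
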
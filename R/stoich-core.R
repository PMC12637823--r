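#' Parse a stoichiometry string
#'
#' Stoichiometry strings use the `"AxBy..."` convention: consecutive
#' capital letters `A`, `B`, `C`, ... name the unique protein entities of a
#' complex and the integer after each letter is that entity's copy number,
#' so `"A2B2"` is a heterotetramer with two copies each of two entities.
#'
#' Letters must start at `A` and be consecutive (no gaps, no duplicates);
#' copy numbers must be positive integers.
#'
#' @param notation A single stoichiometry string, e.g. `"A2B3"`.
#' @return Integer vector of copy numbers, one per entity, in letter order.
#' @examples
#' parse_stoich("A2B2") # c(2, 2)
#' parse_stoich("A12")  # 12
#' @seealso [format_stoich()], [to_composition()]
#' @export
parse_stoich <- function(notation) {
  if (!is.character(notation) || length(notation) != 1L || is.na(notation)) {
    stop("'notation' must be a single string")
  }
  if (!grepl("^([A-Z][0-9]+)+$", notation)) {
    stop("malformed stoichiometry string: '", notation, "'")
  }
  m <- gregexpr("[A-Z][0-9]+", notation)[[1]]
  groups <- regmatches(notation, list(m))[[1]]
  letters_seen <- substr(groups, 1L, 1L)
  copies <- as.integer(substring(groups, 2L))
  expected <- LETTERS[seq_along(groups)]
  if (any(duplicated(letters_seen))) {
    stop("duplicated entity letter in '", notation, "'")
  }
  if (!identical(letters_seen, expected)) {
    stop("entity letters must be consecutive starting at A in '", notation, "'")
  }
  if (any(is.na(copies)) || any(copies < 1L)) {
    stop("copy numbers must be positive integers in '", notation, "'")
  }
  copies
}

#' Format copy numbers as a stoichiometry string
#'
#' Inverse of [parse_stoich()]: entity letters are assigned in the order the
#' copies are given, which is the complex's input entity order.
#'
#' @param copies Vector of positive integer copy numbers.
#' @return A stoichiometry string such as `"A2B2"`.
#' @export
format_stoich <- function(copies) {
  copies <- as.integer(copies)
  if (length(copies) == 0L) stop("empty stoichiometry state")
  if (length(copies) > 26L) stop("at most 26 unique entities are supported")
  if (any(is.na(copies)) || any(copies < 1L)) {
    stop("copy numbers must be positive integers")
  }
  paste0(LETTERS[seq_along(copies)], copies, collapse = "")
}

#' Entity-agnostic composition of a stoichiometry state
#'
#' The composition is the multiset of copy numbers, sorted non-increasing,
#' so permuting entities leaves it unchanged: A2B3 and A3B2 both map to
#' (3, 2).  Compositions are the label space of the global prediction
#' branch and of the frequency baseline.
#'
#' @param copies Vector of positive integer copy numbers (or a stoichiometry
#'   string, which is parsed first).
#' @return Integer vector sorted in non-increasing order.
#' @export
to_composition <- function(copies) {
  if (is.character(copies)) copies <- parse_stoich(copies)
  copies <- as.integer(copies)
  if (length(copies) == 0L) stop("empty stoichiometry state")
  if (any(copies < 1L)) stop("copy numbers must be positive integers")
  sort(copies, decreasing = TRUE)
}

#' Canonical label string for a composition
#'
#' @param copies Copy-number vector; sorted internally.
#' @return A string such as `"3-2"` identifying the composition.
#' @export
composition_label <- function(copies) {
  paste(to_composition(copies), collapse = "-")
}

#' Construct a ranked prediction table
#'
#' A ranked prediction is an ordered table of candidate stoichiometry states
#' with confidence scores, sorted by score (non-increasing).  Ties are broken
#' by the lexicographically smaller notation string so that rankings are
#' deterministic across runs and platforms.
#'
#' @param states Character vector of stoichiometry strings (pairwise distinct).
#' @param scores Numeric scores, same length.
#' @return A `data.frame` with columns `stoichiometry`, `score`, `rank`.
#' @export
ranked_prediction <- function(states, scores) {
  if (length(states) != length(scores)) {
    stop("states and scores must have equal length")
  }
  if (anyDuplicated(states)) stop("candidate states must be pairwise distinct")
  ord <- order(-scores, states, method = "radix")
  out <- data.frame(
    stoichiometry = as.character(states[ord]),
    score = as.numeric(scores[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Construct a complex instance
#'
#' A complex instance bundles the unique entities of one protein complex:
#' their identifiers, (optionally) sequences, one embedding vector per
#' entity, and, when known, the true copy numbers.
#'
#' @param complex_id Identifier string.
#' @param entity_ids Character vector of unique entity identifiers.
#' @param embeddings Numeric matrix, one row per entity (C x d).
#' @param true_copies Optional integer copy-number vector (length C).
#' @param sequences Optional character vector of entity sequences.
#' @param deposition_date Optional `Date`.
#' @return A list of class `"complex_instance"`.
#' @export
complex_instance <- function(complex_id, entity_ids, embeddings,
                             true_copies = NULL, sequences = NULL,
                             deposition_date = NULL) {
  embeddings <- as.matrix(embeddings)
  if (anyDuplicated(entity_ids)) {
    stop("entity ids must be unique within a complex")
  }
  if (nrow(embeddings) != length(entity_ids)) {
    stop("one embedding row per entity required")
  }
  if (!is.null(true_copies)) {
    true_copies <- as.integer(true_copies)
    if (length(true_copies) != length(entity_ids)) {
      stop("true_copies length must equal the number of entities")
    }
    if (any(true_copies < 1L)) stop("copy numbers must be >= 1")
  }
  structure(
    list(
      complex_id = as.character(complex_id),
      entity_ids = as.character(entity_ids),
      embeddings = embeddings,
      true_copies = true_copies,
      sequences = sequences,
      deposition_date = deposition_date
    ),
    class = "complex_instance"
  )
}

#' @export
print.complex_instance <- function(x, ...) {
  cat("<complex_instance> ", x$complex_id, ": ",
      length(x$entity_ids), " entities, d = ", ncol(x$embeddings),
      if (!is.null(x$true_copies)) {
        paste0(", truth ", format_stoich(x$true_copies))
      } else "",
      "\n", sep = "")
  invisible(x)
}

n_entities <- function(instance) length(instance$entity_ids)
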
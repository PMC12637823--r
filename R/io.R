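# Readers and writers for the text formats the package touches: FASTA
# entity lists, embedding tables, truth tables, prediction JSON, YAML
# configuration, and JSON model checkpoints.

#' Read entity FASTA
#'
#' One record per unique entity; complex membership is encoded in the
#' header as `"complexid|entityid"`.  Sequences are uppercased; the 20
#' standard amino acids plus `X` are permitted.
#'
#' @param path FASTA file path.
#' @return `data.frame` with columns `id`, `complex_id`, `entity_id`,
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  starts <- grep("^>", lines)
  if (!length(starts) || starts[1] != 1L) {
    stop("FASTA must start with a header line")
  }
  ids <- sub("^>\\s*", "", lines[starts])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(starts[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(i) {
    if (ends[i] < starts[i] + 1L) {
      stop("record '", ids[i], "' has no sequence")
    }
    toupper(paste(lines[(starts[i] + 1L):ends[i]], collapse = ""))
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header: ", ids[anyDuplicated(ids)])
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad)) {
    stop("illegal sequence characters in record '", ids[which(bad)[1]], "'")
  }
  has_pipe <- grepl("|", ids, fixed = TRUE)
  data.frame(
    id = ids,
    complex_id = ifelse(has_pipe, sub("\\|.*$", "", ids), ids),
    entity_id = ifelse(has_pipe, sub("^[^|]*\\|", "", ids), ids),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' Write entity FASTA
#'
#' @param entities `data.frame` as returned by [read_fasta()] (columns `id`,
#'   `sequence`).
#' @param path Output path.
#' @export
write_fasta <- function(entities, path) {
  writeLines(paste0(">", entities$id, "\n", entities$sequence), path)
}

#' Read an embedding table
#'
#' Tab-separated: first column the sequence/entity identifier, remaining
#' columns the embedding vector.  All rows must share one dimension.
#'
#' @param path TSV path (a header row is optional and detected by a
#'   non-numeric second field).
#' @return Numeric matrix with identifiers as row names.
#' @export
read_embeddings <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  header <- length(first) > 1L && is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M) || anyNA(M)) {
    stop("embedding table contains non-numeric or ragged rows")
  }
  rownames(M) <- ids
  colnames(M) <- NULL
  M
}

#' Write an embedding table
#'
#' @param M Numeric matrix with identifiers as row names.
#' @param path Output TSV path.
#' @export
write_embeddings <- function(M, path) {
  df <- data.frame(id = rownames(M), M, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Assemble complex instances from FASTA + embeddings (+ truth)
#'
#' @param entities `data.frame` from [read_fasta()].
#' @param embeddings Matrix from [read_embeddings()], keyed by entity `id`.
#' @param truth Optional named character vector (or `data.frame` with
#'   columns `complex_id`, `stoichiometry`) of true states.
#' @return List of [complex_instance()] objects (entity order = file order).
#' @export
build_instances <- function(entities, embeddings, truth = NULL) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$stoichiometry, truth$complex_id)
  }
  missing <- setdiff(entities$id, rownames(embeddings))
  if (length(missing)) {
    stop("missing embedding for entity '", missing[1], "'")
  }
  lapply(split(entities, entities$complex_id), function(e) {
    tc <- if (!is.null(truth) && e$complex_id[1] %in% names(truth)) {
      parse_stoich(truth[[e$complex_id[1]]])
    } else NULL
    complex_instance(
      complex_id = e$complex_id[1],
      entity_ids = e$entity_id,
      embeddings = embeddings[e$id, , drop = FALSE],
      true_copies = tc,
      sequences = e$sequence
    )
  })
}

#' Write ranked predictions as JSON
#'
#' Schema: `{"schema_version", "config", "complexes": [{"complex_id",
#' "predictions": [{"stoichiometry", "score", "rank"}]}]}` with
#' deterministic key order, so identical inputs serialize byte-identically.
#'
#' @param preds Named list of [ranked_prediction()] tables (names are
#'   complex ids).
#' @param path Output path.
#' @param config Optional resolved run configuration to embed for
#'   provenance.
#' @export
write_predictions <- function(preds, path, config = NULL) {
  body <- list(
    schema_version = "1.0",
    config = config,
    complexes = lapply(seq_along(preds), function(i) {
      list(complex_id = names(preds)[i],
           predictions = preds[[i]][, c("stoichiometry", "score", "rank")])
    })
  )
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path JSON path.
#' @return Named list of [ranked_prediction()] tables.
#' @export
read_predictions <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cx <- obj$complexes
  if (is.null(cx) || !length(cx)) return(structure(list(), names = character(0)))
  out <- lapply(seq_len(nrow(cx)), function(i) {
    df <- cx$predictions[[i]]
    data.frame(stoichiometry = as.character(df$stoichiometry),
               score = as.numeric(df$score), rank = as.integer(df$rank),
               stringsAsFactors = FALSE)
  })
  names(out) <- cx$complex_id
  out
}

#' Save a trained model as a JSON checkpoint
#'
#' Self-describing text checkpoint: format version, full configuration,
#' global vocabulary, and every parameter tensor (with shapes).
#'
#' @param model A `"stoich_model"`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  tensors <- lapply(model$params, function(x) {
    list(dim = if (is.matrix(x)) dim(x) else length(x), data = as.numeric(x))
  })
  obj <- list(
    format = "oligostate-checkpoint",
    version = "1.0",
    config = unclass(model$config),
    vocab = if (is.null(model$vocab)) NULL else unclass(model$vocab),
    params = tensors
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path Checkpoint path.
#' @return A `"stoich_model"`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "oligostate-checkpoint")) {
    stop("not an oligostate checkpoint: ", path)
  }
  cfg <- obj$config
  config <- model_config(
    d_in = cfg$d_in, d_model = cfg$d_model, n_layers = cfg$n_layers,
    n_heads = cfg$n_heads, K_max = cfg$K_max,
    dropout_rate = cfg$dropout_rate, max_chains = cfg$max_chains,
    use_gat = cfg$use_gat, use_global = cfg$use_global, alpha = cfg$alpha,
    expert_counts = cfg$expert_counts, lambda_g = cfg$lambda_g
  )
  vocab <- NULL
  if (!is.null(obj$vocab)) {
    vocab <- structure(list(labels = lapply(obj$vocab$labels, as.character),
                            min_count = obj$vocab$min_count),
                       class = "global_vocab")
  }
  params <- lapply(obj$params, function(t) {
    d <- unlist(t$dim)
    if (length(d) == 2L) matrix(t$data, d[1], d[2]) else as.numeric(t$data)
  })
  structure(list(params = params, config = config, vocab = vocab,
                 history = NULL),
            class = "stoich_model")
}

#' Write a truth table of stoichiometry states
#'
#' @param instances List of labelled [complex_instance()] objects.
#' @param path Output TSV path (columns `complex_id`, `stoichiometry`).
#' @export
write_truth <- function(instances, path) {
  df <- data.frame(
    complex_id = vapply(instances, function(x) x$complex_id, character(1)),
    stoichiometry = vapply(instances, function(x) format_stoich(x$true_copies),
                           character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a truth table
#'
#' @param path TSV with columns `complex_id`, `stoichiometry`.
#' @return `data.frame`.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("complex_id", "stoichiometry") %in% names(df))) {
    stop("truth table needs columns 'complex_id' and 'stoichiometry'")
  }
  df
}

#' Export a synthetic dataset to disk
#'
#' Writes the FASTA entity list, embedding table, and truth TSV for a
#' generated dataset, so the command-line workflow can run end to end.
#'
#' @param dataset From [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unlist(lapply(dataset, function(x) x$entity_ids))
  seqs <- unlist(lapply(dataset, function(x) x$sequences))
  fa <- file.path(dir, "entities.fasta")
  write_fasta(data.frame(id = ids, sequence = seqs), fa)
  E <- do.call(rbind, lapply(dataset, function(x) x$embeddings))
  rownames(E) <- ids
  em <- file.path(dir, "embeddings.tsv")
  write_embeddings(E, em)
  tr <- file.path(dir, "truth.tsv")
  write_truth(dataset, tr)
  invisible(c(fasta = fa, embeddings = em, truth = tr))
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys matching [model_config()] arguments are
#'   passed through, unknown keys are kept alongside.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
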
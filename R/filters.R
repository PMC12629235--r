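#' Filtering and quality assurance
#'
#' Three filter families remove mappings that would corrupt downstream
#' integration: prefix-based exclusion (subject, object, or prefix-pair),
#' confidence thresholds, and negative-mapping subtraction. Cardinality
#' checking — entities with exact matches to more than one entity in a single
#' target prefix — flags violations for curation by default rather than
#' deleting them; an opt-in mode deletes the whole violating group (never a
#' heuristic subset). Every filter returns both the retained document and the
#' removed mappings, and the two always partition the input exactly.
#'
#' @name filters
NULL

empty_removed <- function() {
  tibble::tibble(hash = character(), subject = character(), predicate = character(),
                 object = character(), reason = character())
}

removed_tbl <- function(doc, hashes, reason) {
  if (!length(hashes)) return(empty_removed())
  ms <- doc$mappings[hashes]
  tibble::tibble(
    hash = hashes,
    subject = vapply(ms, `[[`, character(1), "subject", USE.NAMES = FALSE),
    predicate = vapply(ms, `[[`, character(1), "predicate", USE.NAMES = FALSE),
    object = vapply(ms, `[[`, character(1), "object", USE.NAMES = FALSE),
    reason = reason
  )
}

drop_mappings <- function(doc, hashes) {
  doc$mappings[hashes] <- NULL
  doc
}

#' Construct a filter rule
#'
#' @param kind One of `"subject_prefix"`, `"object_prefix"`, `"prefix_pair"`,
#'   `"cardinality"`, `"confidence_threshold"`, `"negatives"`.
#' @param ... Kind-specific parameters: `prefixes` (character, for the prefix
#'   kinds; for `prefix_pair` a two-column data frame or a vector
#'   `c(subject, object)`), `threshold` (for `confidence_threshold`),
#'   `predicate` and `action` (`"flag"` or `"delete"`, for `cardinality`),
#'   `negatives` (data frame of triples, for `negatives`).
#' @return A `filter_rule`.
#' @export
filter_rule <- function(kind, ...) {
  kind <- match.arg(kind, c("subject_prefix", "object_prefix", "prefix_pair",
                            "cardinality", "confidence_threshold", "negatives"))
  params <- list(...)
  if (kind %in% c("subject_prefix", "object_prefix") &&
      (!length(params$prefixes) || !all(nzchar(params$prefixes)))) {
    abort("Prefix filter rules need a non-empty `prefixes`", class = "semmap_config_error")
  }
  if (kind == "confidence_threshold") {
    check_unit_interval(params$threshold, "threshold")
  }
  structure(c(list(kind = kind), params), class = "filter_rule")
}

#' Remove mappings by subject/object prefix or prefix pair
#'
#' @param doc A `mapping_document`.
#' @param rule A [filter_rule()] of kind `"subject_prefix"`, `"object_prefix"`
#'   or `"prefix_pair"`.
#' @return List with `doc` (retained) and `removed` (tibble with reasons);
#'   together they partition the input.
#' @export
filter_prefixes <- function(doc, rule) {
  tri <- doc_triples(doc)
  sp <- curie_prefix(tri$subject)
  op <- curie_prefix(tri$object)
  hit <- switch(rule$kind,
    subject_prefix = sp %in% rule$prefixes,
    object_prefix = op %in% rule$prefixes,
    prefix_pair = {
      pairs <- rule$prefixes
      if (is.data.frame(pairs)) {
        paste(sp, op) %in% paste(pairs[[1]], pairs[[2]])
      } else {
        sp == pairs[[1]] & op == pairs[[2]]
      }
    },
    abort("Not a prefix filter rule", class = "semmap_config_error")
  )
  removed <- removed_tbl(doc, tri$hash[hit], paste0("excluded ", rule$kind))
  list(doc = drop_mappings(doc, tri$hash[hit]), removed = removed)
}

#' Flag cardinality violations
#'
#' Lists every (subject entity, object prefix) under which the entity has the
#' given predicate to more than one object — the many-to-one structure that
#' prevents consistent data integration and is routed to curation. Assessment
#' is directional (per the directed graph model); set `directed = FALSE` to
#' pool a symmetric predicate's two directions before counting.
#'
#' @param doc A `mapping_document`.
#' @param predicate Predicate to assess (default: exact match).
#' @param directed Assess outgoing edges only (default) or pool both
#'   directions.
#' @return A QA tibble with one row per flagged mapping: `group` (violation
#'   key `subject|object_prefix`), `subject`, `object_prefix`, `n_objects`,
#'   `hash`, `predicate`, `object`, `confidence`. Hand-editable into a
#'   negatives file.
#' @export
flag_cardinality_violations <- function(doc, predicate = PRED_EXACT, directed = TRUE) {
  tri <- doc_triples(doc)
  tri <- tri[tri$predicate == predicate, , drop = FALSE]
  if (!directed && nrow(tri)) {
    flipped <- tri
    flipped$subject <- tri$object
    flipped$object <- tri$subject
    tri <- dplyr::distinct(dplyr::bind_rows(tri, flipped),
                           .data$subject, .data$object, .keep_all = TRUE)
  }
  empty <- tibble::tibble(group = character(), subject = character(),
                          object_prefix = character(), n_objects = integer(),
                          hash = character(), predicate = character(),
                          object = character(), confidence = numeric())
  if (!nrow(tri)) return(empty)
  confs <- document_confidences(doc)
  tri$object_prefix <- curie_prefix(tri$object)
  grp <- dplyr::summarise(
    dplyr::group_by(tri, .data$subject, .data$object_prefix),
    n_objects = dplyr::n_distinct(.data$object), .groups = "drop")
  viol <- grp[grp$n_objects > 1L, , drop = FALSE]
  if (!nrow(viol)) return(empty)
  out <- dplyr::inner_join(tri, viol, by = c("subject", "object_prefix"))
  out$group <- paste(out$subject, out$object_prefix, sep = "|")
  out$confidence <- unname(confs[out$hash])
  out <- out[order(out$group, out$object, method = "radix"), , drop = FALSE]
  out[, c("group", "subject", "object_prefix", "n_objects", "hash",
          "predicate", "object", "confidence")]
}

#' Delete whole cardinality-violating groups
#'
#' Opt-in alternative to flagging: removes *every* mapping participating in a
#' violating (subject, object prefix) group — never a heuristic subset.
#'
#' @inheritParams flag_cardinality_violations
#' @return List with `doc` and `removed`, as for [filter_prefixes()].
#' @export
filter_cardinality <- function(doc, predicate = PRED_EXACT, directed = TRUE) {
  flags <- flag_cardinality_violations(doc, predicate, directed)
  hashes <- intersect(unique(flags$hash), names(doc$mappings))
  removed <- removed_tbl(doc, hashes, "cardinality violation group")
  list(doc = drop_mappings(doc, hashes), removed = removed)
}

#' Remove mappings below a confidence threshold
#'
#' @param doc A `mapping_document`.
#' @param threshold Minimum confidence in `[0, 1]`; mappings with
#'   `c_m < threshold` are removed.
#' @return List with `doc` and `removed`.
#' @export
filter_confidence <- function(doc, threshold) {
  check_unit_interval(threshold, "threshold")
  confs <- document_confidences(doc)
  hashes <- names(confs)[confs < threshold]
  removed <- removed_tbl(doc, hashes,
                         sprintf("confidence below %s", format(threshold)))
  list(doc = drop_mappings(doc, hashes), removed = removed)
}

#' Subtract curated negative mappings
#'
#' Removes every listed triple from the document wherever present. The same
#' negatives, passed to [infer_chains()] (or [full_process()]), are also
#' excluded as chain steps, blocking false inference paths.
#'
#' @param doc A `mapping_document`.
#' @param negatives Data frame with `subject`/`predicate`/`object` columns, or
#'   a character vector of triple hashes.
#' @return The document without the listed triples. Negatives referencing
#'   absent triples are a no-op (noted via message).
#' @export
apply_negatives <- function(doc, negatives) {
  neg <- negative_hashes(negatives)
  present <- intersect(neg, names(doc$mappings))
  absent <- length(neg) - length(present)
  if (absent > 0) {
    message(sprintf("apply_negatives: %d negative triple(s) not present in the document", absent))
  }
  drop_mappings(doc, present)
}

#' Read a negatives file
#'
#' Negatives are curated assertions that two entities are *not* related. The
#' file convention is SSSOM TSV whose `predicate_id` column carries the
#' negated predicate prefixed with `"not:"` (e.g. `not:skos:exactMatch`), or a
#' plain `predicate_id` which is taken as the predicate being negated.
#'
#' @param path SSSOM TSV path.
#' @param registry Prefix registry.
#' @return Tibble with `subject`, `predicate`, `object`.
#' @export
read_negatives <- function(path, registry = default_registry()) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("subject_id", "predicate_id", "object_id"), names(tab))
  if (length(missing)) {
    abort(sprintf("Negatives file missing column(s): %s", paste(missing, collapse = ", ")),
          class = "semmap_format_error")
  }
  pred <- sub("^not:", "", tab$predicate_id)
  tibble::tibble(
    subject = normalize_curies(tab$subject_id, registry),
    predicate = normalize_curies(pred, registry),
    object = normalize_curies(tab$object_id, registry)
  )
}

#' Apply one filter rule to a document
#'
#' Dispatcher used by [full_process()] and the pipeline runner.
#'
#' @param doc A `mapping_document`.
#' @param rule A [filter_rule()].
#' @return List with `doc` and `removed`.
#' @export
apply_filter <- function(doc, rule) {
  stopifnot(inherits(rule, "filter_rule"))
  switch(rule$kind,
    subject_prefix = ,
    object_prefix = ,
    prefix_pair = filter_prefixes(doc, rule),
    confidence_threshold = filter_confidence(doc, rule$threshold),
    cardinality = {
      if (identical(rule$action %||% "flag", "delete")) {
        filter_cardinality(doc, rule$predicate %||% PRED_EXACT,
                           rule$directed %||% TRUE)
      } else {
        flags <- flag_cardinality_violations(doc, rule$predicate %||% PRED_EXACT,
                                             rule$directed %||% TRUE)
        attr(doc, "cardinality_flags") <- flags
        list(doc = doc, removed = empty_removed())
      }
    },
    negatives = {
      before <- names(doc$mappings)
      doc2 <- apply_negatives(doc, rule$negatives)
      gone <- setdiff(before, names(doc2$mappings))
      list(doc = doc2, removed = removed_tbl(doc, gone, "negative mapping"))
    }
  )
}
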
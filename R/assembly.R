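#' Assembly of projection and prioritization mapping sets
#'
#' Two artifacts are assembled from a processed document. A **projection
#' mapping set** maps one identifier space onto another: all subjects share
#' one prefix, all objects another, and the map is functional (at most one
#' object per subject). A **prioritization mapping set** standardizes every
#' entity to a canonical identifier: entities are partitioned into cliques of
#' mutual equivalence (connected components of the exact-match subgraph —
#' after chaining, components and true cliques coincide, and components
#' tolerate incomplete closure), and each clique's canonical entity is the
#' member whose prefix comes earliest in a user-supplied priority list. The
#' result is a star graph per clique: every member maps to the canonical
#' entity, the canonical entity to itself, and each entity appears as subject
#' exactly once.
#'
#' @name assembly
NULL

#' Partition entities into equivalence cliques
#'
#' Connected components of the subgraph formed by mappings carrying the given
#' predicate, ignoring direction (run inversion first so both directions are
#' materialized and the choice cannot matter). Deterministic: members sorted,
#' cliques ordered by their smallest member.
#'
#' @param doc A `mapping_document`.
#' @param predicate Predicate whose subgraph defines equivalence (default:
#'   exact match).
#' @return List of character vectors of entity CURIEs.
#' @export
extract_cliques <- function(doc, predicate = PRED_EXACT) {
  tri <- doc_triples(doc)
  tri <- tri[tri$predicate == predicate, , drop = FALSE]
  if (!nrow(tri)) return(list())
  g <- igraph::graph_from_data_frame(tri[, c("subject", "object")], directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  cliques <- lapply(members, function(v) sort(unname(v)))
  unname(cliques[order(vapply(cliques, `[[`, character(1), 1L), method = "radix")])
}

#' Build a prioritization mapping set
#'
#' For each clique, the canonical entity is the member whose prefix appears
#' earliest in `priority`. Every member yields one exact-match mapping onto
#' the canonical entity (the canonical entity maps to itself), carrying
#' reasoned evidence (operation `"prioritization"`) supported by the clique's
#' own mappings. Cliques holding two entities of the same prefix violate the
#' one-entity-per-prefix assumption; by default that is an error, or they can
#' be excluded with a log entry, or demoted to the next priority prefix that
#' is a singleton within the clique. Cliques with no prefix in the priority
#' list are excluded with a log entry.
#'
#' @param doc A processed `mapping_document`.
#' @param priority Non-empty character vector of prefixes, most preferred
#'   first.
#' @param on_conflict `"error"` (default), `"exclude"`, or `"demote"`.
#' @param predicate Predicate defining equivalence (default exact match).
#' @return A `prioritization_set`: list with `priority`, `mappings` (tibble
#'   `subject` -> `object`), `excluded` (tibble of skipped cliques with
#'   reasons), `cliques`, and `doc` (the star mappings as a
#'   `mapping_document`).
#' @export
build_prioritization <- function(doc, priority, on_conflict = c("error", "exclude", "demote"),
                                 predicate = PRED_EXACT) {
  on_conflict <- match.arg(on_conflict)
  if (!length(priority)) {
    abort("`priority` must be a non-empty prefix list", class = "semmap_config_error")
  }
  cliques <- extract_cliques(doc, predicate)
  tri <- doc_triples(doc)
  tri <- tri[tri$predicate == predicate, , drop = FALSE]

  subjects <- character(); objects <- character()
  excluded <- list()
  star_docs <- mapping_document(mapping_sets = doc$mapping_sets,
                                prefix_map = doc$prefix_map)
  memo <- new.env(parent = emptyenv())
  for (ci in seq_along(cliques)) {
    members <- cliques[[ci]]
    prefixes <- curie_prefix(members)
    canonical <- NA_character_
    for (p in priority) {
      idx <- which(prefixes == p)
      if (length(idx) == 1L) { canonical <- members[idx]; break }
      if (length(idx) > 1L) {
        msg <- sprintf("Clique %d holds %d entities with prefix '%s' (%s)",
                       ci, length(idx), p, paste(members[idx], collapse = ", "))
        if (on_conflict == "error") abort(msg, class = "semmap_cardinality_error")
        if (on_conflict == "exclude") {
          excluded[[length(excluded) + 1L]] <- tibble::tibble(
            clique = ci, members = paste(members, collapse = "|"),
            reason = msg)
          canonical <- NA_character_
          break
        }
        # demote: fall through to the next priority prefix
      }
    }
    if (is.na(canonical)) {
      if (!length(excluded) || excluded[[length(excluded)]]$clique != ci) {
        excluded[[length(excluded) + 1L]] <- tibble::tibble(
          clique = ci, members = paste(members, collapse = "|"),
          reason = "no usable priority prefix in clique")
      }
      next
    }
    support <- tri$hash[tri$subject %in% members & tri$object %in% members]
    support <- sort(unique(support))
    snap <- if (length(support)) {
      noisy_or(vapply(support, function(h) {
        mapping_confidence(doc$mappings[[h]], doc, .memo = memo)
      }, numeric(1)))
    } else 1
    for (m in members) {
      subjects <- c(subjects, m); objects <- c(objects, canonical)
      ev <- reasoned_evidence("prioritization",
                              supports = if (length(support)) support else "self",
                              factor = 1, support_confidence = snap)
      star_docs <- add_mapping(star_docs, new_mapping(m, predicate, canonical, list(ev)))
    }
  }
  structure(
    list(priority = priority,
         mappings = tibble::tibble(subject = subjects, object = objects),
         excluded = if (length(excluded)) dplyr::bind_rows(excluded) else
           tibble::tibble(clique = integer(), members = character(), reason = character()),
         cliques = cliques,
         doc = sort_document(star_docs)),
    class = "prioritization_set"
  )
}

#' @export
print.prioritization_set <- function(x, ...) {
  cat(sprintf("<prioritization_set> %d entities -> %d canonical, priority: %s\n",
              nrow(x$mappings), length(unique(x$mappings$object)),
              paste(x$priority, collapse = " > ")))
  invisible(x)
}

#' Standardize CURIEs against a prioritization mapping set
#'
#' Total and idempotent: clique members map to their canonical entity,
#' canonical entities to themselves, and unknown entities come back unchanged,
#' flagged in the `known` attribute.
#'
#' @param prioritization A `prioritization_set`.
#' @param curies Character vector of CURIEs.
#' @return Character vector of canonical CURIEs, with a logical attribute
#'   `known` marking which inputs were found in the prioritization set.
#' @export
standardize <- function(prioritization, curies) {
  stopifnot(inherits(prioritization, "prioritization_set"))
  idx <- match(curies, prioritization$mappings$subject)
  out <- ifelse(is.na(idx), curies, prioritization$mappings$object[idx])
  attr(out, "known") <- !is.na(idx)
  out
}

#' Check the star-graph structure of a prioritization set
#'
#' Verifies, per clique: each entity appears as subject exactly once; all
#' members of a clique map to a single target; that target is a member of the
#' clique and maps to itself; the target's prefix is the highest-priority
#' prefix present.
#'
#' @param prioritization A `prioritization_set`.
#' @return `TRUE` if all checks pass, otherwise a character vector of
#'   violations.
#' @export
star_graph_check <- function(prioritization) {
  m <- prioritization$mappings
  issues <- character()
  dup <- m$subject[duplicated(m$subject)]
  if (length(dup)) {
    issues <- c(issues, sprintf("entities appearing as subject more than once: %s",
                                paste(unique(dup), collapse = ", ")))
  }
  excluded_members <- unlist(strsplit(prioritization$excluded$members, "|", fixed = TRUE))
  for (ci in seq_along(prioritization$cliques)) {
    members <- prioritization$cliques[[ci]]
    if (length(intersect(members, excluded_members))) next
    targets <- unique(m$object[m$subject %in% members])
    if (length(targets) != 1L) {
      issues <- c(issues, sprintf("clique %d maps to %d targets", ci, length(targets)))
      next
    }
    if (!(targets %in% members)) {
      issues <- c(issues, sprintf("clique %d canonical %s is not a member", ci, targets))
    }
    if (!identical(m$object[m$subject == targets], targets)) {
      issues <- c(issues, sprintf("canonical %s does not map to itself", targets))
    }
    present <- intersect(prioritization$priority, curie_prefix(members))
    if (length(present) && curie_prefix(targets) != present[[1]] &&
        sum(curie_prefix(members) == present[[1]]) == 1L) {
      # a clique may only be demoted past a priority prefix that it duplicates
      issues <- c(issues, sprintf("clique %d canonical prefix %s is not the highest-priority present (%s)",
                                  ci, curie_prefix(targets), present[[1]]))
    }
  }
  if (length(issues)) issues else TRUE
}

#' Build a projection mapping set
#'
#' All mappings with the given predicate whose subject carries `source_prefix`
#' and whose object carries `target_prefix` — whether directly asserted or
#' inferred (simple and reasoned evidence both qualify). Subjects with more
#' than one distinct object are excluded and reported, so the result is
#' guaranteed functional.
#'
#' @param doc A processed `mapping_document`.
#' @param source_prefix,target_prefix Prefixes of subjects and objects.
#' @param predicate Predicate to project (default exact match).
#' @return A `projection_set`: list with `source_prefix`, `target_prefix`,
#'   `mappings` (tibble `subject`, `object`, `confidence`, `hash`),
#'   `excluded` (tibble of non-functional subjects), and `doc`.
#' @export
build_projection <- function(doc, source_prefix, target_prefix, predicate = PRED_EXACT) {
  tri <- doc_triples(doc)
  keep <- tri$predicate == predicate &
    curie_prefix(tri$subject) == source_prefix &
    curie_prefix(tri$object) == target_prefix
  tri <- tri[keep, , drop = FALSE]
  counts <- table(tri$subject)
  multi <- names(counts)[counts > 1L]
  excluded <- tri[tri$subject %in% multi, , drop = FALSE]
  tri <- tri[!(tri$subject %in% multi), , drop = FALSE]
  confs <- if (nrow(tri)) document_confidences(doc)[tri$hash] else numeric()
  proj_doc <- mapping_document(mappings = doc$mappings[tri$hash],
                               mapping_sets = doc$mapping_sets,
                               prefix_map = doc$prefix_map)
  structure(
    list(source_prefix = source_prefix, target_prefix = target_prefix,
         mappings = tibble::tibble(subject = tri$subject, object = tri$object,
                                   confidence = unname(confs), hash = tri$hash),
         excluded = excluded[, c("hash", "subject", "predicate", "object")],
         doc = sort_document(proj_doc)),
    class = "projection_set"
  )
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %s -> %s: %d mapping(s), %d excluded row(s)\n",
              x$source_prefix, x$target_prefix, nrow(x$mappings), nrow(x$excluded)))
  invisible(x)
}

#' Raw/unique/reduction statistics of a processed document
#'
#' `raw` counts distinct entities appearing in the document; merging each
#' clique of equivalent entities into one canonical term leaves
#' `unique = raw - (clique members - cliques)` distinct terms, a reduction of
#' `(raw - unique) / raw * 100` percent.
#'
#' @param doc A processed `mapping_document`.
#' @param predicate Predicate defining equivalence.
#' @return Tibble with `raw_terms`, `unique_terms`, `reduction_pct`,
#'   `n_cliques`.
#' @export
reduction_stats <- function(doc, predicate = PRED_EXACT) {
  tri <- doc_triples(doc)
  raw <- length(unique(c(tri$subject, tri$object)))
  cliques <- extract_cliques(doc, predicate)
  members <- sum(lengths(cliques))
  unique_terms <- raw - (members - length(cliques))
  tibble::tibble(
    raw_terms = raw,
    unique_terms = unique_terms,
    reduction_pct = if (raw > 0) (raw - unique_terms) / raw * 100 else 0,
    n_cliques = length(cliques)
  )
}

#' Write a prioritization or projection set as two-column TSV
#'
#' The compact interchange form: `subject`, `object` columns plus a YAML
#' metadata sidecar block in leading comments (priority list or prefix pair,
#' hash algorithm).
#'
#' @param x A `prioritization_set` or `projection_set`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_two_column <- function(x, path) {
  meta <- if (inherits(x, "prioritization_set")) {
    c("kind: prioritization", paste0("priority: [", paste(x$priority, collapse = ", "), "]"))
  } else {
    c("kind: projection", paste0("source_prefix: ", x$source_prefix),
      paste0("target_prefix: ", x$target_prefix))
  }
  con <- file(path, "w")
  writeLines(paste0("# ", c(meta, "hash_algorithm: sha256")), con)
  close(con)
  readr::write_tsv(x$mappings[, c("subject", "object")], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}
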
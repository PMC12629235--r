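#' Synthetic multi-source mapping fixtures with known ground truth
#'
#' The generator plants cliques of cross-prefix equivalent entities and emits,
#' per source, only a random spanning subset of each clique's edges — so
#' recovering the full cliques genuinely requires inversion and chaining, the
#' fragmentation pattern real mapping landscapes show. Configurable noise
#' emulates the main real-world failure modes: edge dropout (missing
#' mappings), wrong edges joining distinct cliques (the clique-merging failure
#' cardinality QA must catch), planted many-to-many edges (duplicate terms in
#' one resource), and demotion of exact matches to low-precision database
#' cross-references (imprecise predicates that must be mutated back). All
#' randomness is governed by the spec's seed; identical seeds give
#' byte-identical fixtures.
#'
#' @name synthetic-fixtures
NULL

#' Specify a synthetic fixture
#'
#' @param n_prefixes Number of identifier spaces (uses reserved registry
#'   prefixes `fx1`, `fx2`, ...; at most 26).
#' @param n_cliques Number of planted equivalence cliques.
#' @param min_clique_size,max_clique_size Clique sizes are drawn uniformly
#'   from this range; `max_clique_size` may not exceed `n_prefixes` (one
#'   entity per prefix per clique).
#' @param dropout Probability that a planted spanning-tree edge is not
#'   emitted. 0 guarantees full recovery; 1 emits nothing.
#' @param wrong_edge_rate Per-clique probability of one wrong edge to a
#'   different clique.
#' @param m2m_rate Per-clique probability of planting one many-to-many edge
#'   (an extra entity duplicating a member's prefix).
#' @param imprecise_rate Probability that an emitted exact-match edge is
#'   demoted to a database cross-reference.
#' @param seed Integer seed fixing all draws.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_prefixes = 4, n_cliques = 10,
                         min_clique_size = 2, max_clique_size = n_prefixes,
                         dropout = 0, wrong_edge_rate = 0, m2m_rate = 0,
                         imprecise_rate = 0, seed = 1) {
  for (r in c(dropout = dropout, wrong_edge_rate = wrong_edge_rate,
              m2m_rate = m2m_rate, imprecise_rate = imprecise_rate)) {
    check_unit_interval(r, "rate")
  }
  if (max_clique_size > n_prefixes) {
    abort("`max_clique_size` cannot exceed `n_prefixes` (one entity per prefix per clique)",
          class = "semmap_config_error")
  }
  if (min_clique_size < 2 || min_clique_size > max_clique_size) {
    abort("Need 2 <= min_clique_size <= max_clique_size", class = "semmap_config_error")
  }
  if (n_prefixes > 26) abort("At most 26 fixture prefixes are registered", class = "semmap_config_error")
  structure(
    list(n_prefixes = n_prefixes, n_cliques = n_cliques,
         min_clique_size = min_clique_size, max_clique_size = max_clique_size,
         dropout = dropout, wrong_edge_rate = wrong_edge_rate, m2m_rate = m2m_rate,
         imprecise_rate = imprecise_rate, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic mapping sets with ground truth
#'
#' @param spec A [fixture_spec()].
#' @param source_confidence Consumer confidence assigned to every synthetic
#'   source's mapping set.
#' @param registry Prefix registry (must contain the `fx*` prefixes).
#' @return A `fixture_set`: list with `documents` (one `mapping_document` per
#'   source, keyed by source name), `combined` (their merge), `edges` (tibble
#'   of every emitted edge with noise annotations), and `ground_truth` (list:
#'   `cliques` as planted-and-emitted connected entity sets, `violations`
#'   tibble of planted many-to-many groups, `wrong_edges` tibble, and
#'   `raw_terms` / `unique_terms` / `reduction_pct` / `n_cliques` computed on
#'   the clean emitted edges by integer arithmetic).
#' @export
generate_fixtures <- function(spec, source_confidence = 0.9,
                              registry = default_registry()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    prefixes <- paste0("fx", seq_len(spec$n_prefixes))
    edges <- list()
    clique_members <- vector("list", spec$n_cliques)
    violations <- list()
    wrong_edges <- list()

    for (k in seq_len(spec$n_cliques)) {
      sizes <- seq(spec$min_clique_size, spec$max_clique_size)
      s <- sizes[sample.int(length(sizes), 1L)]
      pfx <- sample(prefixes, s)
      members <- paste0(pfx, ":", sprintf("c%04d", k))
      clique_members[[k]] <- sort(members)
      # random spanning tree over the members
      ord <- sample(members)
      for (i in seq_along(ord)[-1]) {
        a <- ord[[sample.int(i - 1L, 1L)]]
        b <- ord[[i]]
        if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
        dropped <- stats::runif(1) < spec$dropout
        predicate <- if (stats::runif(1) < spec$imprecise_rate) PRED_XREF else PRED_EXACT
        edges[[length(edges) + 1L]] <- tibble::tibble(
          subject = a, object = b, predicate = predicate,
          clique = k, kind = "tree", emitted = !dropped)
      }
    }

    emitted_tree <- dplyr::bind_rows(edges)
    emitted_tree <- emitted_tree[emitted_tree$emitted, , drop = FALSE]

    if (spec$n_cliques > 1L) {
      for (k in seq_len(spec$n_cliques)) {
        if (stats::runif(1) < spec$wrong_edge_rate) {
          other <- sample(setdiff(seq_len(spec$n_cliques), k), 1L)
          a <- sample(clique_members[[k]], 1L)
          b <- sample(clique_members[[other]], 1L)
          edges[[length(edges) + 1L]] <- tibble::tibble(
            subject = a, object = b, predicate = PRED_EXACT,
            clique = NA_integer_, kind = "wrong", emitted = TRUE)
          wrong_edges[[length(wrong_edges) + 1L]] <- tibble::tibble(
            subject = a, object = b, clique_a = k, clique_b = other)
        }
      }
    }

    for (k in seq_len(spec$n_cliques)) {
      if (stats::runif(1) < spec$m2m_rate) {
        cand <- emitted_tree[emitted_tree$clique == k & emitted_tree$predicate == PRED_EXACT, , drop = FALSE]
        if (!nrow(cand)) next
        i <- sample.int(nrow(cand), 1L)
        u <- cand$subject[[i]]; v <- cand$object[[i]]
        v2 <- paste0(v, "x")  # duplicate term in v's identifier space
        edges[[length(edges) + 1L]] <- tibble::tibble(
          subject = u, object = v2, predicate = PRED_EXACT,
          clique = k, kind = "m2m", emitted = TRUE)
        violations[[length(violations) + 1L]] <- tibble::tibble(
          subject = u, object_prefix = curie_prefix(v), objects = paste(v, v2, sep = "|"),
          clique = k)
      }
    }

    all_edges <- dplyr::bind_rows(edges)
    emitted <- all_edges[all_edges$emitted, , drop = FALSE]

    # ground truth from the clean (tree) emitted edges, integer arithmetic
    clean <- emitted[emitted$kind == "tree", , drop = FALSE]
    gt_cliques <- if (nrow(clean)) {
      g <- igraph::graph_from_data_frame(clean[, c("subject", "object")], directed = FALSE)
      comp <- igraph::components(g)
      cl <- lapply(split(names(comp$membership), comp$membership), function(v) sort(unname(v)))
      unname(cl[order(vapply(cl, `[[`, character(1), 1L), method = "radix")])
    } else list()
    raw <- length(unique(c(clean$subject, clean$object)))
    members <- sum(lengths(gt_cliques))
    unique_terms <- raw - (members - length(gt_cliques))

    sets <- list()
    docs <- list()
    for (p in prefixes) {
      src <- emitted[curie_prefix(emitted$subject) == p, , drop = FALSE]
      set <- mapping_set(paste0("fx-source-", p), source_confidence,
                         version = "1", license = "CC0-1.0")
      sets[[p]] <- set
      if (!nrow(src)) next
      rows <- tibble::tibble(
        subject = src$subject, predicate = src$predicate, object = src$object,
        justification = JUST_UNSPECIFIED, author = NA_character_,
        confidence = NA_real_, mapping_set = set$hash)
      docs[[set$name]] <- document_from_rows(rows, list(set), registry)
    }

    structure(
      list(
        documents = docs,
        combined = if (length(docs)) merge_documents(docs) else mapping_document(),
        edges = all_edges,
        ground_truth = list(
          cliques = gt_cliques,
          violations = if (length(violations)) dplyr::bind_rows(violations) else
            tibble::tibble(subject = character(), object_prefix = character(),
                           objects = character(), clique = integer()),
          wrong_edges = if (length(wrong_edges)) dplyr::bind_rows(wrong_edges) else
            tibble::tibble(subject = character(), object = character(),
                           clique_a = integer(), clique_b = integer()),
          raw_terms = raw,
          unique_terms = unique_terms,
          reduction_pct = if (raw > 0) (raw - unique_terms) / raw * 100 else 0,
          n_cliques = length(gt_cliques)
        )
      ),
      class = "fixture_set"
    )
  })
}

#' Write a fixture set to disk
#'
#' One SSSOM TSV per synthetic source plus `ground_truth.json`.
#'
#' @param fixtures A `fixture_set` from [generate_fixtures()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (name in names(fixtures$documents)) {
    p <- file.path(dir, paste0(name, ".sssom.tsv"))
    write_sssom(fixtures$documents[[name]], p)
    paths <- c(paths, p)
  }
  gt <- fixtures$ground_truth
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(cliques = gt$cliques,
         violations = gt$violations, wrong_edges = gt$wrong_edges,
         raw_terms = gt$raw_terms, unique_terms = gt$unique_terms,
         reduction_pct = gt$reduction_pct, n_cliques = gt$n_cliques),
    gt_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, gt_path))
}

#' Toy cell-line mapping landscape
#'
#' A hard-coded six-resource rendition of the fragmented cell-line mapping
#' landscape, re-keyed onto reserved toy prefixes (`tcell` a cell-line
#' knowledgebase, `tclo` a cell-line ontology, `tbto` a tissue ontology,
#' `tdep` and `tccle` cancer-screening databases, `tefo` an experimental
#' factor ontology), all describing one astrocytoma cell line. Primary edges
#' point away from the resource that curated them; one is a low-precision
#' database cross-reference that must be mutated to an exact match before it
#' can chain. No direct mapping between the tissue-ontology and cell-line-
#' ontology entries exists before processing; a three-step chain creates it.
#'
#' @param primary_confidence,secondary_confidence Consumer confidences for the
#'   two toy mapping sets.
#' @return A `mapping_document` with 7 mappings from two mapping sets.
#' @export
#' @examples
#' doc <- toy_cell_line_doc()
#' processed <- full_process(doc,
#'   mutations = list(mutation_rule(PRED_XREF, PRED_EXACT, factor = 0.7)))
#' reduction_stats(processed)
toy_cell_line_doc <- function(primary_confidence = 0.9, secondary_confidence = 0.8) {
  primary <- mapping_set("toy-primary", primary_confidence, version = "1")
  secondary <- mapping_set("toy-secondary", secondary_confidence, version = "1")
  rows <- tibble::tribble(
    ~subject,           ~predicate, ~object,            ~mapping_set,
    "tcell:0110",       PRED_XREF,  "tclo:0001072",     primary$hash,
    "tefo:0005236",     PRED_EXACT, "tcell:0110",       primary$hash,
    "tefo:0005236",     PRED_EXACT, "tbto:0000058",     primary$hash,
    "tdep:ACH-000095",  PRED_EXACT, "tcell:0110",       primary$hash,
    "tdep:ACH-000095",  PRED_EXACT, "tccle:1321N1",     primary$hash,
    "tccle:1321N1",     PRED_EXACT, "tefo:0005236",     secondary$hash,
    "tccle:1321N1",     PRED_EXACT, "tcell:0110",       secondary$hash
  )
  rows$justification <- JUST_UNSPECIFIED
  rows$justification[rows$mapping_set == secondary$hash] <- JUST_MANUAL
  rows$author <- NA_character_
  rows$confidence <- NA_real_
  document_from_rows(rows, list(primary, secondary))
}
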
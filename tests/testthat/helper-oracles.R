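# Independent oracles and in-code fixtures shared across the suite.

# --- brute-force probability oracles ----------------------------------------
# Enumerate the independent Bernoulli "correctness" events explicitly instead
# of using any closed form, so the confidence calculus is checked against
# first principles.

# P(at least one of the events with probabilities p fires), by enumeration of
# all 2^k outcomes.
oracle_at_least_one <- function(p) {
  k <- length(p)
  if (k == 0L) return(0)
  outcomes <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  total <- 0
  for (i in seq_len(nrow(outcomes))) {
    fired <- unlist(outcomes[i, ])
    prob <- prod(ifelse(fired, p, 1 - p))
    if (any(fired)) total <- total + prob
  }
  total
}

oracle_simple_evidence <- function(c_set, c_prod) {
  if (is.na(c_prod)) return(c_set)
  oracle_at_least_one(c(c_set, c_prod))
}

oracle_mapping <- function(ces) oracle_at_least_one(ces)

oracle_reasoned <- function(gamma, cms) gamma * oracle_at_least_one(cms)

# --- document builders -------------------------------------------------------

# A document from a bare edge table (subject, predicate, object), one simple
# evidence per row from a single set.
doc_from_edges <- function(edges, set_confidence = 0.9, set_name = "test-set") {
  set <- mapping_set(set_name, set_confidence, version = "1")
  rows <- tibble::tibble(
    subject = edges$subject, predicate = edges$predicate, object = edges$object,
    justification = JUST_UNSPECIFIED, author = NA_character_,
    confidence = NA_real_, mapping_set = set$hash
  )
  document_from_rows(rows, list(set))
}

# Random directed mapping graph over <= n_nodes nodes in fixture prefixes.
random_mapping_graph <- function(n_nodes, n_edges,
                                 predicates = c(PRED_EXACT, PRED_BROAD, PRED_NARROW),
                                 weights = c(0.6, 0.2, 0.2)) {
  nodes <- paste0("fx", ((seq_len(n_nodes) - 1L) %% 8L) + 1L, ":n",
                  sprintf("%02d", seq_len(n_nodes)))
  from <- sample.int(n_nodes, n_edges, replace = TRUE)
  to <- sample.int(n_nodes, n_edges, replace = TRUE)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  edges <- tibble::tibble(
    subject = nodes[from],
    predicate = sample(predicates, length(from), replace = TRUE, prob = weights),
    object = nodes[to]
  )
  edges <- dplyr::distinct(edges)
  doc_from_edges(edges)
}

# --- independent chain-closure oracle ---------------------------------------
# Enumerates every simple node sequence (no composition-based pruning) by
# depth-first search over the *undirected-of-direction-agnostic* adjacency of
# outgoing edges, then folds predicate sets along each sequence. Parallel
# edges contribute every predicate. Returns the set of inferred triples as a
# sorted "s|p|o" character vector.
oracle_chain_closure <- function(doc, rules, max_path_length) {
  tri <- doc_triples(doc)
  if (!nrow(tri)) return(character())
  direct <- paste(tri$subject, tri$predicate, tri$object, sep = "|")
  preds_by_pair <- split(tri$predicate, paste(tri$subject, tri$object, sep = "|"))
  succ <- split(tri$object, tri$subject)
  succ <- lapply(succ, unique)
  nodes <- sort(unique(c(tri$subject, tri$object)))
  found <- character()

  recurse <- function(seq_nodes, composed_set) {
    tail_node <- seq_nodes[[length(seq_nodes)]]
    for (nxt in succ[[tail_node]] %||% character()) {
      if (nxt %in% seq_nodes) next
      step_preds <- preds_by_pair[[paste(tail_node, nxt, sep = "|")]]
      new_set <- unique(unlist(lapply(composed_set, function(cp) {
        vapply(step_preds, function(sp) compose_predicates(cp, sp, rules),
               character(1))
      })))
      new_set <- new_set[!is.na(new_set)]
      seq2 <- c(seq_nodes, nxt)
      if (length(seq2) >= 3L && length(new_set)) {
        for (p in new_set) {
          trip <- paste(seq_nodes[[1]], p, nxt, sep = "|")
          if (!(trip %in% direct)) found <<- c(found, trip)
        }
      }
      if (length(seq2) <= max_path_length) {
        # keep walking even when new_set is empty? no: composition is
        # absorbing, an empty set can never become non-empty again
        if (length(new_set)) recurse(seq2, new_set)
      }
    }
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (start in nodes) {
    for (nxt in succ[[start]] %||% character()) {
      if (nxt == start) next
      recurse(c(start, nxt), preds_by_pair[[paste(start, nxt, sep = "|")]])
    }
  }
  sort(unique(found))
}

# Inferred triples of a processed document relative to a base document.
inferred_triples <- function(processed, base) {
  tri <- doc_triples(processed)
  all <- paste(tri$subject, tri$predicate, tri$object, sep = "|")
  base_tri <- doc_triples(base)
  sort(setdiff(all, paste(base_tri$subject, base_tri$predicate, base_tri$object, sep = "|")))
}
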
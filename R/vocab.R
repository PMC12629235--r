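#' Mapping predicate vocabulary and chain rules
#'
#' The predicate vocabulary ships as ordinary data so users can extend it from
#' configuration. Each predicate records whether it is symmetric and what its
#' inverse is (itself, for symmetric predicates). The chain-rule table says
#' which predicate (if any) the composition of two predicates along a path
#' yields; compositions not listed yield nothing and block chaining.
#'
#' @name predicate-vocabulary
NULL

#' Predicate and justification CURIE constants
#'
#' Convenience constants for the predicates in [default_vocabulary()] and the
#' mapping-justification terms the package records on evidence. The
#' justification terms for mutation and prioritization extend the semantic
#' mapping vocabulary, which has no terms for those operations.
#'
#' @name vocabulary-constants
#' @export
PRED_EXACT   <- "skos:exactMatch"
#' @rdname vocabulary-constants
#' @export
PRED_CLOSE   <- "skos:closeMatch"
#' @rdname vocabulary-constants
#' @export
PRED_RELATED <- "skos:relatedMatch"
#' @rdname vocabulary-constants
#' @export
PRED_BROAD   <- "skos:broadMatch"
#' @rdname vocabulary-constants
#' @export
PRED_NARROW  <- "skos:narrowMatch"
#' @rdname vocabulary-constants
#' @export
PRED_EQUIV   <- "owl:equivalentClass"
#' @rdname vocabulary-constants
#' @export
PRED_XREF    <- "oboinowl:hasDbXref"
#' @rdname vocabulary-constants
#' @export
PRED_HAS_GENE_PRODUCT <- "ro:0002205"
#' @rdname vocabulary-constants
#' @export
PRED_GENE_PRODUCT_OF  <- "ro:0002204"

#' @rdname vocabulary-constants
#' @export
JUST_UNSPECIFIED   <- "semapv:UnspecifiedMatching"
#' @rdname vocabulary-constants
#' @export
JUST_MANUAL        <- "semapv:ManualMappingCuration"
#' @rdname vocabulary-constants
#' @export
JUST_INVERSION     <- "semapv:MappingInversion"
#' @rdname vocabulary-constants
#' @export
JUST_CHAINING      <- "semapv:MappingChaining"
#' @rdname vocabulary-constants
#' @export
JUST_MUTATION      <- "semapv:MappingMutation"
#' @rdname vocabulary-constants
#' @export
JUST_PRIORITIZATION <- "semapv:MappingPrioritization"

#' Default mapping-predicate vocabulary
#'
#' Covers the SKOS match predicates, OWL class equivalence, the low-precision
#' database cross-reference predicate, and the gene/gene-product relation pair.
#'
#' @return A tibble with columns `predicate`, `label`, `symmetric`, `inverse`.
#' @export
#' @examples
#' default_vocabulary()
default_vocabulary <- function() {
  tibble::tribble(
    ~predicate,             ~label,                   ~symmetric, ~inverse,
    PRED_EXACT,             "exact match",            TRUE,       PRED_EXACT,
    PRED_CLOSE,             "close match",            TRUE,       PRED_CLOSE,
    PRED_RELATED,           "related match",          TRUE,       PRED_RELATED,
    PRED_BROAD,             "broad match",            FALSE,      PRED_NARROW,
    PRED_NARROW,            "narrow match",           FALSE,      PRED_BROAD,
    PRED_EQUIV,             "equivalent class",       TRUE,       PRED_EQUIV,
    PRED_XREF,              "database cross-reference", TRUE,     PRED_XREF,
    PRED_HAS_GENE_PRODUCT,  "has gene product",       FALSE,      PRED_GENE_PRODUCT_OF,
    PRED_GENE_PRODUCT_OF,   "gene product of",        FALSE,      PRED_HAS_GENE_PRODUCT
  )
}

#' Inverse of a predicate under a vocabulary
#'
#' @param predicate Character vector of predicate CURIEs.
#' @param vocabulary Vocabulary tibble, see [default_vocabulary()].
#' @return Character vector of inverse predicate CURIEs.
#' @export
invert_predicate <- function(predicate, vocabulary = default_vocabulary()) {
  idx <- match(predicate, vocabulary$predicate)
  if (anyNA(idx)) {
    abort(sprintf("Predicate(s) without declared inverse: %s",
                  paste(unique(predicate[is.na(idx)]), collapse = ", ")),
          class = "semmap_vocabulary_error")
  }
  vocabulary$inverse[idx]
}

#' Default predicate chain-rule table
#'
#' Composition rules used by transitive chaining, following the community
#' chaining conventions for SKOS match predicates: exact matches compose with
#' everything listed and act as the identity; broad composes with broad, narrow
#' with narrow; broad-then-narrow (and vice versa) composes to nothing; close
#' and related compose only with exact; class equivalence composes with itself
#' and degrades to the SKOS predicate when combined with exact; database
#' cross-references compose with nothing and must be mutated to a precise
#' predicate before they can participate in chains.
#'
#' @return A tibble with columns `p1`, `p2`, `result` (composed predicate).
#'   Pairs absent from the table compose to nothing.
#' @export
default_chain_rules <- function() {
  tibble::tribble(
    ~p1,          ~p2,          ~result,
    PRED_EXACT,   PRED_EXACT,   PRED_EXACT,
    PRED_EXACT,   PRED_BROAD,   PRED_BROAD,
    PRED_BROAD,   PRED_EXACT,   PRED_BROAD,
    PRED_BROAD,   PRED_BROAD,   PRED_BROAD,
    PRED_EXACT,   PRED_NARROW,  PRED_NARROW,
    PRED_NARROW,  PRED_EXACT,   PRED_NARROW,
    PRED_NARROW,  PRED_NARROW,  PRED_NARROW,
    PRED_EXACT,   PRED_CLOSE,   PRED_CLOSE,
    PRED_CLOSE,   PRED_EXACT,   PRED_CLOSE,
    PRED_EXACT,   PRED_RELATED, PRED_RELATED,
    PRED_RELATED, PRED_EXACT,   PRED_RELATED,
    PRED_EQUIV,   PRED_EQUIV,   PRED_EQUIV,
    PRED_EQUIV,   PRED_EXACT,   PRED_EXACT,
    PRED_EXACT,   PRED_EQUIV,   PRED_EXACT
  )
}

# Fast lookup environment "p1|p2" -> result for a chain-rule table.
chain_rule_index <- function(chain_rules) {
  env <- new.env(parent = emptyenv(), size = max(29L, nrow(chain_rules) * 2L))
  for (i in seq_len(nrow(chain_rules))) {
    r <- chain_rules$result[[i]]
    if (!is.na(r)) {
      assign(paste(chain_rules$p1[[i]], chain_rules$p2[[i]], sep = "|"), r, envir = env)
    }
  }
  env
}

#' Compose two predicates under a chain-rule table
#'
#' @param p1,p2 Predicate CURIEs (scalars).
#' @param rules Chain-rule table or the index built by the chaining engine.
#' @return The composed predicate CURIE, or `NA_character_` when the pair does
#'   not compose (absorbing: anything composed with nothing is nothing).
#' @export
compose_predicates <- function(p1, p2, rules = default_chain_rules()) {
  if (is.na(p1) || is.na(p2)) return(NA_character_)
  idx <- if (is.environment(rules)) rules else chain_rule_index(rules)
  get0(paste(p1, p2, sep = "|"), envir = idx, ifnotfound = NA_character_)
}
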
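#' Confidence calculus
#'
#' Confidence is propagated through a noisy-OR calculus. Every confidence is a
#' probability in `[0, 1]` that the thing it is attached to is correct.
#'
#' * Simple evidence combines the consumer's confidence in the mapping set
#'   (`c_set`) with the producer's published confidence (`c_prod`), treating
#'   the two as independent reasons to believe the mapping:
#'   `c_e = 1 - (1 - c_set)(1 - c_prod)`. When the producer published no
#'   confidence the fallback branch returns `c_set` exactly (numerically the
#'   same as assuming a producer confidence of 1 would *not* be — absence is
#'   treated as "no additional signal", collapsing the formula to `c_set`).
#' * A mapping supported by evidences `E` is correct if at least one evidence
#'   is: `c_m = 1 - prod_{e in E} (1 - c_e)`.
#' * Reasoned evidence derived from supporting mappings `M` by an operation
#'   with scaling factor `gamma` has `c_e = gamma * (1 - prod_{m in M} (1 - c_m))`.
#'
#' Because evidence may point at mappings whose own evidence is reasoned, the
#' computation recurses through the provenance graph, which must be a DAG; a
#' cycle raises a `semmap_provenance_error`.
#'
#' @name confidence-calculus
NULL

noisy_or <- function(p) {
  1 - prod(1 - p)
}

#' Confidence of an evidence object
#'
#' @param e A `semmap_evidence`.
#' @param doc The `mapping_document` the evidence lives in (resolves mapping
#'   sets and supporting mappings).
#' @param .memo,.stack Internal recursion state; leave at defaults.
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' set <- mapping_set("src", 0.9)
#' doc <- add_mapping_set(mapping_document(), set)
#' evidence_confidence(simple_evidence(set, confidence = 0.5), doc)  # 0.95
evidence_confidence <- function(e, doc, .memo = NULL, .stack = character()) {
  if (identical(e$type, "simple")) {
    set <- doc$mapping_sets[[e$mapping_set]]
    if (is.null(set)) {
      abort("Evidence cites a mapping set not registered in the document",
            class = "semmap_provenance_error")
    }
    if (is.na(e$confidence)) {
      return(set$confidence)
    }
    return(1 - (1 - set$confidence) * (1 - e$confidence))
  }
  # reasoned: gamma * noisy-OR over supporting mappings
  if (is.null(.memo)) .memo <- new.env(parent = emptyenv())
  present <- e$supports[e$supports %in% names(doc$mappings)]
  if (length(present) < length(e$supports)) {
    if (!is.na(e$support_confidence)) {
      return(e$factor * e$support_confidence)
    }
    abort("Reasoned evidence cites supporting mappings absent from the document and carries no snapshot",
          class = "semmap_provenance_error")
  }
  cms <- vapply(present, function(h) {
    mapping_confidence(doc$mappings[[h]], doc, .memo = .memo, .stack = .stack)
  }, numeric(1))
  e$factor * noisy_or(cms)
}

#' Confidence of a mapping
#'
#' Noisy-OR over the confidences of all its evidences: the probability that at
#' least one supporting evidence is correct. Monotone non-decreasing in every
#' evidence confidence and under growth of the evidence set.
#'
#' @param m A `semmap_mapping` (must carry at least one evidence).
#' @param doc The `mapping_document` it lives in.
#' @param .memo,.stack Internal recursion state; leave at defaults.
#' @return A probability in `[0, 1]`.
#' @export
mapping_confidence <- function(m, doc, .memo = NULL, .stack = character()) {
  if (!length(m$evidences)) {
    abort(sprintf("Mapping %s -> %s has an empty evidence set", m$subject, m$object),
          class = "semmap_invariant_error")
  }
  if (is.null(.memo)) .memo <- new.env(parent = emptyenv())
  h <- m$hash
  hit <- get0(h, envir = .memo, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  if (h %in% .stack) {
    abort(sprintf("Provenance cycle through mapping %s -> %s", m$subject, m$object),
          class = "semmap_provenance_error")
  }
  .stack <- c(.stack, h)
  ces <- vapply(m$evidences, function(e) {
    evidence_confidence(e, doc, .memo = .memo, .stack = .stack)
  }, numeric(1))
  out <- noisy_or(ces)
  assign(h, out, envir = .memo)
  out
}

#' Confidences of every mapping in a document
#'
#' @param doc A `mapping_document`.
#' @return Named numeric vector, mapping hash -> confidence.
#' @export
document_confidences <- function(doc) {
  memo <- new.env(parent = emptyenv())
  vapply(doc$mappings, function(m) mapping_confidence(m, doc, .memo = memo), numeric(1))
}
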
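#' Deterministic content hashing
#'
#' Mappings, evidences and mapping sets are identified by a SHA-256 digest of a
#' canonical serialization, so that identical content receives an identical
#' identifier across processes, runs and implementations. The canonical form
#' is, bit-exactly:
#'
#' * UTF-8 text of the form `kind<US>field=value<US>field=value...`, where
#'   `<US>` is the unit separator byte `0x1F`;
#' * fields appear in a fixed, documented order per kind (never alphabetized at
#'   run time);
#' * within every value, `\` is escaped as `\\` and the `0x1F` byte as
#'   `` (6 literal characters);
#' * absent optional values serialize as the empty string;
#' * numeric values serialize via `sprintf("%.17g", x)`;
#' * list-valued fields (supporting mapping hashes) are joined with `,` in
#'   their stored order.
#'
#' Field orders:
#' * mapping: `mapping<US>subject=s<US>predicate=p<US>object=o` — a mapping's
#'   identity covers only its triple, so accruing evidence never changes it;
#' * mapping set: `mapping_set<US>name=n<US>version=v<US>license=l` (consumer
#'   confidence is the consumer's, not the set's content, and is excluded);
#' * simple evidence:
#'   `evidence:simple<US>justification=j<US>author=a<US>confidence=c<US>mapping_set=H(set)`;
#' * reasoned evidence:
#'   `evidence:reasoned<US>justification=j<US>operation=op<US>factor=f<US>supports=h1,h2,...`.
#'
#' The digest algorithm name is recorded as `hash_algorithm: sha256` in every
#' export so digests are comparable across implementations.
#'
#' @name content-hashing
NULL

HASH_ALGORITHM <- "sha256"
.US <- "\x1f"

hash_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub(.US, "\\u001f", x, fixed = TRUE)
}

hash_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

hash_chr <- function(x) {
  ifelse(is.na(x), "", hash_escape(x))
}

sha256_hex <- function(x) {
  as.character(openssl::sha256(x))
}

#' Content hash of a mapping triple
#'
#' Vectorized over its arguments. Covers only (subject, predicate, object):
#' two mappings with the same triple share a hash regardless of evidence.
#'
#' @param subject,predicate,object CURIE character vectors.
#' @return Character vector of hex digests.
#' @export
#' @examples
#' mapping_hash("fx1:1", "skos:exactMatch", "fx2:1")
mapping_hash <- function(subject, predicate, object) {
  sha256_hex(paste0(
    "mapping", .US,
    "subject=", hash_chr(subject), .US,
    "predicate=", hash_chr(predicate), .US,
    "object=", hash_chr(object)
  ))
}

#' Content hash of a mapping set (name, version, license)
#'
#' @param name,version,license Character scalars; version and license may be
#'   empty strings.
#' @return Hex digest string.
#' @export
mapping_set_hash <- function(name, version = "", license = "") {
  sha256_hex(paste0(
    "mapping_set", .US,
    "name=", hash_chr(name), .US,
    "version=", hash_chr(version), .US,
    "license=", hash_chr(license)
  ))
}

simple_evidence_hash <- function(justification, author, confidence, mapping_set_hash) {
  sha256_hex(paste0(
    "evidence:simple", .US,
    "justification=", hash_chr(justification), .US,
    "author=", hash_chr(author), .US,
    "confidence=", hash_num(confidence), .US,
    "mapping_set=", mapping_set_hash
  ))
}

reasoned_evidence_hash <- function(justification, operation, factor, supports) {
  sha256_hex(paste0(
    "evidence:reasoned", .US,
    "justification=", hash_chr(justification), .US,
    "operation=", hash_chr(operation), .US,
    "factor=", hash_num(factor), .US,
    "supports=", paste(supports, collapse = ",")
  ))
}

#' Content hash of a model object
#'
#' Dispatches on the model classes: `semmap_mapping`, `semmap_mapping_set`,
#' and the two evidence classes. See [content-hashing] for the canonical
#' serialization each hash covers.
#'
#' @param x A mapping, mapping set, or evidence object.
#' @return Hex digest string.
#' @export
content_hash <- function(x) {
  UseMethod("content_hash")
}

#' @export
content_hash.semmap_mapping <- function(x) {
  mapping_hash(x$subject, x$predicate, x$object)
}

#' @export
content_hash.semmap_mapping_set <- function(x) {
  mapping_set_hash(x$name, x$version, x$license)
}

#' @export
content_hash.semmap_evidence <- function(x) {
  if (identical(x$type, "simple")) {
    simple_evidence_hash(x$justification, x$author, x$confidence, x$mapping_set)
  } else {
    reasoned_evidence_hash(x$justification, x$operation, x$factor, x$supports)
  }
}
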
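#' Prefix registries and CURIE validation
#'
#' A prefix registry maps identifier-space prefixes (the part of a CURIE before
#' the colon) to their canonical casing and URI expansion, and records
#' lower-cased synonyms. The registry shipped with the package is a small,
#' frozen subset sufficient for the predicate vocabulary, the worked examples
#' and the synthetic fixtures; production users can build their own registry
#' from a community resource such as the Bioregistry export and pass it to any
#' function that takes a `registry` argument. No network access is ever
#' performed.
#'
#' @name prefix-registry
NULL

new_prefix_registry <- function(entries) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  synonyms <- list()
  for (canonical in names(entries)) {
    e <- entries[[canonical]]
    syns <- unique(c(tolower(canonical), tolower(e$synonyms %||% character())))
    for (s in syns) synonyms[[s]] <- canonical
  }
  structure(
    list(entries = entries, synonyms = synonyms),
    class = "prefix_registry"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Default frozen prefix registry
#'
#' Contains the mapping-predicate and justification vocabularies (`skos`,
#' `owl`, `oboinowl`, `ro`, `semapv`, `orcid`), a handful of real biomedical
#' prefixes used in documentation examples (`clo`, `cellosaurus`, `hgnc`,
#' `mesh`), reserved toy prefixes for the worked cell-line example
#' (`tcell`, `tclo`, `tbto`, `tdep`, `tccle`, `tefo`) and reserved synthetic
#' fixture prefixes `fx1` ... `fx26`. Toy and fixture prefixes resolve under
#' `https://example.org/` so they can never be mistaken for claims about real
#' resources.
#'
#' @return A `prefix_registry` object.
#' @export
#' @examples
#' reg <- default_registry()
#' validate_reference("CLO:0001072", reg)
default_registry <- function() {
  ex <- function(uri, syn = character()) list(uri_prefix = uri, synonyms = syn)
  entries <- list(
    skos       = ex("http://www.w3.org/2004/02/skos/core#"),
    owl        = ex("http://www.w3.org/2002/07/owl#"),
    oboinowl   = ex("http://www.geneontology.org/formats/oboInOwl#", "oboInOwl"),
    ro         = ex("http://purl.obolibrary.org/obo/RO_", "RO"),
    semapv     = ex("https://w3id.org/semapv/vocab/"),
    orcid      = ex("https://orcid.org/"),
    clo        = ex("http://purl.obolibrary.org/obo/CLO_", "CLO"),
    cellosaurus = ex("https://www.cellosaurus.org/", "Cellosaurus"),
    hgnc       = ex("https://bioregistry.io/hgnc:", "HGNC"),
    mesh       = ex("http://id.nlm.nih.gov/mesh/", "MeSH")
  )
  for (p in c("tcell", "tclo", "tbto", "tdep", "tccle", "tefo")) {
    entries[[p]] <- ex(paste0("https://example.org/", p, "/"))
  }
  for (i in seq_len(26)) {
    p <- paste0("fx", i)
    entries[[p]] <- ex(paste0("https://example.org/", p, "/"))
  }
  new_prefix_registry(entries)
}

#' Add a prefix to a registry
#'
#' @param registry A `prefix_registry`.
#' @param prefix Canonical prefix string (non-empty).
#' @param uri_prefix URI expansion for the prefix.
#' @param synonyms Optional character vector of alternative casings/spellings.
#' @return The extended registry.
#' @export
register_prefix <- function(registry, prefix, uri_prefix = paste0("https://example.org/", prefix, "/"),
                            synonyms = character()) {
  stopifnot(inherits(registry, "prefix_registry"), nzchar(prefix))
  registry$entries[[prefix]] <- list(uri_prefix = uri_prefix, synonyms = synonyms)
  new_prefix_registry(registry$entries)
}

registry_prefixes <- function(registry) names(registry$entries)

#' Resolve a prefix to its canonical form
#'
#' Case-insensitive lookup through the registry's synonym table.
#'
#' @param prefix Character vector of raw prefixes.
#' @param registry A `prefix_registry`.
#' @return Character vector of canonical prefixes, `NA` where unknown.
#' @export
resolve_prefix <- function(prefix, registry) {
  hits <- registry$synonyms[tolower(prefix)]
  vapply(hits, function(h) if (is.null(h)) NA_character_ else h, character(1), USE.NAMES = FALSE)
}

#' Validate and normalize a CURIE against a prefix registry
#'
#' Splits `prefix:local_id` at the first colon, normalizes the prefix to the
#' registry's canonical casing (synonyms allowed) and keeps the local
#' identifier verbatim. Validation never rewrites local identifiers.
#'
#' @param raw_curie A single CURIE string containing at least one colon.
#' @param registry A `prefix_registry`.
#' @return A `semmap_reference`: list with `prefix`, `local_id` and the
#'   normalized `curie`.
#' @export
#' @examples
#' validate_reference("CLO:0001072", default_registry())
validate_reference <- function(raw_curie, registry) {
  stopifnot(is.character(raw_curie), length(raw_curie) == 1L)
  if (!grepl(":", raw_curie, fixed = TRUE)) {
    abort(sprintf("Malformed CURIE (no colon): '%s'", raw_curie), class = "semmap_curie_error")
  }
  colon <- regexpr(":", raw_curie, fixed = TRUE)
  prefix <- substr(raw_curie, 1L, colon - 1L)
  local_id <- substr(raw_curie, colon + 1L, nchar(raw_curie))
  if (!nzchar(prefix)) {
    abort(sprintf("Malformed CURIE (empty prefix): '%s'", raw_curie), class = "semmap_curie_error")
  }
  canonical <- resolve_prefix(prefix, registry)
  if (is.na(canonical)) {
    abort(sprintf("Unknown prefix '%s' in CURIE '%s'", prefix, raw_curie),
          class = "semmap_unknown_prefix")
  }
  structure(
    list(prefix = canonical, local_id = local_id,
         curie = paste0(canonical, ":", local_id)),
    class = "semmap_reference"
  )
}

#' @export
print.semmap_reference <- function(x, ...) {
  cat("<reference>", x$curie, "\n")
  invisible(x)
}

#' @export
format.semmap_reference <- function(x, ...) x$curie

#' Normalize a vector of CURIEs
#'
#' Vectorized counterpart of [validate_reference()]. With `strict = TRUE`
#' (default) any malformed CURIE or unknown prefix raises an error naming the
#' offenders; otherwise offending entries come back as `NA` with a warning.
#'
#' @param curies Character vector of CURIEs.
#' @param registry A `prefix_registry`.
#' @param strict Fail on any invalid entry (`TRUE`) or return `NA` for it.
#' @return Character vector of normalized CURIEs.
#' @export
normalize_curies <- function(curies, registry, strict = TRUE) {
  colon <- regexpr(":", curies, fixed = TRUE)
  bad_form <- colon <= 1L | is.na(curies)
  prefix <- ifelse(bad_form, NA_character_, substr(curies, 1L, colon - 1L))
  local <- ifelse(bad_form, NA_character_, substr(curies, colon + 1L, nchar(curies)))
  canonical <- resolve_prefix(prefix, registry)
  out <- ifelse(is.na(canonical), NA_character_, paste0(canonical, ":", local))
  if (any(is.na(out))) {
    bad <- curies[is.na(out)]
    unknown <- unique(prefix[!bad_form & is.na(canonical)])
    msg <- sprintf(
      "%d invalid CURIE(s)%s; e.g. '%s'", length(bad),
      if (length(unknown)) paste0(" (unknown prefixes: ", paste(unknown, collapse = ", "), ")") else "",
      bad[[1]]
    )
    if (strict) abort(msg, class = "semmap_curie_error") else warn(msg)
  }
  out
}

curie_prefix <- function(curies) {
  sub(":.*$", "", curies)
}

#' Prefix map (CURIE prefix to URI prefix) for a set of prefixes
#'
#' @param prefixes Character vector of canonical prefixes.
#' @param registry A `prefix_registry`.
#' @return Named character vector prefix -> URI prefix.
#' @export
prefix_map_for <- function(prefixes, registry) {
  prefixes <- sort(unique(prefixes))
  uris <- vapply(prefixes, function(p) {
    e <- registry$entries[[p]]
    if (is.null(e)) abort(sprintf("Prefix '%s' not in registry", p), class = "semmap_unknown_prefix")
    e$uri_prefix
  }, character(1))
  setNames(uris, prefixes)
}
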
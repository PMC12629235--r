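#' SSSOM TSV input and output
#'
#' The reader and writer speak a pragmatic SSSOM TSV dialect: an optional
#' leading block of `#`-prefixed YAML metadata (curie map and set-level
#' fields), then a header row and one data row per (mapping, evidence) pair.
#' Required columns are `subject_id`, `predicate_id`, `object_id` and
#' `mapping_justification`. Recognized optional columns: `confidence`
#' (producer confidence), `author_id`, `mapping_set_name`,
#' `mapping_set_version`, `mapping_set_license`, `mapping_set_confidence`
#' (consumer confidence), and — for reasoned evidence, as documented extension
#' columns — `reasoning_operation`, `reasoning_factor` and
#' `supporting_mapping_hashes` (pipe-separated content hashes; standard SSSOM
#' has no slot for multi-mapping provenance). Unknown columns are preserved in
#' a pass-through extension map and written back on export.
#'
#' @name sssom-io
NULL

SSSOM_REQUIRED <- c("subject_id", "predicate_id", "object_id", "mapping_justification")
SSSOM_KNOWN <- c(SSSOM_REQUIRED, "confidence", "author_id",
                 "mapping_set_name", "mapping_set_version", "mapping_set_license",
                 "mapping_set_confidence", "reasoning_operation", "reasoning_factor",
                 "supporting_mapping_hashes")

read_sssom_metadata <- function(path) {
  lines <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l) || !startsWith(l, "#")) break
    lines <- c(lines, sub("^#\\s?", "", l))
  }
  if (!length(lines)) return(list())
  meta <- tryCatch(yaml::yaml.load(paste(lines, collapse = "\n")), error = function(e) NULL)
  if (is.list(meta)) meta else list()
}

#' Read a mapping document from SSSOM TSV
#'
#' Each data row becomes one simple evidence attached to its (possibly merged)
#' unique triple; duplicate triples across rows merge evidences. A row-level
#' `confidence` column becomes the producer confidence. Rows whose
#' `supporting_mapping_hashes` column is non-empty are reconstructed as
#' reasoned evidence.
#'
#' @param path Path to an SSSOM TSV file, optionally with a leading
#'   `#`-prefixed YAML metadata block.
#' @param set_defaults Named list with `name`, `version`, `license` used for
#'   rows that carry no per-row mapping-set columns; the file's embedded
#'   metadata block takes precedence over these, per-row columns over both.
#' @param consumer_confidence Consumer confidence assigned to mapping sets that
#'   do not state one (column `mapping_set_confidence`); default 1.
#' @param registry Prefix registry for CURIE normalization.
#' @param strict `TRUE` (library mode): any malformed CURIE fails with its line
#'   number. `FALSE` (pipeline mode): offending rows are skipped with a
#'   warning.
#' @return A `mapping_document`.
#' @export
read_sssom <- function(path, set_defaults = list(name = basename(path)),
                       consumer_confidence = 1,
                       registry = default_registry(), strict = TRUE) {
  meta <- read_sssom_metadata(path)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(SSSOM_REQUIRED, names(tab))
  if (length(missing)) {
    abort(sprintf("SSSOM file '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "semmap_format_error")
  }
  set_name <- meta$mapping_set_name %||% set_defaults$name %||% basename(path)
  set_version <- meta$mapping_set_version %||% set_defaults$version %||% ""
  set_license <- meta$license %||% set_defaults$license %||% ""
  default_conf <- as.numeric(meta$mapping_set_confidence %||% consumer_confidence)

  doc <- mapping_document()
  if (!nrow(tab)) {
    doc <- add_mapping_set(doc, mapping_set(set_name, default_conf, set_version, set_license))
    doc$prefix_map <- character()
    return(doc)
  }

  subj <- suppressWarnings(normalize_curies(tab$subject_id, registry, strict = FALSE))
  pred <- suppressWarnings(normalize_curies(tab$predicate_id, registry, strict = FALSE))
  obj <- suppressWarnings(normalize_curies(tab$object_id, registry, strict = FALSE))
  bad <- which(is.na(subj) | is.na(pred) | is.na(obj))
  if (length(bad)) {
    msg <- sprintf("%d row(s) with unparseable CURIEs in '%s' (data rows: %s)",
                   length(bad), path, paste(head(bad, 5L), collapse = ", "))
    if (strict) abort(msg, class = "semmap_curie_error")
    warn(paste0(msg, " — skipped"))
    keep <- setdiff(seq_len(nrow(tab)), bad)
    tab <- tab[keep, , drop = FALSE]
    subj <- subj[keep]; pred <- pred[keep]; obj <- obj[keep]
  }

  col_or <- function(col, default) if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  set_names <- col_or("mapping_set_name", set_name)
  set_versions <- col_or("mapping_set_version", set_version)
  set_licenses <- col_or("mapping_set_license", set_license)
  set_confs <- suppressWarnings(as.numeric(col_or("mapping_set_confidence", default_conf)))
  set_versions[is.na(set_versions)] <- set_version
  set_licenses[is.na(set_licenses)] <- set_license
  set_names[is.na(set_names)] <- set_name
  set_confs[is.na(set_confs)] <- default_conf

  set_key <- paste(set_names, set_versions, set_licenses, set_confs, sep = "\x1f")
  sets <- list()
  set_hashes <- character(nrow(tab))
  for (k in unique(set_key)) {
    i <- which(set_key == k)[1]
    s <- mapping_set(set_names[i], set_confs[i], set_versions[i], set_licenses[i])
    sets[[s$hash]] <- s
    set_hashes[set_key == k] <- s$hash
  }

  prod_conf <- suppressWarnings(as.numeric(col_or("confidence", NA_real_)))
  authors <- col_or("author_id", NA_character_)
  supports_raw <- col_or("supporting_mapping_hashes", NA_character_)
  ops <- col_or("reasoning_operation", NA_character_)
  factors <- suppressWarnings(as.numeric(col_or("reasoning_factor", NA_real_)))
  extra_cols <- setdiff(names(tab), SSSOM_KNOWN)

  for (s in sets) doc <- add_mapping_set(doc, s)
  is_reasoned <- !is.na(supports_raw) & nzchar(supports_raw)
  hashes <- mapping_hash(subj, pred, obj)
  for (i in seq_len(nrow(tab))) {
    if (is_reasoned[i]) {
      ev <- reasoned_evidence(
        operation = ops[i] %|na|% "chain",
        supports = strsplit(supports_raw[i], "|", fixed = TRUE)[[1]],
        factor = factors[i] %|na|% 1,
        justification = tab$mapping_justification[i]
      )
    } else {
      ev <- simple_evidence(set_hashes[i], tab$mapping_justification[i],
                            authors[i], prod_conf[i])
    }
    if (length(extra_cols)) {
      ext <- as.list(tab[i, extra_cols, drop = FALSE])
      ext <- ext[!vapply(ext, function(v) is.na(v[[1]]), logical(1))]
      if (length(ext)) ev$extensions <- ext
    }
    doc <- add_mapping(doc, new_mapping(subj[i], pred[i], obj[i], list(ev)))
  }
  pm <- prefix_map_for(unique(curie_prefix(c(subj, obj))), registry)
  if (is.list(meta$curie_map)) {
    extra_pm <- unlist(meta$curie_map)
    pm <- c(pm, extra_pm[setdiff(names(extra_pm), names(pm))])
  }
  doc$prefix_map <- pm
  sort_document(doc)
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

#' Write a mapping document to SSSOM TSV
#'
#' One row per (mapping, evidence) pair, preceded by a `#`-prefixed YAML
#' metadata block carrying the curie map and the digest algorithm name.
#' Reasoned evidence rows carry the reasoning justification term plus the
#' `reasoning_operation`, `reasoning_factor` and `supporting_mapping_hashes`
#' extension columns. `read_sssom(write_sssom(doc))` preserves triples,
#' predicates, evidence counts and confidences.
#'
#' @param doc A `mapping_document`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sssom <- function(doc, path) {
  doc <- sort_document(doc)
  rows <- list()
  for (m in doc$mappings) {
    for (e in m$evidences) {
      set <- if (e$type == "simple") doc$mapping_sets[[e$mapping_set]] else NULL
      rows[[length(rows) + 1L]] <- c(
        list(
          subject_id = m$subject, predicate_id = m$predicate, object_id = m$object,
          mapping_justification = e$justification,
          confidence = if (e$type == "simple") e$confidence else NA_real_,
          author_id = if (e$type == "simple") e$author else NA_character_,
          mapping_set_name = if (is.null(set)) NA_character_ else set$name,
          mapping_set_version = if (is.null(set)) NA_character_ else set$version,
          mapping_set_license = if (is.null(set)) NA_character_ else set$license,
          mapping_set_confidence = if (is.null(set)) NA_real_ else set$confidence,
          reasoning_operation = if (e$type == "reasoned") e$operation else NA_character_,
          reasoning_factor = if (e$type == "reasoned") e$factor else NA_real_,
          supporting_mapping_hashes = if (e$type == "reasoned") paste(e$supports, collapse = "|") else NA_character_
        ),
        if (!is.null(e$extensions)) lapply(e$extensions, `[[`, 1L) else list()
      )
    }
  }
  tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (!nrow(tab)) {
    tab <- tibble::as_tibble(setNames(
      rep(list(character()), length(SSSOM_KNOWN)), SSSOM_KNOWN))
  }
  meta <- c(
    "hash_algorithm: sha256",
    "curie_map:",
    if (length(doc$prefix_map)) {
      paste0("  ", names(doc$prefix_map), ": ", unname(doc$prefix_map))
    }
  )
  con <- file(path, "w")
  writeLines(paste0("# ", meta), con)
  close(con)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, na = "")
  invisible(path)
}

#' Read a bare cross-reference TSV under a declared default predicate
#'
#' Minimal importer for two-column (subject CURIE, object CURIE) files as
#' distributed by many resources. Every row becomes a mapping with the
#' declared default predicate and an unspecified-matching justification;
#' duplicated rows deduplicate to a single evidence by content hash.
#'
#' @param path Path to a TSV whose first two columns are CURIEs. A header row
#'   is auto-detected (a first row that does not parse as two CURIEs is taken
#'   as a header).
#' @param set A `semmap_mapping_set` describing the source (carries the
#'   consumer confidence).
#' @param default_predicate Predicate assigned to every row; defaults to the
#'   database cross-reference predicate.
#' @param justification Justification term recorded on every evidence.
#' @param registry Prefix registry for CURIE normalization.
#' @param strict As in [read_sssom()].
#' @param exclude_prefixes Optional character vector; rows whose subject or
#'   object prefix is listed are dropped with a message.
#' @return A `mapping_document`.
#' @export
read_xref_tsv <- function(path, set, default_predicate = PRED_XREF,
                          justification = JUST_UNSPECIFIED,
                          registry = default_registry(), strict = TRUE,
                          exclude_prefixes = character()) {
  stopifnot(inherits(set, "semmap_mapping_set"))
  tab <- readr::read_tsv(path, comment = "#", col_names = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tab) < 2L) {
    abort(sprintf("Cross-reference file '%s' needs at least 2 columns", path),
          class = "semmap_format_error")
  }
  if (nrow(tab)) {
    first_ok <- !is.na(suppressWarnings(normalize_curies(unlist(tab[1, 1:2]), registry, strict = FALSE)))
    if (!all(first_ok)) tab <- tab[-1, , drop = FALSE]  # header row
  }
  if (!nrow(tab)) {
    doc <- add_mapping_set(mapping_document(), set)
    return(doc)
  }
  subj <- suppressWarnings(normalize_curies(tab[[1]], registry, strict = FALSE))
  obj <- suppressWarnings(normalize_curies(tab[[2]], registry, strict = FALSE))
  bad <- which(is.na(subj) | is.na(obj))
  if (length(bad)) {
    msg <- sprintf("%d row(s) with unparseable CURIEs in '%s'", length(bad), path)
    if (strict) abort(msg, class = "semmap_curie_error")
    warn(paste0(msg, " — skipped"))
  }
  keep <- setdiff(seq_along(subj), bad)
  if (length(exclude_prefixes)) {
    excl <- curie_prefix(subj) %in% exclude_prefixes | curie_prefix(obj) %in% exclude_prefixes
    n_excl <- sum(excl[keep])
    if (n_excl) message(sprintf("read_xref_tsv: dropped %d row(s) with excluded prefixes", n_excl))
    keep <- keep[!excl[keep]]
  }
  rows <- tibble::tibble(
    subject = subj[keep],
    predicate = default_predicate,
    object = obj[keep],
    justification = justification,
    author = NA_character_,
    confidence = NA_real_,
    mapping_set = set$hash
  )
  document_from_rows(rows, list(set), registry)
}
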
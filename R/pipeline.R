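#' Declarative pipeline configuration and orchestration
#'
#' A pipeline is declared in a YAML file and run end-to-end: ingest the listed
#' inputs, apply mutations, inversions, chaining and filters, assemble
#' prioritization/projection outputs, and write every requested export. The
#' core pipeline is deterministic by construction (canonical ordering
#' everywhere); the seed only governs optional sampling utilities and fixture
#' generation.
#'
#' Schema (version 1) — top-level keys, all optional unless noted:
#' * `inputs` (required): list of `{path, kind: sssom|xref, predicate,
#'   mapping_set: {name, version, license, confidence}}`
#' * `mutations`: list of `{source, target, factor, subject_prefix,
#'   object_prefix}`
#' * `inversions`: logical (default `true`)
#' * `chains`: `{max_path_length (default 5), factor (default 1)}` or `false`
#' * `chain_rules`: list of `{p1, p2, result}` overriding the default table
#' * `filters`: ordered list of `{kind, ...}` (see [filter_rule()])
#' * `negatives`: list of SSSOM paths of curated negative mappings
#' * `priority`: prefix list (required when a prioritization output is asked)
#' * `on_conflict`: `error|exclude|demote` for prioritization cliques
#' * `outputs`: list of `{kind: sssom|pgraph|prioritization|projection,
#'   path, format: sssom|tsv, source, target}`
#' * `seed`: integer (default 1); `strict`: logical (default `false`:
#'   pipeline mode skips and logs bad rows)
#'
#' @name pipeline
NULL

CONFIG_DEFAULTS <- list(
  schema_version = 1L, mutations = list(), inversions = TRUE,
  chains = list(max_path_length = 5L, factor = 1),
  chain_rules = NULL, filters = list(), negatives = list(),
  priority = character(), on_conflict = "error", outputs = list(),
  seed = 1L, strict = FALSE
)

#' Load and validate a pipeline configuration
#'
#' @param path YAML file path, or a list already in config shape.
#' @return A validated `pipeline_config` with all defaults filled; the names
#'   of defaulted fields are recorded in attribute `"defaulted"`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) abort("Config must be a YAML mapping", class = "semmap_config_error")
  defaulted <- setdiff(names(CONFIG_DEFAULTS), names(cfg))
  for (k in defaulted) cfg[[k]] <- CONFIG_DEFAULTS[[k]]
  # canonical scalar-vector fields so YAML round-trips are lossless
  cfg$priority <- as.character(unlist(cfg$priority))
  cfg$negatives <- as.character(unlist(cfg$negatives))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config", defaulted = defaulted)
}

validate_config <- function(cfg) {
  fail <- function(field, constraint) {
    abort(sprintf("Config field `%s`: %s", field, constraint), class = "semmap_config_error")
  }
  if (!length(cfg$inputs)) fail("inputs", "at least one input is required")
  for (i in seq_along(cfg$inputs)) {
    inp <- cfg$inputs[[i]]
    if (is.null(inp$path)) fail(sprintf("inputs[%d].path", i), "is required")
    kind <- inp$kind %||% "sssom"
    if (!kind %in% c("sssom", "xref")) {
      fail(sprintf("inputs[%d].kind", i), "must be 'sssom' or 'xref'")
    }
    conf <- inp$mapping_set$confidence
    if (!is.null(conf) && (!is.numeric(conf) || conf < 0 || conf > 1)) {
      fail(sprintf("inputs[%d].mapping_set.confidence", i), "must lie in [0, 1]")
    }
  }
  for (i in seq_along(cfg$mutations)) {
    f <- cfg$mutations[[i]]$factor %||% 1
    if (!is.numeric(f) || f < 0 || f > 1) {
      fail(sprintf("mutations[%d].factor", i), "must lie in [0, 1]")
    }
  }
  if (!isFALSE(cfg$chains)) {
    mpl <- cfg$chains$max_path_length %||% 5L
    if (!is.numeric(mpl) || mpl < 2) fail("chains.max_path_length", "must be >= 2")
  }
  for (i in seq_along(cfg$filters)) {
    fr <- cfg$filters[[i]]
    if (identical(fr$kind, "confidence_threshold") &&
        (!is.numeric(fr$threshold) || fr$threshold < 0 || fr$threshold > 1)) {
      fail(sprintf("filters[%d].threshold", i), "must lie in [0, 1]")
    }
  }
  wants_prio <- any(vapply(cfg$outputs, function(o) identical(o$kind, "prioritization"), logical(1)))
  if (wants_prio && !length(cfg$priority)) {
    fail("priority", "must be non-empty when a prioritization output is requested")
  }
  invisible(cfg)
}

#' Write a pipeline configuration back to YAML
#'
#' `load_config(write_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param cfg A `pipeline_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

file_sha256 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  unclass(as.character(openssl::sha256(con)))
}

config_mutation_rules <- function(cfg) {
  lapply(cfg$mutations, function(m) {
    mutation_rule(m$source, m$target, m$factor %||% 1,
                  m$subject_prefix, m$object_prefix)
  })
}

config_filter_rules <- function(cfg, base_dir, registry) {
  lapply(cfg$filters, function(f) {
    if (identical(f$kind, "negatives") && is.character(f$negatives)) {
      f$negatives <- read_negatives(file.path(base_dir, f$negatives), registry)
    }
    if (is.list(f$prefixes)) f$prefixes <- unlist(f$prefixes)
    do.call(filter_rule, f[names(f) != "kind"] |> c(list(kind = f$kind)))
  })
}

#' Run a declarative pipeline end-to-end
#'
#' Ingest, process, assemble, export. Repeated runs on identical inputs and
#' config produce byte-identical outputs; the run report carries a
#' content-hash manifest so this is checkable.
#'
#' @param config A `pipeline_config` (or a path, passed to [load_config()]).
#' @param base_dir Directory against which relative input/output paths
#'   resolve.
#' @param registry Prefix registry.
#' @return A run report: list with `log` (per-stage mapping/evidence counts),
#'   `n_cliques`, `reduction` (raw/unique/reduction tibble), `removed`
#'   (filtered mappings), `cardinality_flags`, `outputs` (tibble of written
#'   paths and their SHA-256 digests), and `doc` (the processed document).
#' @export
run_pipeline <- function(config, base_dir = ".", registry = default_registry()) {
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- load_config(config)
  }
  strict <- isTRUE(config$strict)
  docs <- list()
  for (inp in config$inputs) {
    path <- file.path(base_dir, inp$path)
    kind <- inp$kind %||% "sssom"
    ms_meta <- inp$mapping_set %||% list()
    if (kind == "sssom") {
      docs[[length(docs) + 1L]] <- read_sssom(
        path,
        set_defaults = list(name = ms_meta$name %||% basename(path),
                            version = ms_meta$version, license = ms_meta$license),
        consumer_confidence = ms_meta$confidence %||% 1,
        registry = registry, strict = strict)
    } else {
      set <- mapping_set(ms_meta$name %||% basename(path),
                         ms_meta$confidence %||% 1,
                         ms_meta$version %||% "", ms_meta$license %||% "")
      docs[[length(docs) + 1L]] <- read_xref_tsv(
        path, set,
        default_predicate = inp$predicate %||% PRED_XREF,
        registry = registry, strict = strict,
        exclude_prefixes = unlist(inp$exclude_prefixes) %||% character())
    }
  }
  doc <- merge_documents(docs)

  negatives <- NULL
  if (length(config$negatives)) {
    negatives <- dplyr::bind_rows(lapply(config$negatives, function(p) {
      read_negatives(file.path(base_dir, p), registry)
    }))
  }

  chains <- if (isFALSE(config$chains)) NULL else {
    list(max_path_length = config$chains$max_path_length %||% 5L,
         factor = config$chains$factor %||% 1,
         rules = if (!is.null(config$chain_rules)) {
           dplyr::bind_rows(lapply(config$chain_rules, tibble::as_tibble))
         } else default_chain_rules())
  }

  doc <- full_process(
    doc,
    mutations = config_mutation_rules(config),
    inversions = isTRUE(config$inversions),
    chains = chains,
    filters = config_filter_rules(config, base_dir, registry),
    negatives = negatives
  )

  red <- reduction_stats(doc)
  prio <- NULL
  if (length(config$priority)) {
    prio <- build_prioritization(doc, unlist(config$priority),
                                 on_conflict = config$on_conflict %||% "error")
  }

  out_rows <- list()
  record <- function(path) {
    out_rows[[length(out_rows) + 1L]] <<- tibble::tibble(
      path = path, sha256 = file_sha256(path))
  }
  for (out in config$outputs) {
    path <- file.path(base_dir, out$path)
    switch(out$kind,
      sssom = { write_sssom(doc, path); record(path) },
      pgraph = {
        paths <- export_property_graph(doc, path)
        for (p in unlist(paths)) record(p)
      },
      prioritization = {
        if (is.null(prio)) abort("Prioritization output requested without `priority`",
                                 class = "semmap_config_error")
        if (identical(out$format %||% "tsv", "sssom")) {
          write_sssom(prio$doc, path)
        } else {
          write_two_column(prio, path)
        }
        record(path)
      },
      projection = {
        proj <- build_projection(doc, out$source, out$target)
        if (identical(out$format %||% "tsv", "sssom")) {
          write_sssom(proj$doc, path)
        } else {
          write_two_column(proj, path)
        }
        record(path)
      },
      abort(sprintf("Unknown output kind '%s'", out$kind), class = "semmap_config_error")
    )
  }

  list(
    log = attr(doc, "processing_log"),
    n_cliques = red$n_cliques,
    reduction = red,
    removed = attr(doc, "removed"),
    cardinality_flags = attr(doc, "cardinality_flags"),
    prioritization = prio,
    outputs = if (length(out_rows)) dplyr::bind_rows(out_rows) else
      tibble::tibble(path = character(), sha256 = character()),
    doc = doc
  )
}
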
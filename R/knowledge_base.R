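#' Load the gene-syndrome knowledge base
#'
#' Reads the structured-text (YAML) knowledge base that encodes the curated
#' gene panel: genes with their inheritance mode and associated syndromes,
#' key clinical features grouped into body systems with linked HPO terms,
#' and per-syndrome major/minor feature weights. Weights may optionally be
#' restricted to a subset of a syndrome's genes, which is how
#' syndrome-variant footnotes (features seen only with particular genes)
#' are encoded.
#'
#' All cross-references are validated on load; any dangling reference,
#' unknown body-system label, duplicate weight for a (syndrome, feature)
#' pair, or malformed field is an error, never a warning.
#'
#' @param path Path to a YAML knowledge-base file. The packaged ciliopathy
#'   panel lives at
#'   `system.file("extdata", "ciliopathy_kb.yaml", package = "revphen")`.
#' @return An object of class `knowledge_base`: a list with tibbles `genes`
#'   (`symbol`, `inheritance`, `canonical_transcript`, `syndromes`
#'   list-column), `features` (`feature_id`, `label`, `system`, `hpo_terms`
#'   list-column), `weights` (`syndrome_id`, `feature_id`, `weight`, `genes`
#'   list-column of optional gene restrictions), `syndromes` (`syndrome_id`,
#'   `label`), plus the `systems` character vector and `schema_version`.
#' @export
#' @examples
#' kb <- load_knowledge_base(
#'   system.file("extdata", "ciliopathy_kb.yaml", package = "revphen")
#' )
#' glance(kb)
load_knowledge_base <- function(path) {
  check_file_exists(path)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_validation("cannot parse knowledge base: ", conditionMessage(e))
  )
  if (is.null(raw) || !is.list(raw) || length(raw) == 0L) {
    stop_validation("knowledge base file is empty: ", path)
  }
  for (f in c("schema_version", "systems", "syndromes", "genes", "features", "weights")) {
    if (is.null(raw[[f]])) stop_validation("knowledge base missing field: ", f)
  }

  systems <- as.character(raw$systems)
  syndromes <- tibble(
    syndrome_id = purrr::map_chr(raw$syndromes, "id"),
    label = purrr::map_chr(raw$syndromes, "label")
  )

  genes <- tibble(
    symbol = purrr::map_chr(raw$genes, "symbol"),
    inheritance = purrr::map_chr(raw$genes, "inheritance"),
    canonical_transcript = purrr::map_chr(raw$genes, "canonical_transcript"),
    syndromes = purrr::map(raw$genes, ~ as.character(.x$syndromes))
  )
  bad_inh <- setdiff(genes$inheritance, c("autosomal_recessive", "x_linked"))
  if (length(bad_inh) > 0L) {
    stop_validation("unknown inheritance mode: ", paste(bad_inh, collapse = ", "))
  }
  dangling <- setdiff(unlist(genes$syndromes), syndromes$syndrome_id)
  if (length(dangling) > 0L) {
    stop_validation("gene references unknown syndrome: ", paste(dangling, collapse = ", "))
  }

  features <- tibble(
    feature_id = purrr::map_chr(raw$features, "id"),
    label = purrr::map_chr(raw$features, "label"),
    system = purrr::map_chr(raw$features, "system"),
    hpo_terms = purrr::map(raw$features, ~ as.character(.x$hpo))
  )
  bad_sys <- setdiff(features$system, systems)
  if (length(bad_sys) > 0L) {
    stop_validation("unknown body-system label: ", paste(bad_sys, collapse = ", "))
  }
  if (any(lengths(features$hpo_terms) == 0L)) {
    stop_validation("every clinical feature needs at least one linked HPO term")
  }

  weights <- tibble(
    syndrome_id = purrr::map_chr(raw$weights, "syndrome"),
    feature_id = purrr::map_chr(raw$weights, "feature"),
    weight = purrr::map_chr(raw$weights, "weight"),
    genes = purrr::map(raw$weights, ~ if (is.null(.x$genes)) character() else as.character(.x$genes))
  )
  bad_w <- setdiff(weights$weight, c("major", "minor"))
  if (length(bad_w) > 0L) {
    stop_validation("weight must be major or minor, got: ", paste(bad_w, collapse = ", "))
  }
  if (length(setdiff(weights$syndrome_id, syndromes$syndrome_id)) > 0L) {
    stop_validation("weight references unknown syndrome")
  }
  if (length(setdiff(weights$feature_id, features$feature_id)) > 0L) {
    stop_validation("weight references unknown feature")
  }
  if (length(setdiff(unlist(weights$genes), genes$symbol)) > 0L) {
    stop_validation("weight gene restriction references unknown gene")
  }
  if (anyDuplicated(weights[, c("syndrome_id", "feature_id")]) > 0L) {
    stop_validation("more than one weight for a (syndrome, feature) pair")
  }

  structure(
    list(
      schema_version = raw$schema_version,
      systems = systems,
      syndromes = syndromes,
      genes = genes,
      features = features,
      weights = weights
    ),
    class = "knowledge_base"
  )
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(
    "<knowledge_base> schema v", x$schema_version, ": ",
    nrow(x$genes), " genes, ", nrow(x$syndromes), " syndromes, ",
    nrow(x$features), " features across ", length(x$systems), " body systems\n",
    sep = ""
  )
  invisible(x)
}

#' Serialise a knowledge base back to YAML
#'
#' Inverse of [load_knowledge_base()]; the written file loads back to an
#' identical object (round-trip tested).
#'
#' @param kb A `knowledge_base` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "knowledge_base"))
  doc <- list(
    schema_version = kb$schema_version,
    systems = as.list(kb$systems),
    syndromes = purrr::pmap(kb$syndromes, function(syndrome_id, label) {
      list(id = syndrome_id, label = label)
    }),
    genes = purrr::pmap(kb$genes, function(symbol, inheritance, canonical_transcript, syndromes) {
      list(
        symbol = symbol, inheritance = inheritance,
        canonical_transcript = canonical_transcript,
        syndromes = as.list(syndromes)
      )
    }),
    features = purrr::pmap(kb$features, function(feature_id, label, system, hpo_terms) {
      list(id = feature_id, label = label, system = system, hpo = as.list(hpo_terms))
    }),
    weights = purrr::pmap(kb$weights, function(syndrome_id, feature_id, weight, genes) {
      out <- list(syndrome = syndrome_id, feature = feature_id, weight = weight)
      if (length(genes) > 0L) out$genes <- as.list(genes)
      out
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Pooled feature weights for one gene
#'
#' Pools key clinical features over every syndrome a gene is associated
#' with. When a feature is major in any of the gene's syndromes and minor
#' in another, the pooled weight is major: feature counts are recorded per
#' participant per gene, not per syndrome, so the strongest association
#' wins. Weights carrying a gene restriction (syndrome-variant footnotes)
#' only apply to the listed genes.
#'
#' @param kb A [knowledge_base][load_knowledge_base] object.
#' @param gene Gene symbol present in `kb`.
#' @return Tibble with one row per associated feature: `feature_id`,
#'   `weight` (`"major"`/`"minor"`), `label`, `system`.
#' @export
features_for_gene <- function(kb, gene) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (!gene %in% kb$genes$symbol) stop_validation("unknown gene: ", gene)
  gene_syndromes <- kb$genes$syndromes[[match(gene, kb$genes$symbol)]]
  w <- kb$weights %>%
    filter(.data$syndrome_id %in% gene_syndromes) %>%
    filter(purrr::map_lgl(.data$genes, ~ length(.x) == 0L || gene %in% .x)) %>%
    group_by(.data$feature_id) %>%
    summarise(weight = if (any(.data$weight == "major")) "major" else "minor", .groups = "drop")
  w %>%
    left_join(select(kb$features, "feature_id", "label", "system"), by = "feature_id") %>%
    arrange(.data$feature_id)
}

#' Feature HPO closures for a knowledge base
#'
#' Precomputes [expand_hpo()] for every feature in the knowledge base, for
#' repeated use by [phenotype_match()].
#'
#' @inheritParams features_for_gene
#' @param ontology An [hpo_ontology][read_obo] object.
#' @return Named list of character vectors (names are `feature_id`s).
#' @export
feature_closures <- function(kb, ontology) {
  stopifnot(inherits(kb, "knowledge_base"))
  setNames(
    purrr::map(kb$features$hpo_terms, expand_hpo, ontology = ontology),
    kb$features$feature_id
  )
}

#' @exportS3Method generics::tidy
tidy.knowledge_base <- function(x, ...) {
  x$weights %>%
    left_join(select(x$features, "feature_id", "label", "system"), by = "feature_id") %>%
    mutate(gene_restriction = purrr::map_chr(
      .data$genes, ~ if (length(.x)) paste(.x, collapse = ",") else NA_character_
    )) %>%
    select("syndrome_id", "feature_id", "label", "system", "weight", "gene_restriction")
}

#' @exportS3Method generics::glance
glance.knowledge_base <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_syndromes = nrow(x$syndromes),
    n_features = nrow(x$features),
    n_systems = length(x$systems),
    n_weights = nrow(x$weights),
    schema_version = x$schema_version
  )
}
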
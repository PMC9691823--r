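#' Read a phenotype ontology from an OBO file
#'
#' Parses the `[Term]` stanzas of an OBO-format ontology (id, name, `is_a`
#' parents, obsolete flag) into a directed acyclic graph of subsumption
#' relations. Only the fields needed for descendant-closure phenotype
#' matching are kept; obsolete terms are dropped.
#'
#' The package ships a miniature synthetic ontology extract
#' (`system.file("extdata", "hpo_mini.obo", package = "revphen")`) that is
#' sufficient for the packaged knowledge base; pointing `path` at a full
#' HPO `.obo` release works the same way.
#'
#' @param path Path to an `.obo` file.
#' @return An object of class `hpo_ontology`: a list with `terms` (tibble of
#'   `id`, `name`), `edges` (tibble of `child`, `parent`) and an igraph
#'   `graph` with edges directed parent -> child.
#' @export
#' @examples
#' obo <- read_obo(system.file("extdata", "hpo_mini.obo", package = "revphen"))
#' obo
read_obo <- function(path) {
  check_file_exists(path)
  lines <- readr::read_lines(path)
  # stanza boundaries
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop_validation("no [Term] stanzas in OBO file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  terms <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ": "), block, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      sub(paste0("^", key, ": "), "", hit[1])
    }
    if (any(grepl("^is_obsolete: true", block))) next
    id <- get1("id")
    if (is.na(id)) next
    parents <- sub("^is_a: ", "", grep("^is_a: ", block, value = TRUE))
    parents <- stringr::str_trim(sub("!.*$", "", parents)) # strip trailing comment
    terms[[i]] <- list(id = id, name = get1("name"), parents = parents)
  }
  terms <- purrr::compact(terms)
  term_tbl <- tibble(
    id = purrr::map_chr(terms, "id"),
    name = purrr::map_chr(terms, "name")
  )
  if (anyDuplicated(term_tbl$id)) {
    stop_validation("duplicate term ids in OBO file: ", path)
  }
  edges <- purrr::map_dfr(terms, function(t) {
    if (length(t$parents) == 0L) return(tibble(child = character(), parent = character()))
    tibble(child = t$id, parent = t$parents)
  })
  missing_parents <- setdiff(edges$parent, term_tbl$id)
  if (length(missing_parents) > 0L) {
    stop_validation(
      "is_a parents absent from ontology: ",
      paste(missing_parents, collapse = ", ")
    )
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$parent, to = edges$child),
    directed = TRUE,
    vertices = data.frame(name = term_tbl$id)
  )
  if (!igraph::is_dag(g)) stop_validation("ontology subsumption graph is cyclic")
  structure(
    list(terms = term_tbl, edges = edges, graph = g),
    class = "hpo_ontology"
  )
}

#' @export
print.hpo_ontology <- function(x, ...) {
  cat(
    "<hpo_ontology> ", nrow(x$terms), " terms, ",
    nrow(x$edges), " is-a edges\n",
    sep = ""
  )
  invisible(x)
}

#' Descendant closure of ontology terms
#'
#' Returns each query term together with all of its is-a descendants,
#' deduplicated. This is the subsumption rule used for phenotype matching:
#' a clinician-entered term matches a key clinical feature when it falls
#' anywhere below (or at) one of the feature's linked terms.
#'
#' @param ontology An [hpo_ontology][read_obo] object.
#' @param terms Character vector of term IDs (`HP:NNNNNNN`).
#' @return Character vector of term IDs (query terms plus descendants).
#' @export
hpo_descendants <- function(ontology, terms) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  terms <- unique(terms)
  absent <- setdiff(terms, ontology$terms$id)
  if (length(absent) > 0L) {
    stop_validation("terms absent from ontology: ", paste(absent, collapse = ", "))
  }
  if (length(terms) == 0L) return(character())
  out <- lapply(terms, function(t) {
    names(igraph::subcomponent(ontology$graph, t, mode = "out"))
  })
  unique(unlist(out))
}

#' Expand a clinical feature to its full set of acceptable HPO terms
#'
#' Takes the HPO terms linked to a knowledge-base clinical feature and
#' returns their descendant closure, so that more specific terms entered by
#' recruiting clinicians are captured by the feature.
#'
#' @param feature Either a character vector of HPO IDs or a list/row with an
#'   `hpo_terms` element (as stored in a [knowledge_base][load_knowledge_base]
#'   `features` table).
#' @param ontology An [hpo_ontology][read_obo] object.
#' @return Character vector of HPO IDs: the linked terms plus all their
#'   is-a descendants, deduplicated.
#' @export
expand_hpo <- function(feature, ontology) {
  terms <- if (is.character(feature)) {
    feature
  } else if (!is.null(feature$hpo_terms)) {
    unlist(feature$hpo_terms)
  } else {
    stop_validation("feature must be a character vector or carry an hpo_terms field")
  }
  if (length(terms) == 0L) stop_validation("feature has no linked HPO terms")
  hpo_descendants(ontology, terms)
}
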
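# Packaged fixtures: the knowledge-base panel and the published-style
# diagnosis tables (reportable and unreportable), with checksum-guarded
# loading and a replay driver for the reportability/confidence rules.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "revphen")
  if (identical(p, "")) stop_io("packaged fixture not found: ", file)
  p
}

check_manifest <- function(file) {
  manifest <- readr::read_lines(fixture_path("MANIFEST.md5"))
  manifest <- stringr::str_split_fixed(manifest, "  ", 2)
  expected <- manifest[manifest[, 2] == file, 1]
  if (length(expected) != 1L) stop_validation("fixture missing from manifest: ", file)
  actual <- unname(tools::md5sum(fixture_path(file)))
  if (!identical(actual, expected)) {
    stop_validation("fixture checksum mismatch for ", file)
  }
  invisible(TRUE)
}

#' Load a packaged fixture
#'
#' * `"table1"`: the ciliopathy gene-syndrome knowledge base (returns a
#'   [knowledge_base][load_knowledge_base]);
#' * `"table2"`: reportable new diagnoses (18 participants, 30 variant
#'   rows) with printed diagnostic-confidence labels, curator ACMG classes
#'   and key-feature counts; five participants whose variants were already
#'   listed elsewhere carry `excluded_listed = TRUE`;
#' * `"table3"`: novel unreportable diagnoses (11 participants, all with
#'   zero major key features).
#'
#' TSV fixtures are verified against a packaged MD5 manifest before
#' parsing; a checksum mismatch is an error.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return A `knowledge_base` for `"table1"`, otherwise a validated tibble
#'   of class `rp_fixture`.
#' @export
#' @examples
#' t2 <- load_fixture("table2")
#' nrow(t2) # 30 variant rows
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("table1", "table2", "table3")) {
    stop_validation("unknown fixture: ", as.character(name)[1])
  }
  if (name == "table1") {
    return(load_knowledge_base(fixture_path("ciliopathy_kb.yaml")))
  }
  file <- paste0(name, ".tsv")
  check_manifest(file)
  tbl <- readr::read_tsv(fixture_path(file), comment = "#", show_col_types = FALSE)
  if (name == "table2") {
    if (nrow(tbl) != 30L) stop_validation("table2 fixture must have 30 variant rows")
    if (n_distinct(tbl$research_id) != 18L) {
      stop_validation("table2 fixture must have 18 participants")
    }
    n_excl <- n_distinct(tbl$research_id[tbl$excluded_listed])
    if (n_excl != 5L) stop_validation("table2 fixture must flag 5 already-listed participants")
  } else {
    if (n_distinct(tbl$research_id) != 11L) {
      stop_validation("table3 fixture must have 11 participants")
    }
    if (any(tbl$major_count != 0L)) {
      stop_validation("table3 fixture participants must have zero major features")
    }
  }
  class(tbl) <- c("rp_fixture", class(tbl))
  tbl
}

#' Replay a fixture table through the reportability and confidence rules
#'
#' Applies [decide_reportable()] to each participant's key-feature counts
#' and, where ACMG classes are present, [classify_confidence()] to the
#' participant's alleles (gene inheritance taken from the knowledge base).
#' The rule-derived confidence is computed fresh; the printed label, when
#' the fixture carries one, is kept alongside for comparison.
#'
#' @param table A fixture tibble from [load_fixture()] (`"table2"` or
#'   `"table3"`).
#' @param kb A [knowledge_base][load_knowledge_base] (defaults to the
#'   packaged panel).
#' @return Tibble of class `rp_replay`, one row per participant:
#'   `research_id`, `gene`, `major_count`, `minor_count`, `reportable`,
#'   `confidence` (rule-derived; `"unreportable"` when no major feature),
#'   `printed_confidence` (`NA` if the fixture has none), `excluded_listed`.
#' @export
#' @examples
#' replay <- replay_fixture(load_fixture("table2"))
#' glance(replay)
replay_fixture <- function(table, kb = load_fixture("table1")) {
  stopifnot(inherits(kb, "knowledge_base"))
  table <- as_tibble(table)
  inh <- setNames(kb$genes$inheritance, kb$genes$symbol)
  has_acmg <- "acmg_class" %in% names(table)
  per <- table %>%
    group_by(.data$research_id) %>%
    dplyr::group_map(function(rows, key) {
      gene <- rows$gene[1]
      major <- rows$major_count[1]
      minor <- rows$minor_count[1]
      reportable <- decide_reportable(major)
      confidence <- if (!reportable) {
        "unreportable"
      } else if (has_acmg) {
        classify_confidence(
          tolower(rows$acmg_class),
          tolower(rows$zygosity),
          inh[[gene]]
        )
      } else {
        NA_character_
      }
      tibble(
        research_id = key$research_id,
        gene = gene,
        major_count = major,
        minor_count = minor,
        reportable = reportable,
        confidence = confidence,
        printed_confidence = if ("printed_confidence" %in% names(rows)) {
          rows$printed_confidence[1]
        } else {
          NA_character_
        },
        excluded_listed = if ("excluded_listed" %in% names(rows)) {
          isTRUE(rows$excluded_listed[1])
        } else {
          FALSE
        }
      )
    }) %>%
    bind_rows() %>%
    arrange(.data$research_id)
  class(per) <- c("rp_replay", class(per))
  per
}

#' @exportS3Method generics::glance
glance.rp_replay <- function(x, ...) {
  tibble(
    n_participants = nrow(x),
    n_reportable = sum(x$reportable),
    n_confident = sum(x$confidence == "confident", na.rm = TRUE),
    n_probable = sum(x$confidence == "probable", na.rm = TRUE),
    n_possible = sum(x$confidence == "possible", na.rm = TRUE),
    n_unreportable = sum(x$confidence == "unreportable", na.rm = TRUE),
    n_new = sum(x$reportable & !x$excluded_listed)
  )
}
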
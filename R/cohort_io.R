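# Readers and writers for cohort-side inputs: pedigree, participant
# metadata, HPO profiles, curator ACMG classes.

#' Read a PED pedigree file
#'
#' Standard 6-column PED: family, individual, father, mother, sex (1 male,
#' 2 female, 0 unknown), affection (2 affected, 1 unaffected, 0/-9
#' missing). `0` parent IDs become `NA`. Lines starting with `#` are
#' ignored.
#'
#' @param path PED path.
#' @return Tibble `family_id`, `participant_id`, `father_id`, `mother_id`,
#'   `sex` (`male`/`female`/`unknown`), `affected` (logical, `NA` if
#'   missing).
#' @export
read_ped <- function(path) {
  check_file_exists(path)
  ped <- readr::read_tsv(
    path,
    comment = "#",
    col_names = c("family_id", "participant_id", "father_id", "mother_id", "sex", "affection"),
    col_types = "ccccii"
  )
  ped %>%
    mutate(
      father_id = dplyr::na_if(.data$father_id, "0"),
      mother_id = dplyr::na_if(.data$mother_id, "0"),
      sex = dplyr::case_match(.data$sex, 1L ~ "male", 2L ~ "female", .default = "unknown"),
      affected = dplyr::case_match(.data$affection, 2L ~ TRUE, 1L ~ FALSE, .default = NA)
    ) %>%
    select(-"affection")
}

#' Write a PED pedigree file
#'
#' Inverse of [read_ped()]; columns are re-encoded to the numeric PED
#' conventions. A `# seed:` style header comment can be supplied.
#'
#' @param ped Tibble as returned by [read_ped()].
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, header = NULL) {
  out <- ped %>%
    mutate(
      father_id = dplyr::coalesce(.data$father_id, "0"),
      mother_id = dplyr::coalesce(.data$mother_id, "0"),
      sex = dplyr::case_match(.data$sex, "male" ~ 1L, "female" ~ 2L, .default = 0L),
      affection = dplyr::case_when(
        is.na(.data$affected) ~ 0L, .data$affected ~ 2L, .default = 1L
      )
    ) %>%
    select("family_id", "participant_id", "father_id", "mother_id", "sex", "affection")
  lines <- c(header, apply(out, 1L, paste, collapse = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

SOLVED_STATUSES <- c(
  "unsolved", "solved_other_gene", "partially_solved_other_gene", "solved_target_gene"
)

#' Read participant metadata
#'
#' TSV with columns `participant_id`, `proband` (logical), `solved_status`
#' (`unsolved`, `solved_other_gene`, `partially_solved_other_gene`,
#' `solved_target_gene`), `recruitment_category`.
#'
#' @param path TSV path.
#' @return Validated tibble.
#' @export
read_participant_meta <- function(path) {
  check_file_exists(path)
  meta <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("participant_id", "proband", "solved_status", "recruitment_category")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) stop_validation("missing metadata columns: ", paste(miss, collapse = ", "))
  if (any(!meta$solved_status %in% SOLVED_STATUSES)) {
    stop_validation("invalid solved_status value")
  }
  meta
}

#' Read sparse HPO phenotype profiles
#'
#' Long TSV with columns `participant_id`, `hpo_id` (one term per row;
#' participants may be entirely absent, reflecting empty profiles).
#'
#' @param path TSV path.
#' @return Tibble `participant_id`, `hpo_id`.
#' @export
read_hpo_profiles <- function(path) {
  check_file_exists(path)
  prof <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("participant_id", "hpo_id") %in% names(prof))) {
    stop_validation("HPO profile TSV needs participant_id and hpo_id columns")
  }
  distinct(prof[, c("participant_id", "hpo_id")])
}

ACMG_CLASSES <- c("pathogenic", "likely_pathogenic", "vus", "likely_benign", "benign")

#' Read curator-supplied ACMG variant classes
#'
#' ACMG pathogenicity classes are curator inputs (assigned by manual
#' review), keyed by participant and variant. TSV columns:
#' `participant_id`, `variant_id`, `acmg_class`.
#'
#' @param path TSV path.
#' @return Validated tibble.
#' @export
read_acmg_classes <- function(path) {
  check_file_exists(path)
  acmg <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("participant_id", "variant_id", "acmg_class")
  miss <- setdiff(need, names(acmg))
  if (length(miss) > 0L) stop_validation("missing ACMG columns: ", paste(miss, collapse = ", "))
  if (any(!acmg$acmg_class %in% ACMG_CLASSES)) stop_validation("invalid acmg_class value")
  acmg
}

#' Sample IDs present in a VCF
#'
#' Reads the sample columns of the `#CHROM` header line; used to
#' distinguish genotyped non-carriers from ungenotyped individuals during
#' segregation.
#'
#' @param path VCF path.
#' @return Character vector of sample IDs.
#' @export
read_vcf_samples <- function(path) {
  check_file_exists(path)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop_validation("no #CHROM header line in VCF: ", path)
    if (startsWith(line, "#CHROM")) {
      fields <- stringr::str_split_1(line, stringr::fixed("\t"))
      return(if (length(fields) > 9L) fields[-(1:9)] else character())
    }
  }
}

#' Assemble a full cohort from a directory of standard files
#'
#' Reads the conventional file layout written by [generate_cohort()]:
#' `small_variants.vcf`, `svs.tsv`, `pedigree.ped`, `participants.tsv`,
#' `hpo.tsv`, `acmg.tsv`, `exons.bed`.
#'
#' @param dir Directory containing the cohort files.
#' @param gene_set Character vector of target gene symbols (used when
#'   reading the annotated VCF).
#' @return A list of class `rp_cohort` with elements `variants`,
#'   `genotypes`, `sv_calls`, `ped`, `meta`, `hpo`, `acmg`, `exons`.
#' @export
read_cohort <- function(dir, gene_set) {
  p <- function(f) file.path(dir, f)
  structure(
    list(
      variants = read_annotated_vcf(p("small_variants.vcf"), gene_set),
      genotypes = read_vcf_genotypes(p("small_variants.vcf")),
      samples = read_vcf_samples(p("small_variants.vcf")),
      sv_calls = read_sv_table(p("svs.tsv")),
      ped = read_ped(p("pedigree.ped")),
      meta = read_participant_meta(p("participants.tsv")),
      hpo = read_hpo_profiles(p("hpo.tsv")),
      acmg = read_acmg_classes(p("acmg.tsv")),
      exons = read_exon_bed(p("exons.bed"))
    ),
    class = "rp_cohort"
  )
}

#' @export
print.rp_cohort <- function(x, ...) {
  cat(
    "<rp_cohort> ", nrow(x$ped), " participants, ",
    nrow(x$variants), " annotated variants, ",
    nrow(x$sv_calls), " SV calls\n",
    sep = ""
  )
  invisible(x)
}
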
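# Small-variant (SNV/indel) rarity filtering and prioritisation.

# VEP "high impact" consequence terms used for the high-impact sublist
HIGH_IMPACT_TERMS <- c(
  "stop_gained", "stop_lost", "start_lost",
  "splice_acceptor_variant", "splice_donor_variant",
  "frameshift_variant", "transcript_ablation", "transcript_amplification"
)

CLINSIG_LEVELS <- c(
  "pathogenic", "likely_pathogenic", "vus",
  "likely_benign", "benign", "conflicting", "absent"
)

#' Construct and validate an annotated-variant table
#'
#' Builds the canonical annotated-variant tibble consumed by every filter
#' in the pipeline, filling optional columns and validating ranges. One row
#' is one alt allele at one site on one (canonical) transcript.
#'
#' @param df Data frame with at least `chrom`, `pos`, `ref`, `alt`, `gene`.
#'   Recognised further columns: `transcript`, `canonical` (logical),
#'   `consequence` (`&`-separated sequence-ontology terms), `cohort_af`,
#'   `popdb_af` (proportions; `NA` means absent/novel), `clinsig`
#'   (`pathogenic`, `likely_pathogenic`, `vus`, `likely_benign`, `benign`,
#'   `conflicting`, `absent`), `missense_class` (`deleterious`, `tolerated`,
#'   `absent`), splice delta scores `ds_ag`, `ds_al`, `ds_dg`, `ds_dl` (in
#'   \[0, 1\], `NA` = absent), `hgvs_c`, `hgvs_p`.
#' @return A tibble with all columns present, a `variant_id`
#'   (`chrom:pos:ref:alt`) first, and validated values.
#' @export
annotated_variants <- function(df) {
  df <- as_tibble(df)
  need <- c("chrom", "pos", "ref", "alt", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_validation("missing variant columns: ", paste(miss, collapse = ", "))
  }
  defaults <- list(
    transcript = NA_character_, canonical = TRUE, consequence = "",
    cohort_af = NA_real_, popdb_af = NA_real_,
    clinsig = "absent", missense_class = "absent",
    ds_ag = NA_real_, ds_al = NA_real_, ds_dg = NA_real_, ds_dl = NA_real_,
    hgvs_c = NA_character_, hgvs_p = NA_character_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  if (any(!is.finite(df$pos) | df$pos < 1)) stop_validation("pos must be >= 1")
  if (any(grepl(",", df$alt, fixed = TRUE))) {
    stop_validation("alt must be a single allele; split multi-allelic records first")
  }
  if (!all(df$clinsig %in% CLINSIG_LEVELS)) {
    stop_validation("invalid clinsig value")
  }
  if (!all(df$missense_class %in% c("deleterious", "tolerated", "absent"))) {
    stop_validation("invalid missense_class value")
  }
  for (ds in c("ds_ag", "ds_al", "ds_dg", "ds_dl")) {
    x <- df[[ds]]
    if (any(!is.na(x) & (x < 0 | x > 1))) stop_validation(ds, " must be in [0, 1]")
  }
  df$variant_id <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  select(df, "variant_id", dplyr::everything())
}

#' Exclude common variants
#'
#' Rarity and transcript filter: a variant is retained iff its within-cohort
#' allele frequency and its population-database allele frequency are both
#' strictly below their thresholds (absent frequencies count as 0, i.e. a
#' novel variant is rare) and the call is on the canonical transcript. Row
#' order is preserved; the operation is idempotent.
#'
#' @param variants Annotated-variant tibble (see [annotated_variants()]).
#' @param thresholds A [threshold_config()].
#' @return The retained rows of `variants`.
#' @export
exclude_common <- function(variants, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  variants <- as_tibble(variants)
  cohort <- dplyr::coalesce(variants$cohort_af, 0)
  popdb <- dplyr::coalesce(variants$popdb_af, 0)
  keep <- cohort < thresholds$cohort_af_max &
    popdb < thresholds$popdb_af_max &
    variants$canonical
  out <- variants[keep, , drop = FALSE]
  log_stage("exclude_common", n_in = nrow(variants), n_out = nrow(out))
  out
}

#' Assign priority classes to variants
#'
#' Adds the three prioritisation sublists as logical columns:
#'
#' * `clinvar_pathogenic`: clinical-significance assertion is pathogenic or
#'   likely pathogenic (conflicting assertions do not qualify);
#' * `high_impact`: any consequence term is among the eight high-impact
#'   terms (stop gained/lost, start lost, splice acceptor/donor, frameshift,
#'   transcript ablation/amplification);
#' * `deleterious_missense`: a missense consequence predicted deleterious.
#'
#' Classes are independent and may co-occur; they do not depend on allele
#' frequency, so classification and rarity filtering commute.
#'
#' @param variants Annotated-variant tibble.
#' @return `variants` with columns `clinvar_pathogenic`, `high_impact`,
#'   `deleterious_missense` and `priority_any` appended.
#' @export
classify_priority <- function(variants) {
  variants <- as_tibble(variants)
  cons <- stringr::str_split(dplyr::coalesce(variants$consequence, ""), stringr::fixed("&"))
  variants$clinvar_pathogenic <-
    variants$clinsig %in% c("pathogenic", "likely_pathogenic")
  variants$high_impact <-
    purrr::map_lgl(cons, ~ any(.x %in% HIGH_IMPACT_TERMS))
  variants$deleterious_missense <-
    purrr::map_lgl(cons, ~ "missense_variant" %in% .x) &
      variants$missense_class == "deleterious"
  variants$priority_any <- variants$clinvar_pathogenic |
    variants$high_impact | variants$deleterious_missense
  variants
}

#' The high-impact consequence term set
#'
#' @return Character vector of the eight sequence-ontology terms treated as
#'   high impact by [classify_priority()].
#' @export
high_impact_consequences <- function() HIGH_IMPACT_TERMS

# parse the pipe-delimited RPANN entry grammar (see read_annotated_vcf)
parse_ann_entry <- function(entry) {
  f <- stringr::str_split_1(entry, stringr::fixed("|"))
  if (length(f) != 15L) {
    stop_validation("malformed RPANN entry (expected 15 subfields): ", entry)
  }
  numna <- function(x) if (x == "" || x == ".") NA_real_ else as.numeric(x)
  strna <- function(x) if (x == "" || x == ".") NA_character_ else x
  list(
    allele = f[1], gene = f[2], transcript = strna(f[3]),
    canonical = identical(f[4], "YES"),
    consequence = f[5],
    cohort_af = numna(f[6]), popdb_af = numna(f[7]),
    clinsig = if (f[8] == "" || f[8] == ".") "absent" else f[8],
    missense_class = if (f[9] == "" || f[9] == ".") "absent" else f[9],
    ds_ag = numna(f[10]), ds_al = numna(f[11]),
    ds_dg = numna(f[12]), ds_dl = numna(f[13]),
    hgvs_c = strna(f[14]), hgvs_p = strna(f[15])
  )
}

#' Read an annotated VCF into an annotated-variant table
#'
#' Reads a VCF 4.2 file whose `RPANN` INFO field carries per-transcript
#' annotation entries, comma-separated, each pipe-delimited with subfields
#'
#' `Allele|Gene|Transcript|Canonical|Consequence|Cohort_AF|PopDB_AF|ClinSig|Missense|DS_AG|DS_AL|DS_DG|DS_DL|HGVSc|HGVSp`
#'
#' (`Canonical` is `YES` or empty; `Consequence` is `&`-separated;
#' empty/`.` numeric subfields mean absent). One output row is produced per
#' (site, alt allele, canonical transcript of a gene in `gene_set`);
#' multi-allelic records are split by matching each annotation entry's
#' `Allele` subfield. Positions are taken as given (1-based, no
#' re-normalisation).
#'
#' @param path Path to the VCF file.
#' @param gene_set Character vector of target gene symbols.
#' @return Annotated-variant tibble (see [annotated_variants()]).
#' @export
read_annotated_vcf <- function(path, gene_set) {
  check_file_exists(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(annotated_variants(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), gene = character()
    )))
  }
  info_ann <- vcfR::extract.info(vcf, element = "RPANN")
  if (all(is.na(info_ann))) {
    stop_validation("VCF has no RPANN annotation INFO field: ", path)
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    if (is.na(info_ann[i])) next
    alts <- stringr::str_split_1(fix[i, "ALT"], stringr::fixed(","))
    entries <- stringr::str_split_1(info_ann[i], stringr::fixed(","))
    for (entry in entries) {
      ann <- parse_ann_entry(entry)
      if (!ann$gene %in% gene_set) next
      if (!ann$canonical) next
      if (!ann$allele %in% alts) next
      rows[[length(rows) + 1L]] <- tibble(
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = ann$allele,
        gene = ann$gene,
        transcript = ann$transcript,
        canonical = TRUE,
        consequence = ann$consequence,
        cohort_af = ann$cohort_af,
        popdb_af = ann$popdb_af,
        clinsig = ann$clinsig,
        missense_class = ann$missense_class,
        ds_ag = ann$ds_ag, ds_al = ann$ds_al,
        ds_dg = ann$ds_dg, ds_dl = ann$ds_dl,
        hgvs_c = ann$hgvs_c, hgvs_p = ann$hgvs_p
      )
    }
  }
  out <- if (length(rows)) annotated_variants(bind_rows(rows)) else {
    annotated_variants(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), gene = character()
    ))
  }
  log_stage("read_annotated_vcf", n_records = nrow(fix), n_variants = nrow(out))
  out
}

#' Read per-sample genotypes from a VCF
#'
#' Extracts sample genotypes in long form, with one row per (variant,
#' sample) where the sample carries the alt allele. Multi-allelic records
#' are resolved per alt allele by counting that allele index in the GT
#' field; `"1"`-style single-entry genotypes (as on male X chromosomes)
#' yield zygosity `hom` and are reinterpreted as hemizygous downstream
#' where sex and gene inheritance are known.
#'
#' @param path Path to the VCF file.
#' @return Tibble with `variant_id`, `participant_id`, `zygosity`
#'   (`"het"`/`"hom"`).
#' @export
read_vcf_genotypes <- function(path) {
  check_file_exists(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) {
    return(tibble(variant_id = character(), participant_id = character(), zygosity = character()))
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- stringr::str_split_1(fix[i, "ALT"], stringr::fixed(","))
    for (s in colnames(gt)) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      alleles <- stringr::str_split_1(g, "[/|]")
      for (ai in seq_along(alts)) {
        dose <- sum(alleles == as.character(ai))
        if (dose == 0L) next
        zyg <- if (dose >= 2L || length(alleles) == 1L) "hom" else "het"
        rows[[length(rows) + 1L]] <- tibble(
          variant_id = variant_key(fix[i, "CHROM"], as.integer(fix[i, "POS"]), fix[i, "REF"], alts[ai]),
          participant_id = s,
          zygosity = zyg
        )
      }
    }
  }
  if (length(rows)) bind_rows(rows) else {
    tibble(variant_id = character(), participant_id = character(), zygosity = character())
  }
}

#' Write prioritised variant sublists to TSV
#'
#' @param variants Output of [classify_priority()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sublists <- function(variants, path) {
  readr::write_tsv(as_tibble(variants), path)
  invisible(path)
}
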
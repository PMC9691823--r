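# Diagnosis engine: candidate assembly, segregation, reverse phenotyping,
# reportability and diagnostic confidence.

#' Select participants eligible for reverse phenotyping
#'
#' Participants are excluded if recruited as unaffected relatives, or if
#' already solved or partially solved with variants in alternative genes.
#' Affected probands and affected relatives who are unsolved (or solved
#' with a target gene) remain.
#'
#' @param participants Tibble with at least `participant_id`, `affected`
#'   (logical) and `solved_status` (see [read_participant_meta()]).
#' @return The eligible rows of `participants`.
#' @export
eligible_participants <- function(participants) {
  participants <- as_tibble(participants)
  out <- filter(
    participants,
    !is.na(.data$affected), .data$affected,
    !.data$solved_status %in% c("solved_other_gene", "partially_solved_other_gene")
  )
  log_stage("eligible_participants", n_in = nrow(participants), n_out = nrow(out))
  out
}

acmg_severity <- function(class) {
  dplyr::case_match(class,
    "pathogenic" ~ 2, "likely_pathogenic" ~ 2, "vus" ~ 1,
    .default = 0
  )
}

#' Assemble inheritance-consistent candidate diagnoses
#'
#' For autosomal recessive genes a candidate is either one homozygous
#' prioritised allele, or a pair of heterozygous prioritised alleles (all
#' pairs are emitted, initially unphased; structural-variant and splice
#' candidates count as alleles alongside sublist SNVs). For X-linked genes
#' a single heterozygous allele in a female, or hemizygous (or homozygous)
#' allele in a male or female respectively, forms a candidate.
#'
#' @param alleles Tibble of prioritised alleles: `participant_id`, `gene`,
#'   `allele_id`, `zygosity` (`het`/`hom`/`hemi`), `source`
#'   (`snv_sublist`/`sv`/`splice`), and optionally `acmg_class`, `hgvs_c`.
#' @param kb A [knowledge_base][load_knowledge_base] (for gene inheritance).
#' @return Candidate tibble: `candidate_id`, `participant_id`, `gene`,
#'   `inheritance`, `n_alleles`, and list-columns `allele_ids`,
#'   `zygosities`, `sources`, plus `phase` initialised to `"unphased"`.
#' @export
assemble_candidates <- function(alleles, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  alleles <- as_tibble(alleles)
  if (nrow(alleles) == 0L) {
    return(tibble(
      candidate_id = character(), participant_id = character(), gene = character(),
      inheritance = character(), n_alleles = integer(),
      allele_ids = list(), zygosities = list(), sources = list(), phase = character()
    ))
  }
  inh <- setNames(kb$genes$inheritance, kb$genes$symbol)
  unknown <- setdiff(unique(alleles$gene), names(inh))
  if (length(unknown) > 0L) {
    stop_validation("alleles in genes absent from knowledge base: ", paste(unknown, collapse = ", "))
  }
  out <- list()
  grouped <- alleles %>%
    mutate(.gene_inh = inh[.data$gene]) %>%
    group_by(.data$participant_id, .data$gene)
  keys <- dplyr::group_keys(grouped)
  splits <- dplyr::group_split(grouped)
  for (gi in seq_along(splits)) {
    a <- splits[[gi]]
    mode <- a$.gene_inh[1]
    if (mode == "autosomal_recessive") {
      homs <- filter(a, .data$zygosity %in% c("hom", "hemi"))
      for (j in seq_len(nrow(homs))) {
        out[[length(out) + 1L]] <- tibble(
          participant_id = a$participant_id[1], gene = a$gene[1], inheritance = mode,
          n_alleles = 1L,
          allele_ids = list(homs$allele_id[j]),
          zygosities = list(homs$zygosity[j]),
          sources = list(homs$source[j])
        )
      }
      hets <- filter(a, .data$zygosity == "het")
      if (nrow(hets) >= 2L) {
        pairs <- utils::combn(nrow(hets), 2L)
        for (k in seq_len(ncol(pairs))) {
          i1 <- pairs[1, k]; i2 <- pairs[2, k]
          out[[length(out) + 1L]] <- tibble(
            participant_id = a$participant_id[1], gene = a$gene[1], inheritance = mode,
            n_alleles = 2L,
            allele_ids = list(c(hets$allele_id[i1], hets$allele_id[i2])),
            zygosities = list(c("het", "het")),
            sources = list(c(hets$source[i1], hets$source[i2]))
          )
        }
      }
    } else { # x_linked: single-allele candidates
      for (j in seq_len(nrow(a))) {
        out[[length(out) + 1L]] <- tibble(
          participant_id = a$participant_id[1], gene = a$gene[1], inheritance = mode,
          n_alleles = 1L,
          allele_ids = list(a$allele_id[j]),
          zygosities = list(a$zygosity[j]),
          sources = list(a$source[j])
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(
      candidate_id = character(), participant_id = character(), gene = character(),
      inheritance = character(), n_alleles = integer(),
      allele_ids = list(), zygosities = list(), sources = list(), phase = character()
    ))
  }
  res <- bind_rows(out) %>%
    mutate(
      candidate_id = paste0("cand", row_number()),
      phase = "unphased"
    ) %>%
    select("candidate_id", dplyr::everything())
  log_stage("assemble_candidates", n_candidates = nrow(res))
  res
}

# origin of one allele for one proband given carrier sets
allele_origin <- function(in_mother, in_father, mother_genotyped, father_genotyped) {
  if (mother_genotyped && father_genotyped) {
    if (in_mother && !in_father) return("maternal")
    if (in_father && !in_mother) return("paternal")
    if (!in_mother && !in_father) return("de_novo")
    return("unknown") # carried by both: ambiguous for a het allele
  }
  if (mother_genotyped && in_mother) return("maternal")
  if (father_genotyped && in_father) return("paternal")
  "unknown"
}

#' Segregate candidate alleles against parental genotypes
#'
#' Sets each allele's parental origin from the genotyped parents (maternal
#' or paternal when observed in exactly that parent, de novo when both
#' parents are genotyped and neither carries it, unknown otherwise), and
#' phases compound-heterozygous candidates: one maternal plus one paternal
#' allele is in trans; two alleles traced to the same single parent with
#' both parents genotyped is in cis, and the candidate is excluded from
#' reporting. A homozygous allele observed in both parents is recorded as
#' bi-parental (in trans). Mendelian inconsistencies (homozygous child,
#' genotyped parent without the allele) yield a warning and origin unknown.
#'
#' @param candidates Candidate tibble from [assemble_candidates()].
#' @param carriers Tibble `participant_id`, `allele_id` listing every
#'   individual (probands and relatives) carrying each allele; for SV
#'   alleles, cluster co-members count as carriers of the allele.
#' @param ped Pedigree from [read_ped()].
#' @param genotyped_ids Character vector of individuals with genotype data
#'   (a parent absent from this set is treated as not genotyped, never as
#'   a non-carrier).
#' @return `candidates` with list-column `origins`, a `segregation` label,
#'   and `phase` set (`in_trans`, `unphased`, `in_cis_excluded`).
#' @export
segregate <- function(candidates, carriers, ped, genotyped_ids) {
  candidates <- as_tibble(candidates)
  carriers <- distinct(as_tibble(carriers)[, c("participant_id", "allele_id")])
  if (nrow(candidates) == 0L) {
    return(mutate(candidates, origins = list(), segregation = character()))
  }
  par_lookup <- ped %>% select("participant_id", "father_id", "mother_id")
  origins <- vector("list", nrow(candidates))
  phase <- character(nrow(candidates))
  segregation <- character(nrow(candidates))
  carrier_set <- paste(carriers$participant_id, carriers$allele_id, sep = "\r")
  carries <- function(id, allele) {
    !is.na(id) && paste(id, allele, sep = "\r") %in% carrier_set
  }
  for (i in seq_len(nrow(candidates))) {
    pid <- candidates$participant_id[i]
    prow <- par_lookup[par_lookup$participant_id == pid, ]
    mother <- if (nrow(prow)) prow$mother_id[1] else NA_character_
    father <- if (nrow(prow)) prow$father_id[1] else NA_character_
    m_gt <- !is.na(mother) && mother %in% genotyped_ids
    f_gt <- !is.na(father) && father %in% genotyped_ids
    ids <- candidates$allele_ids[[i]]
    zygs <- candidates$zygosities[[i]]
    ors <- character(length(ids))
    biparental <- FALSE
    for (j in seq_along(ids)) {
      in_m <- m_gt && carries(mother, ids[j])
      in_f <- f_gt && carries(father, ids[j])
      if (zygs[j] %in% c("hom", "hemi")) {
        if (m_gt && f_gt && in_m && in_f) {
          ors[j] <- "unknown"
          biparental <- TRUE
        } else if ((m_gt && !in_m && f_gt && in_f) || (f_gt && !in_f && m_gt && in_m)) {
          # homozygote with one genotyped parent lacking the allele
          rlang::warn(paste0(
            "Mendelian inconsistency for ", pid, " allele ", ids[j],
            ": homozygous child, parent without allele"
          ))
          ors[j] <- "unknown"
        } else if (m_gt && f_gt && !in_m && !in_f) {
          ors[j] <- "de_novo"
        } else {
          ors[j] <- allele_origin(in_m, in_f, m_gt, f_gt)
        }
      } else {
        ors[j] <- allele_origin(in_m, in_f, m_gt, f_gt)
      }
    }
    origins[[i]] <- ors
    if (length(ids) == 2L) {
      if (all(sort(ors) == c("maternal", "paternal")) ||
          (any(ors == "de_novo") && any(ors %in% c("maternal", "paternal")))) {
        phase[i] <- "in_trans"
      } else if (m_gt && f_gt &&
                 (all(ors == "maternal") || all(ors == "paternal"))) {
        phase[i] <- "in_cis_excluded"
      } else {
        phase[i] <- "unphased"
      }
      segregation[i] <- paste(ors, collapse = "/")
    } else {
      phase[i] <- if (biparental) "in_trans" else "unphased"
      segregation[i] <- if (biparental) "bi_parental" else ors[1]
    }
  }
  candidates$origins <- origins
  candidates$phase <- phase
  candidates$segregation <- segregation
  candidates
}

#' Match a participant's phenotype profile against a gene's key features
#'
#' Reverse phenotyping step: a knowledge-base feature of the gene is
#' matched when the participant's HPO term set intersects the feature's
#' descendant closure ([expand_hpo()]). Each matched feature counts once
#' regardless of how many participant terms hit it; counts are tallied by
#' the pooled per-gene weight ([features_for_gene()]), and the body systems
#' involved are derived from the matched features only. Participant terms
#' absent from the ontology are ignored with a logged count.
#'
#' @param hpo_terms Character vector of the participant's HPO term IDs
#'   (possibly empty: sparse phenotyping is expected).
#' @param gene Gene symbol present in the knowledge base.
#' @param kb A [knowledge_base][load_knowledge_base].
#' @param ontology An [hpo_ontology][read_obo].
#' @param closures Optional precomputed [feature_closures()] (avoids
#'   recomputation across participants).
#' @return One-row tibble: `major_count`, `minor_count`, `systems`
#'   (list-column), `matched_features` (list-column tibble of `feature_id`,
#'   `weight`).
#' @export
phenotype_match <- function(hpo_terms, gene, kb, ontology, closures = NULL) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (is.null(closures)) closures <- feature_closures(kb, ontology)
  known <- hpo_terms[hpo_terms %in% ontology$terms$id]
  n_unknown <- length(hpo_terms) - length(known)
  if (n_unknown > 0L) log_stage("phenotype_match", unknown_terms = n_unknown)
  gf <- features_for_gene(kb, gene)
  hit <- purrr::map_lgl(gf$feature_id, ~ any(known %in% closures[[.x]]))
  matched <- gf[hit, c("feature_id", "weight", "system")]
  tibble(
    major_count = sum(matched$weight == "major"),
    minor_count = sum(matched$weight == "minor"),
    systems = list(sort(unique(matched$system))),
    matched_features = list(matched)
  )
}

#' Reportability decision
#'
#' A candidate diagnosis is reportable iff at least one major key clinical
#' feature compatible with the implicated gene is present; minor features
#' alone never justify reporting.
#'
#' @param major_count Integer vector of matched major-feature counts.
#' @return Logical vector.
#' @export
decide_reportable <- function(major_count) {
  if (any(is.na(major_count) | major_count < 0)) {
    stop_validation("major_count must be non-negative")
  }
  major_count >= 1
}

#' Diagnostic confidence tier from ACMG classes
#'
#' Applies the confidence rule to the curator-supplied ACMG classes of a
#' candidate's alleles. For recessive genes (a homozygous allele counts as
#' two alleles of its class): two pathogenic/likely pathogenic alleles give
#' a confident diagnosis, one pathogenic/likely pathogenic plus one VUS a
#' probable diagnosis, two VUS a possible diagnosis. For X-linked genes a
#' single pathogenic/likely pathogenic allele is confident and a single
#' VUS possible; no probable tier exists. Any benign or likely benign
#' allele invalidates the candidate (error).
#'
#' @param acmg_classes Character vector of ACMG classes, one per allele
#'   record (`pathogenic`, `likely_pathogenic`, `vus`, `likely_benign`,
#'   `benign`).
#' @param zygosities Character vector parallel to `acmg_classes`
#'   (`het`/`hom`/`hemi`).
#' @param inheritance `"autosomal_recessive"` or `"x_linked"`.
#' @return `"confident"`, `"probable"` or `"possible"`.
#' @export
classify_confidence <- function(acmg_classes, zygosities, inheritance) {
  if (any(!acmg_classes %in% ACMG_CLASSES)) stop_validation("invalid ACMG class")
  if (any(acmg_classes %in% c("benign", "likely_benign"))) {
    stop_validation("candidate invalid: allele classed benign/likely benign")
  }
  plp <- c("pathogenic", "likely_pathogenic")
  if (inheritance == "x_linked") {
    if (length(acmg_classes) != 1L) {
      stop_validation("x-linked candidates carry a single allele")
    }
    return(if (acmg_classes %in% plp) "confident" else "possible")
  }
  # recessive: expand hom/hemi to two copies
  expanded <- rep(acmg_classes, ifelse(zygosities %in% c("hom", "hemi"), 2L, 1L))
  if (length(expanded) != 2L) {
    stop_validation("recessive candidates need two allele copies, got ", length(expanded))
  }
  n_plp <- sum(expanded %in% plp)
  if (n_plp == 2L) "confident" else if (n_plp == 1L) "probable" else "possible"
}

# rank candidates within (participant, gene): summed ACMG severity first
# (P/LP = 2, VUS = 1), then resolved phase over unphased
candidate_rank <- function(acmg_list, phase) {
  sev <- purrr::map_dbl(acmg_list, ~ sum(acmg_severity(.x)))
  sev + ifelse(phase == "in_trans", 0.5, 0)
}

#' Run the full reverse-phenotyping diagnostic pipeline
#'
#' Deterministic end-to-end composition of every stage: rarity filtering
#' and sublist prioritisation of small variants, splice screening,
#' SV database aggregation with rarity / coding-overlap / read-support
#' screening gated on first-hit carriers, eligibility filtering, candidate
#' assembly, trio segregation (in-cis pairs dropped), reverse phenotype
#' matching, reportability and diagnostic confidence classification.
#' One row is reported per (participant, gene): the top-ranked candidate
#' by summed ACMG severity, with resolved phase breaking ties. Candidates
#' carrying a benign/likely benign allele are dropped.
#'
#' @param cohort An [rp_cohort][read_cohort] list (or an equivalent list
#'   with elements `variants`, `genotypes`, `sv_calls`, `ped`, `meta`,
#'   `hpo`, `acmg`, `exons`, and optionally `samples`).
#' @param kb A [knowledge_base][load_knowledge_base].
#' @param ontology An [hpo_ontology][read_obo].
#' @param thresholds A [threshold_config()].
#' @return A tibble of class `rp_diagnoses`, one row per candidate
#'   diagnosis, with zygosity, consequence, HGVS, allele frequencies,
#'   segregation, ACMG classes, key-feature counts, systems, reportability
#'   and confidence (`"unreportable"` when no major feature matches).
#' @export
run_pipeline <- function(cohort, kb, ontology, thresholds = threshold_config()) {
  stopifnot(inherits(kb, "knowledge_base"))
  log_stage("run_pipeline",
    cohort_af_max = thresholds$cohort_af_max,
    popdb_af_max = thresholds$popdb_af_max,
    splice_delta_min = thresholds$splice_delta_min,
    sv_common_count = thresholds$sv_common_count,
    sv_read_fraction_min = thresholds$sv_read_fraction_min
  )
  genotyped_ids <- cohort$samples %||% unique(cohort$genotypes$participant_id)

  # participants
  participants <- cohort$ped %>%
    left_join(cohort$meta, by = "participant_id")
  eligible <- eligible_participants(participants)
  hpo_sets <- split(cohort$hpo$hpo_id, cohort$hpo$participant_id)

  # stage 1-2: rarity filter + priority sublists
  rare <- exclude_common(cohort$variants, thresholds)
  prio <- classify_priority(rare)
  # stage 4: splice screen
  spl <- splice_candidates(rare, thresholds)

  # per-participant SNV alleles
  gt <- cohort$genotypes
  x_genes <- kb$genes$symbol[kb$genes$inheritance == "x_linked"]
  snv_alleles <- gt %>%
    inner_join(
      filter(prio, .data$priority_any) %>%
        select("variant_id", "gene", "consequence", "hgvs_c",
               "clinvar_pathogenic", "high_impact", "deleterious_missense"),
      by = "variant_id", relationship = "many-to-many"
    ) %>%
    mutate(source = "snv_sublist")
  splice_alleles <- gt %>%
    inner_join(
      select(spl, "variant_id", "gene", "consequence", "hgvs_c"),
      by = "variant_id", relationship = "many-to-many"
    ) %>%
    mutate(
      source = "splice",
      clinvar_pathogenic = FALSE, high_impact = FALSE, deleterious_missense = FALSE
    ) %>%
    anti_join(snv_alleles, by = c("participant_id", "variant_id"))
  small_alleles <- bind_rows(snv_alleles, splice_alleles) %>%
    rename(allele_id = "variant_id") %>%
    left_join(select(participants, "participant_id", "sex"), by = "participant_id") %>%
    mutate(zygosity = if_else(
      .data$zygosity == "hom" & .data$gene %in% x_genes & .data$sex == "male",
      "hemi", .data$zygosity
    )) %>%
    select(-"sex")

  # stage 3: SV rarity screen, gated on first-hit het carriers
  gate <- sv_gate(small_alleles)
  gated_ids <- gate$participant_id[gate$sv_gate]
  db <- build_sv_database(
    cohort$sv_calls,
    reciprocal_overlap_min = thresholds$sv_reciprocal_overlap_min,
    ins_window = thresholds$sv_ins_window
  )
  rare_clusters <- rare_svs(db, thresholds$sv_common_count)
  rare_members <- semi_join(db$members, rare_clusters, by = "cluster_id")
  sv_screened <- rare_members %>%
    overlaps_coding(cohort$exons) %>%
    filter(.data$overlaps_coding)
  sv_screened <- sv_screened[supported(sv_screened, thresholds), , drop = FALSE]
  sv_alleles <- sv_screened %>%
    filter(.data$participant_id %in% gated_ids) %>%
    tidyr::separate_longer_delim("genes_hit", delim = ",") %>%
    rename(gene = "genes_hit", allele_id = "sv_id") %>%
    mutate(
      zygosity = if_else(.data$genotype == "hom", "hom", "het"),
      source = "sv",
      consequence = paste0("sv_", tolower(.data$svtype)),
      hgvs_c = NA_character_,
      clinvar_pathogenic = FALSE, high_impact = FALSE, deleterious_missense = FALSE
    ) %>%
    filter(.data$gene %in% kb$genes$symbol) %>%
    select("participant_id", "allele_id", "gene", "zygosity", "source",
           "consequence", "hgvs_c", "cluster_id",
           "clinvar_pathogenic", "high_impact", "deleterious_missense")

  alleles <- bind_rows(small_alleles, select(sv_alleles, -"cluster_id")) %>%
    filter(.data$participant_id %in% eligible$participant_id)

  # curator ACMG classes; alleles without a curated class default to VUS
  alleles <- alleles %>%
    left_join(cohort$acmg, by = c("participant_id", "allele_id" = "variant_id")) %>%
    mutate(acmg_class = dplyr::coalesce(.data$acmg_class, "vus"))

  candidates <- assemble_candidates(alleles, kb)
  if (nrow(candidates) == 0L) {
    return(empty_diagnoses())
  }

  # carrier table for segregation: small-variant carriers from genotypes,
  # SV carriers from cluster co-membership
  sv_carriers <- sv_alleles %>%
    distinct(.data$allele_id, .data$cluster_id) %>%
    inner_join(
      select(db$members, "cluster_id", carrier = "participant_id"),
      by = "cluster_id", relationship = "many-to-many"
    ) %>%
    select(participant_id = "carrier", "allele_id")
  carriers <- bind_rows(
    select(gt, "participant_id", allele_id = "variant_id"),
    sv_carriers
  )
  candidates <- segregate(candidates, carriers, cohort$ped, genotyped_ids)
  n_cis <- sum(candidates$phase == "in_cis_excluded")
  if (n_cis > 0L) log_stage("segregate", in_cis_excluded = n_cis)
  candidates <- filter(candidates, .data$phase != "in_cis_excluded")
  if (nrow(candidates) == 0L) return(empty_diagnoses())

  # attach allele ACMG classes; drop candidates carrying benign alleles
  acmg_lookup <- alleles %>% distinct(.data$participant_id, .data$allele_id, .data$acmg_class)
  candidates$acmg <- purrr::map2(
    candidates$participant_id, candidates$allele_ids,
    function(pid, ids) {
      acmg_lookup$acmg_class[match(paste(pid, ids), paste(acmg_lookup$participant_id, acmg_lookup$allele_id))]
    }
  )
  benign <- purrr::map_lgl(candidates$acmg, ~ any(.x %in% c("benign", "likely_benign")))
  if (any(benign)) log_stage("confidence", dropped_benign = sum(benign))
  candidates <- candidates[!benign, , drop = FALSE]
  if (nrow(candidates) == 0L) return(empty_diagnoses())

  # one candidate per (participant, gene): top-ranked pair/genotype
  candidates <- candidates %>%
    mutate(.rank = candidate_rank(.data$acmg, .data$phase)) %>%
    group_by(.data$participant_id, .data$gene) %>%
    arrange(dplyr::desc(.data$.rank), .data$candidate_id, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select(-".rank")

  # reverse phenotyping
  closures <- feature_closures(kb, ontology)
  match_tbl <- purrr::map2_dfr(
    candidates$participant_id, candidates$gene,
    function(pid, g) {
      phenotype_match(hpo_sets[[pid]] %||% character(), g, kb, ontology, closures)
    }
  )
  candidates <- bind_cols(candidates, match_tbl)
  candidates$reportable <- decide_reportable(candidates$major_count)
  candidates$confidence <- purrr::pmap_chr(
    list(candidates$acmg, candidates$zygosities, candidates$inheritance, candidates$reportable),
    function(acmg, zyg, inh, rep) {
      if (!rep) return("unreportable")
      classify_confidence(acmg, zyg, inh)
    }
  )

  allele_detail <- alleles %>%
    distinct(.data$participant_id, .data$allele_id, .keep_all = TRUE)
  detail <- function(ids, pid, col) {
    vals <- allele_detail[[col]][match(
      paste(pid, ids),
      paste(allele_detail$participant_id, allele_detail$allele_id)
    )]
    paste(dplyr::coalesce(as.character(vals), "."), collapse = ";")
  }
  out <- candidates %>%
    left_join(
      select(participants, "participant_id", "sex", "recruitment_category"),
      by = "participant_id"
    ) %>%
    mutate(
      zygosity = purrr::map_chr(.data$zygosities, paste, collapse = ";"),
      source = purrr::map_chr(.data$sources, paste, collapse = ";"),
      origin = purrr::map_chr(.data$origins, paste, collapse = ";"),
      acmg_classes = purrr::map_chr(.data$acmg, paste, collapse = ";"),
      alleles = purrr::map_chr(.data$allele_ids, paste, collapse = ";"),
      consequence = purrr::map2_chr(.data$allele_ids, .data$participant_id,
                                    ~ detail(.x, .y, "consequence")),
      hgvs_c = purrr::map2_chr(.data$allele_ids, .data$participant_id,
                               ~ detail(.x, .y, "hgvs_c")),
      systems_involved = purrr::map_chr(.data$systems, paste, collapse = ";")
    ) %>%
    select(
      "participant_id", "sex", "recruitment_category", "gene", "inheritance",
      "n_alleles", "alleles", "zygosity", "source", "consequence", "hgvs_c",
      "segregation", "phase", "acmg_classes",
      "major_count", "minor_count", "systems_involved",
      "reportable", "confidence"
    ) %>%
    arrange(.data$participant_id, .data$gene)
  log_stage("run_pipeline", n_diagnoses = nrow(out), n_reportable = sum(out$reportable))
  class(out) <- c("rp_diagnoses", class(out))
  out
}

empty_diagnoses <- function() {
  out <- tibble(
    participant_id = character(), sex = character(), recruitment_category = character(),
    gene = character(), inheritance = character(), n_alleles = integer(),
    alleles = character(), zygosity = character(), source = character(),
    consequence = character(), hgvs_c = character(), segregation = character(),
    phase = character(), acmg_classes = character(),
    major_count = integer(), minor_count = integer(), systems_involved = character(),
    reportable = logical(), confidence = character()
  )
  class(out) <- c("rp_diagnoses", class(out))
  out
}

#' @exportS3Method generics::glance
glance.rp_diagnoses <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    n_reportable = sum(x$reportable),
    n_confident = sum(x$confidence == "confident"),
    n_probable = sum(x$confidence == "probable"),
    n_possible = sum(x$confidence == "possible"),
    n_unreportable = sum(x$confidence == "unreportable")
  )
}

#' Write the diagnosis table and per-participant summaries
#'
#' Writes the diagnosis table as TSV and, optionally, a plain-text
#' per-participant research-diagnosis summary.
#'
#' @param diagnoses An `rp_diagnoses` tibble from [run_pipeline()].
#' @param path Output TSV path.
#' @param report_dir Optional directory for per-participant text reports.
#' @return `path`, invisibly.
#' @export
write_diagnoses <- function(diagnoses, path, report_dir = NULL) {
  readr::write_tsv(as_tibble(diagnoses), path)
  if (!is.null(report_dir)) {
    dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(diagnoses))) {
      d <- diagnoses[i, ]
      lines <- c(
        paste0("Research-identified candidate diagnosis"),
        paste0("Participant: ", d$participant_id, " (", d$sex, ")"),
        paste0("Recruitment category: ", d$recruitment_category),
        paste0("Gene: ", d$gene, " [", d$inheritance, "]"),
        paste0("Alleles: ", d$alleles),
        paste0("Zygosity: ", d$zygosity, "; source: ", d$source),
        paste0("Segregation: ", d$segregation, "; phase: ", d$phase),
        paste0("ACMG classes: ", d$acmg_classes),
        paste0("Key features matched: ", d$major_count, " major, ", d$minor_count,
               " minor (systems: ", d$systems_involved, ")"),
        paste0("Reportable: ", ifelse(d$reportable, "yes", "no"),
               "; diagnostic confidence: ", d$confidence)
      )
      readr::write_lines(
        lines,
        file.path(report_dir, paste0(d$participant_id, "_", d$gene, ".txt"))
      )
    }
  }
  invisible(path)
}
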
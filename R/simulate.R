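# Seeded synthetic-cohort generator: emits every input file the pipeline
# reads, plus a truth table for recovery scoring.

#' Default planted-diagnosis plan
#'
#' One planted diagnosis per mechanism class the pipeline must recover:
#' homozygous SNV, compound-heterozygous SNVs, SNV plus rare coding SV,
#' SNV plus deep-intronic splice variant, and an X-linked single allele.
#' `acmg_1` applies to the first (or only) allele, `acmg_2` to the second.
#'
#' @return Tibble `gene`, `mechanism`, `acmg_1`, `acmg_2`.
#' @export
default_planted <- function() {
  tibble(
    gene = c("BBS10", "ALMS1", "ALMS1", "CEP290", "OFD1"),
    mechanism = c("hom_snv", "comphet_snv", "snv_plus_sv", "snv_plus_splice", "xlinked"),
    acmg_1 = c("vus", "pathogenic", "pathogenic", "pathogenic", "pathogenic"),
    acmg_2 = c(NA, "pathogenic", "likely_pathogenic", "vus", NA)
  )
}

MECHANISMS <- c("hom_snv", "comphet_snv", "snv_plus_sv", "snv_plus_splice", "xlinked")

#' Simulation configuration for synthetic cohorts
#'
#' Defines the statistical structure of a generated cohort. Defaults
#' emulate the conditions the pipeline was designed for: sparse HPO entry
#' (one or two terms per participant on average), a minority of planted
#' true diagnoses spanning all mechanism classes, decoy variants with
#' allele frequencies straddling the 0.002 rarity boundary (log-uniform
#' over \[1e-6, 0.05\]), common SV clusters above the 10-occurrence
#' cut-off, unaffected relatives in trios, and participants already solved
#' with other genes.
#'
#' @param n_participants Number of affected probands.
#' @param fraction_trios Fraction of probands with both parents sequenced.
#' @param planted Tibble of planted diagnoses (`gene`, `mechanism` in
#'   `hom_snv`, `comphet_snv`, `snv_plus_sv`, `snv_plus_splice`,
#'   `xlinked`, `acmg_1`, `acmg_2`); defaults to [default_planted()].
#' @param hpo_sparsity Expected HPO terms per participant (Poisson mean;
#'   zero-term profiles occur).
#' @param phenotype_noise Probability that a planted participant's profile
#'   contains no major-feature term, making the planted diagnosis
#'   unreportable.
#' @param decoy_rate Expected decoy small variants per participant;
#'   decoy allele frequencies are drawn log-uniformly over \[1e-6, 0.05\].
#' @param common_sv_cluster_sizes Carrier counts for planted common SV
#'   clusters (all at or above the rarity cut-off by default).
#' @param noise_sv_rate Expected non-coding noise SVs per participant.
#' @param n_solved_other Probands given a planted-like genotype but
#'   recorded as solved with an alternative gene (must not be reported).
#' @param planted_cis Number of additional compound-het plants whose two
#'   alleles are given to the same parent (must be phased out; requires
#'   trios).
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 100L,
                              fraction_trios = 0.5,
                              planted = default_planted(),
                              hpo_sparsity = 2,
                              phenotype_noise = 0.3,
                              decoy_rate = 0.5,
                              common_sv_cluster_sizes = c(15L, 12L),
                              noise_sv_rate = 0.2,
                              n_solved_other = 2L,
                              planted_cis = 0L,
                              seed) {
  if (missing(seed)) stop_validation("seed is mandatory for reproducibility")
  planted <- as_tibble(planted)
  if (nrow(planted) > 0L) {
    if (!all(c("gene", "mechanism", "acmg_1") %in% names(planted))) {
      stop_validation("planted needs gene, mechanism, acmg_1 (and acmg_2) columns")
    }
    if (!"acmg_2" %in% names(planted)) planted$acmg_2 <- NA_character_
    if (any(!planted$mechanism %in% MECHANISMS)) {
      stop_validation("unknown mechanism; use ", paste(MECHANISMS, collapse = ", "))
    }
    two_allele <- planted$mechanism %in% c("comphet_snv", "snv_plus_sv", "snv_plus_splice")
    if (any(two_allele & is.na(planted$acmg_2))) {
      stop_validation("two-allele mechanisms need acmg_2")
    }
  }
  if (!is_proportion(fraction_trios, lo_open = FALSE, hi_open = FALSE)) {
    stop_validation("fraction_trios must be in [0, 1]")
  }
  if (!is_proportion(phenotype_noise, lo_open = FALSE, hi_open = FALSE)) {
    stop_validation("phenotype_noise must be in [0, 1]")
  }
  n_trio <- floor(fraction_trios * n_participants)
  if (nrow(planted) + n_solved_other + planted_cis > n_participants) {
    stop_validation("infeasible config: more planted diagnoses than participants")
  }
  if (planted_cis > 0L && n_trio < nrow(planted) + n_solved_other + planted_cis) {
    stop_validation("infeasible config: cis plants need trio probands beyond the planted ones")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      fraction_trios = fraction_trios,
      planted = planted,
      hpo_sparsity = hpo_sparsity,
      phenotype_noise = phenotype_noise,
      decoy_rate = decoy_rate,
      common_sv_cluster_sizes = as.integer(common_sv_cluster_sizes),
      noise_sv_rate = noise_sv_rate,
      n_solved_other = as.integer(n_solved_other),
      planted_cis = as.integer(planted_cis),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# variant annotation templates by ACMG class: P/LP plants are ClinVar-asserted
# frameshifts (high impact), VUS plants are deleterious missenses
plant_annotation <- function(acmg_class) {
  if (acmg_class %in% c("pathogenic", "likely_pathogenic")) {
    list(consequence = "frameshift_variant", clinsig = acmg_class,
         missense_class = "absent")
  } else {
    list(consequence = "missense_variant", clinsig = "absent",
         missense_class = "deleterious")
  }
}

rand_base <- function(n, not = NULL) {
  bases <- c("A", "C", "G", "T")
  out <- sample(bases, n, replace = TRUE)
  if (!is.null(not)) {
    while (any(out == not)) {
      out[out == not] <- sample(bases, sum(out == not), replace = TRUE)
    }
  }
  out
}

#' Generate a synthetic cohort with a truth table
#'
#' Writes every input file the pipeline reads (`small_variants.vcf` with
#' the documented `RPANN` annotation and per-sample genotypes, `svs.tsv`,
#' `pedigree.ped`, `participants.tsv`, `hpo.tsv`, `acmg.tsv`, `exons.bed`)
#' plus `truth.tsv`, the list of planted diagnoses with their expected
#' reportability (derived from whether the sampled HPO terms include a
#' major-feature term) and expected confidence tier. Output is
#' deterministic given the config seed, which is recorded in each file
#' header.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param kb Knowledge base (defaults to the packaged panel).
#' @param ontology Ontology (defaults to the packaged miniature extract).
#' @return Invisibly, a list with `dir`, `truth` (tibble) and the in-memory
#'   cohort tables.
#' @export
generate_cohort <- function(cfg, dir,
                            kb = load_fixture("table1"),
                            ontology = read_obo(system.file("extdata", "hpo_mini.obo", package = "revphen"))) {
  stopifnot(inherits(cfg, "simulation_config"))
  bad_gene <- setdiff(cfg$planted$gene, kb$genes$symbol)
  if (length(bad_gene) > 0L) {
    stop_validation("planted gene not in knowledge base: ", paste(bad_gene, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_rp_seed(cfg$seed, generate_cohort_impl(cfg, dir, kb, ontology))
}

generate_cohort_impl <- function(cfg, dir, kb, ontology) {
  n <- cfg$n_participants
  exons <- synthetic_exons()
  models <- synthetic_gene_models()
  closures <- feature_closures(kb, ontology)
  inh <- setNames(kb$genes$inheritance, kb$genes$symbol)
  background_terms <- grep("^HP:98900", ontology$terms$id, value = TRUE)
  if (length(background_terms) == 0L) {
    # fall back to terms outside every feature closure
    background_terms <- setdiff(ontology$terms$id, unique(unlist(closures)))
  }

  # --- participants and pedigree ------------------------------------------
  pid <- sprintf("P%04d", seq_len(n))
  n_trio <- floor(cfg$fraction_trios * n)
  is_trio <- seq_len(n) <= n_trio
  sex <- sample(c("male", "female"), n, replace = TRUE)
  fam <- sprintf("FAM%04d", seq_len(n))
  father <- ifelse(is_trio, sprintf("F%04d", seq_len(n)), NA_character_)
  mother <- ifelse(is_trio, sprintf("M%04d", seq_len(n)), NA_character_)

  n_plant <- nrow(cfg$planted)
  # planted diagnoses occupy the first probands, then solved-other decoys,
  # then cis plants; trios are the first n_trio probands, so cis plants are
  # guaranteed trios by the feasibility check
  plant_idx <- seq_len(n_plant)
  solved_idx <- if (cfg$n_solved_other > 0L) n_plant + seq_len(cfg$n_solved_other) else integer()
  cis_idx <- if (cfg$planted_cis > 0L) {
    n_plant + cfg$n_solved_other + seq_len(cfg$planted_cis)
  } else {
    integer()
  }
  # xlinked plants need a sex-consistent carrier; fix sex now
  if (n_plant > 0L) {
    for (k in plant_idx) {
      if (cfg$planted$mechanism[k] == "xlinked" && sex[k] == "unknown") sex[k] <- "female"
    }
  }

  ped <- tibble(
    family_id = fam, participant_id = pid,
    father_id = father, mother_id = mother,
    sex = sex, affected = TRUE
  )
  parent_rows <- bind_rows(
    tibble(
      family_id = fam[is_trio], participant_id = father[is_trio],
      father_id = NA_character_, mother_id = NA_character_,
      sex = "male", affected = FALSE
    ),
    tibble(
      family_id = fam[is_trio], participant_id = mother[is_trio],
      father_id = NA_character_, mother_id = NA_character_,
      sex = "female", affected = FALSE
    )
  )
  ped <- bind_rows(ped, parent_rows)

  solved_status <- rep("unsolved", n)
  solved_status[solved_idx] <- "solved_other_gene"
  meta <- tibble(
    participant_id = pid,
    proband = TRUE,
    solved_status = solved_status,
    recruitment_category = sample(
      c("Rod-cone dystrophy", "Cystic kidney disease", "Intellectual disability",
        "Congenital hearing impairment", "Epilepsy plus other features"),
      n, replace = TRUE
    )
  )
  meta <- bind_rows(meta, tibble(
    participant_id = parent_rows$participant_id,
    proband = FALSE, solved_status = "unsolved",
    recruitment_category = "Unaffected relative"
  ))
  all_ids <- ped$participant_id

  # --- variant bookkeeping -------------------------------------------------
  variants <- list()  # annotated variant rows
  carriers <- list()  # (variant_id, participant_id, zygosity)
  acmg <- list()      # curator classes for planted alleles
  svs <- list()       # SV call rows
  truth <- list()
  used_gene <- character() # "pid|gene" pairs with planted/decoy priority hets

  exon_pos <- function(gene, exon_no, offset) {
    e <- exons[exons$gene == gene & exons$exon_no == exon_no, ]
    list(chrom = e$chrom[1], pos = as.integer(e$start[1] + offset))
  }
  add_variant <- function(gene, chrom, pos, acmg_class = NULL, splice = FALSE,
                          cohort_af = NULL) {
    ref <- rand_base(1)
    alt <- rand_base(1, not = ref)
    af <- cohort_af %||% 10^runif(1, -6, -4.5)
    if (splice) {
      ann <- list(consequence = "intron_variant", clinsig = "absent",
                  missense_class = "absent")
      ds <- round(runif(1, 0.55, 0.95), 2)
    } else {
      ann <- plant_annotation(acmg_class %||% "vus")
      ds <- NA_real_
    }
    row <- tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
      transcript = NA_character_,
      canonical = TRUE,
      consequence = ann$consequence,
      cohort_af = signif(af, 3), popdb_af = NA_real_,
      clinsig = ann$clinsig, missense_class = ann$missense_class,
      ds_ag = ds, ds_al = NA_real_, ds_dg = NA_real_, ds_dl = NA_real_,
      hgvs_c = paste0(gene, ":c.", pos %% 10000, ref, ">", alt),
      hgvs_p = NA_character_
    )
    row$transcript <- kb$genes$canonical_transcript[match(gene, kb$genes$symbol)]
    variants[[length(variants) + 1L]] <<- row
    variant_key(chrom, pos, ref, alt)
  }
  add_carrier <- function(vid, who, zyg) {
    carriers[[length(carriers) + 1L]] <<- tibble(
      variant_id = vid, participant_id = who, zygosity = zyg
    )
  }

  # distinct random exon offsets per gene so planted sites never collide
  next_offset <- new.env()
  fresh_pos <- function(gene, exon_no) {
    key <- paste(gene, exon_no)
    cur <- get0(key, envir = next_offset, ifnotfound = 10L)
    assign(key, cur + sample(3:9, 1), envir = next_offset)
    exon_pos(gene, exon_no, cur)
  }

  plant_one <- function(k, idx, cis = FALSE) {
    gene <- cfg$planted$gene[k]
    mech <- cfg$planted$mechanism[k]
    a1 <- cfg$planted$acmg_1[k]
    a2 <- cfg$planted$acmg_2[k]
    who <- pid[idx]
    trio <- is_trio[idx]
    allele_ids <- character()
    if (mech == "hom_snv") {
      p <- fresh_pos(gene, sample(2:9, 1))
      vid <- add_variant(gene, p$chrom, p$pos, a1)
      add_carrier(vid, who, "hom")
      if (trio) {
        add_carrier(vid, ped$father_id[idx], "het")
        add_carrier(vid, ped$mother_id[idx], "het")
      }
      allele_ids <- vid
      acmg[[length(acmg) + 1L]] <<- tibble(
        participant_id = who, variant_id = vid, acmg_class = a1
      )
      zyg <- "hom"
    } else if (mech == "comphet_snv") {
      p1 <- fresh_pos(gene, sample(2:5, 1))
      p2 <- fresh_pos(gene, sample(6:9, 1))
      v1 <- add_variant(gene, p1$chrom, p1$pos, a1)
      v2 <- add_variant(gene, p2$chrom, p2$pos, a2)
      add_carrier(v1, who, "het")
      add_carrier(v2, who, "het")
      if (trio) {
        if (cis) {
          add_carrier(v1, ped$mother_id[idx], "het")
          add_carrier(v2, ped$mother_id[idx], "het")
        } else {
          add_carrier(v1, ped$mother_id[idx], "het")
          add_carrier(v2, ped$father_id[idx], "het")
        }
      }
      allele_ids <- c(v1, v2)
      acmg[[length(acmg) + 1L]] <<- tibble(
        participant_id = who, variant_id = c(v1, v2), acmg_class = c(a1, a2)
      )
      zyg <- "het;het"
    } else if (mech == "snv_plus_sv") {
      p1 <- fresh_pos(gene, sample(2:4, 1))
      v1 <- add_variant(gene, p1$chrom, p1$pos, a1)
      add_carrier(v1, who, "het")
      if (trio) add_carrier(v1, ped$father_id[idx], "het")
      # deletion spanning the terminal four exons
      ge <- exons[exons$gene == gene, ]
      del_start <- ge$start[7] - 500L
      del_end <- ge$end[10] + 500L
      sv_row <- tibble(
        participant_id = who, chrom = ge$chrom[1],
        start = del_start, end = del_end, svtype = "DEL",
        caller = "canvas", read_fraction = round(runif(1, 0.4, 0.6), 2),
        genotype = "het"
      )
      svs[[length(svs) + 1L]] <<- sv_row
      if (trio) {
        svs[[length(svs) + 1L]] <<- mutate(sv_row, participant_id = ped$mother_id[idx])
      }
      sv_vid <- paste(who, ge$chrom[1], del_start, del_end, "DEL", sep = ":")
      allele_ids <- c(v1, sv_vid)
      acmg[[length(acmg) + 1L]] <<- tibble(
        participant_id = who, variant_id = c(v1, sv_vid), acmg_class = c(a1, a2)
      )
      zyg <- "het;het"
    } else if (mech == "snv_plus_splice") {
      p1 <- fresh_pos(gene, sample(2:5, 1))
      v1 <- add_variant(gene, p1$chrom, p1$pos, a1)
      # deep-intronic splice variant: well inside the intron after exon 6
      ge <- exons[exons$gene == gene, ]
      sp_pos <- as.integer(ge$end[6] + 874L)
      v2 <- add_variant(gene, ge$chrom[1], sp_pos, splice = TRUE)
      add_carrier(v1, who, "het")
      add_carrier(v2, who, "het")
      if (trio) {
        add_carrier(v1, ped$mother_id[idx], "het")
        add_carrier(v2, ped$father_id[idx], "het")
      }
      allele_ids <- c(v1, v2)
      acmg[[length(acmg) + 1L]] <<- tibble(
        participant_id = who, variant_id = c(v1, v2), acmg_class = c(a1, a2)
      )
      zyg <- "het;het"
    } else { # xlinked
      p <- fresh_pos(gene, sample(2:9, 1))
      vid <- add_variant(gene, p$chrom, p$pos, a1)
      zyg1 <- if (sex[idx] == "male") "hom" else "het" # single-entry X genotype
      add_carrier(vid, who, zyg1)
      allele_ids <- vid
      acmg[[length(acmg) + 1L]] <<- tibble(
        participant_id = who, variant_id = vid, acmg_class = a1
      )
      zyg <- if (sex[idx] == "male") "hemi" else "het"
    }
    used_gene <<- c(used_gene, paste(who, gene, sep = "|"))
    tibble(
      participant_id = who, gene = gene, mechanism = mech,
      zygosity = zyg, trio = trio, cis = cis,
      acmg_1 = a1, acmg_2 = a2,
      allele_ids = paste(allele_ids, collapse = ";")
    )
  }

  for (k in seq_len(n_plant)) {
    truth[[length(truth) + 1L]] <- plant_one(k, plant_idx[k])
  }
  # solved-other decoys reuse the first planted mechanisms
  for (j in seq_along(solved_idx)) {
    k <- ((j - 1L) %% max(n_plant, 1L)) + 1L
    if (n_plant > 0L) {
      row <- plant_one(k, solved_idx[j])
      row$mechanism <- paste0(row$mechanism, "_solved_other")
      truth[[length(truth) + 1L]] <- row
    }
  }
  # cis plants: comp-het with both alleles given to one parent; reuse the
  # first planted row's gene but force a comp-het plan
  for (j in seq_along(cis_idx)) {
    kk <- which(cfg$planted$mechanism == "comphet_snv")
    use <- if (length(kk) > 0L) kk[1] else 1L
    saved <- cfg$planted
    cfg$planted$mechanism[use] <- "comphet_snv"
    if (is.na(cfg$planted$acmg_2[use])) cfg$planted$acmg_2[use] <- "pathogenic"
    row <- plant_one(use, cis_idx[j], cis = TRUE)
    cfg$planted <- saved
    truth[[length(truth) + 1L]] <- row
  }

  # --- decoy small variants ------------------------------------------------
  n_decoys <- round(cfg$decoy_rate * n)
  for (d in seq_len(n_decoys)) {
    gene <- sample(kb$genes$symbol, 1)
    af <- 10^runif(1, log10(1e-6), log10(0.05))
    p <- fresh_pos(gene, sample(2:9, 1))
    vid <- add_variant(gene, p$chrom, p$pos, "vus", cohort_af = signif(af, 3))
    if (af >= 0.002) {
      # common decoy: many carriers (removed by the rarity filter)
      n_car <- max(3L, round(af * 2 * n))
      for (who in sample(pid, min(n_car, n))) add_carrier(vid, who, "het")
    } else {
      # rare singleton decoy: one carrier, never in a gene where that
      # participant already has a prioritised allele (no accidental pairs)
      # and never in a participant with a planted diagnosis, whose sampled
      # phenotype terms may legitimately match other panel genes
      planted_pids <- unique(bind_rows(truth)$participant_id)
      cand <- pid[!paste(pid, gene, sep = "|") %in% used_gene &
                    !pid %in% planted_pids]
      if (length(cand) == 0L) next
      who <- sample(cand, 1)
      add_carrier(vid, who, "het")
      used_gene <- c(used_gene, paste(who, gene, sep = "|"))
    }
  }

  # --- SV decoys -----------------------------------------------------------
  for (s in cfg$common_sv_cluster_sizes) {
    gene <- sample(kb$genes$symbol, 1)
    ge <- exons[exons$gene == gene, ]
    base_start <- ge$start[3] - 200L
    base_end <- ge$end[5] + 200L
    span <- base_end - base_start + 1L
    for (who in sample(all_ids, min(s, length(all_ids)))) {
      jitter <- sample(0:floor(span * 0.02), 2, replace = TRUE)
      svs[[length(svs) + 1L]] <- tibble(
        participant_id = who, chrom = ge$chrom[1],
        start = base_start + jitter[1], end = base_end + jitter[2],
        svtype = "DEL", caller = "manta",
        read_fraction = round(runif(1, 0.35, 0.6), 2), genotype = "het"
      )
    }
  }
  n_noise_sv <- round(cfg$noise_sv_rate * n)
  for (d in seq_len(n_noise_sv)) {
    g <- models[sample(nrow(models), 1), ]
    # wholly intronic: inside the intron after exon 1, never touching exons
    istart <- as.integer(g$tx_start + g$exon_len + 100L + sample(0:2000, 1))
    svs[[length(svs) + 1L]] <- tibble(
      participant_id = sample(all_ids, 1), chrom = g$chrom,
      start = istart, end = istart + 800L,
      svtype = sample(c("DEL", "DUP", "INV"), 1), caller = "manta",
      read_fraction = round(runif(1, 0.1, 0.6), 2), genotype = "het"
    )
  }

  # --- HPO profiles --------------------------------------------------------
  hpo_rows <- list()
  truth_tbl <- bind_rows(truth)
  planted_by_pid <- split(truth_tbl$gene, truth_tbl$participant_id)
  major_hit <- setNames(rep(FALSE, n), pid)
  for (i in seq_len(n)) {
    who <- pid[i]
    genes_i <- planted_by_pid[[who]]
    terms <- character()
    if (!is.null(genes_i)) {
      gf <- features_for_gene(kb, genes_i[1])
      majors <- gf$feature_id[gf$weight == "major"]
      minors <- gf$feature_id[gf$weight == "minor"]
      noisy <- runif(1) < cfg$phenotype_noise
      if (!noisy && length(majors) > 0L) {
        feat <- sample(majors, 1)
        terms <- c(terms, sample(closures[[feat]], 1))
      }
      n_extra <- rpois(1, max(cfg$hpo_sparsity - 1, 0))
      extra_pool <- c(
        if (length(minors) > 0L) unlist(closures[minors]) else character(),
        background_terms
      )
      if (n_extra > 0L && length(extra_pool) > 0L) {
        terms <- c(terms, sample(extra_pool, min(n_extra, length(extra_pool))))
      }
    } else {
      n_terms <- rpois(1, cfg$hpo_sparsity)
      if (n_terms > 0L) {
        terms <- sample(background_terms, min(n_terms, length(background_terms)))
      }
    }
    terms <- unique(terms)
    if (length(terms) > 0L) {
      hpo_rows[[length(hpo_rows) + 1L]] <- tibble(participant_id = who, hpo_id = terms)
    }
    # expected reportability from the actually sampled terms
    if (!is.null(genes_i)) {
      m <- phenotype_match(terms, genes_i[1], kb, ontology, closures)
      major_hit[who] <- m$major_count >= 1
    }
  }
  hpo <- if (length(hpo_rows)) bind_rows(hpo_rows) else {
    tibble(participant_id = character(), hpo_id = character())
  }

  # --- truth table ---------------------------------------------------------
  truth_tbl <- truth_tbl %>%
    mutate(
      eligible = !stringr::str_detect(.data$mechanism, "solved_other"),
      expected_reportable = major_hit[.data$participant_id],
      expected_reported = .data$eligible & !.data$cis & .data$expected_reportable,
      expected_confidence = purrr::pmap_chr(
        list(.data$acmg_1, .data$acmg_2, .data$zygosity, .data$gene, .data$expected_reportable),
        function(a1, a2, zyg, gene, rep) {
          if (!rep) return("unreportable")
          classes <- c(a1, if (!is.na(a2)) a2)
          zygs <- stringr::str_split_1(zyg, stringr::fixed(";"))
          classify_confidence(classes, zygs, inh[[gene]])
        }
      )
    )

  # --- write files ---------------------------------------------------------
  variants_tbl <- annotated_variants(bind_rows(variants))
  carriers_tbl <- bind_rows(carriers)
  svs_tbl <- if (length(svs)) sv_calls(bind_rows(svs)) else {
    sv_calls(tibble(
      participant_id = character(), chrom = character(),
      start = integer(), end = integer(), svtype = character()
    ))
  }
  acmg_tbl <- bind_rows(acmg)
  seed_hdr <- paste0("# seed: ", cfg$seed)

  write_cohort_vcf(variants_tbl, carriers_tbl, all_ids, file.path(dir, "small_variants.vcf"), cfg$seed)
  readr::write_lines(seed_hdr, file.path(dir, "svs.tsv"))
  readr::write_tsv(select(svs_tbl, -"sv_id"), file.path(dir, "svs.tsv"), append = TRUE, col_names = TRUE)
  write_ped(ped, file.path(dir, "pedigree.ped"), header = seed_hdr)
  readr::write_lines(seed_hdr, file.path(dir, "participants.tsv"))
  readr::write_tsv(meta, file.path(dir, "participants.tsv"), append = TRUE, col_names = TRUE)
  readr::write_lines(seed_hdr, file.path(dir, "hpo.tsv"))
  readr::write_tsv(hpo, file.path(dir, "hpo.tsv"), append = TRUE, col_names = TRUE)
  readr::write_lines(seed_hdr, file.path(dir, "acmg.tsv"))
  readr::write_tsv(acmg_tbl, file.path(dir, "acmg.tsv"), append = TRUE, col_names = TRUE)
  write_exon_bed(synthetic_exons(), file.path(dir, "exons.bed"))
  readr::write_lines(seed_hdr, file.path(dir, "truth.tsv"))
  readr::write_tsv(truth_tbl, file.path(dir, "truth.tsv"), append = TRUE, col_names = TRUE)

  log_stage("generate_cohort",
    n_participants = n, n_variants = nrow(variants_tbl),
    n_svs = nrow(svs_tbl), n_planted = nrow(truth_tbl)
  )
  invisible(list(
    dir = dir, truth = truth_tbl, variants = variants_tbl,
    carriers = carriers_tbl, sv_calls = svs_tbl, ped = ped, meta = meta,
    hpo = hpo, acmg = acmg_tbl
  ))
}

# write a VCF 4.2 with RPANN annotations and per-sample GT columns
write_cohort_vcf <- function(variants, carriers, sample_ids, path, seed) {
  ann <- sprintf(
    "%s|%s|%s|YES|%s|%s|%s|%s|%s|%s|%s|%s|%s|%s|%s",
    variants$alt, variants$gene, variants$transcript,
    variants$consequence,
    ifelse(is.na(variants$cohort_af), "", format(variants$cohort_af, scientific = TRUE, trim = TRUE)),
    ifelse(is.na(variants$popdb_af), "", format(variants$popdb_af, scientific = TRUE, trim = TRUE)),
    ifelse(variants$clinsig == "absent", "", variants$clinsig),
    ifelse(variants$missense_class == "absent", "", variants$missense_class),
    ifelse(is.na(variants$ds_ag), "", format(variants$ds_ag, trim = TRUE)),
    ifelse(is.na(variants$ds_al), "", format(variants$ds_al, trim = TRUE)),
    ifelse(is.na(variants$ds_dg), "", format(variants$ds_dg, trim = TRUE)),
    ifelse(is.na(variants$ds_dl), "", format(variants$ds_dl, trim = TRUE)),
    ifelse(is.na(variants$hgvs_c), "", variants$hgvs_c),
    ifelse(is.na(variants$hgvs_p), "", variants$hgvs_p)
  )
  gt_map <- matrix("0/0", nrow = nrow(variants), ncol = length(sample_ids),
                   dimnames = list(variants$variant_id, sample_ids))
  for (i in seq_len(nrow(carriers))) {
    vid <- carriers$variant_id[i]
    who <- carriers$participant_id[i]
    if (!who %in% sample_ids) next
    gt_map[vid, who] <- if (carriers$zygosity[i] == "hom") "1/1" else "0/1"
  }
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##seed=", seed),
    paste0(
      "##INFO=<ID=RPANN,Number=.,Type=String,Description=\"Annotation: ",
      "Allele|Gene|Transcript|Canonical|Consequence|Cohort_AF|PopDB_AF|",
      "ClinSig|Missense|DS_AG|DS_AL|DS_DG|DS_DL|HGVSc|HGVSp\">"
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", sample_ids),
          collapse = "\t")
  )
  body <- vapply(ord, function(i) {
    paste(c(
      variants$chrom[i], variants$pos[i], ".", variants$ref[i], variants$alt[i],
      ".", "PASS", paste0("RPANN=", ann[i]), "GT", gt_map[i, ]
    ), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Score pipeline recovery against a truth table
#'
#' Sensitivity is the fraction of planted, expected-reportable diagnoses
#' (eligible, not in cis) recovered as reportable output rows, matching on
#' (participant, gene). A false report is a reportable output row whose
#' (participant, gene) appears nowhere in the truth table.
#'
#' @param truth Truth tibble from [generate_cohort()].
#' @param diagnoses Output of [run_pipeline()].
#' @return One-row tibble: `n_expected`, `n_recovered`, `sensitivity`,
#'   `n_false_reports`.
#' @export
score_recovery <- function(truth, diagnoses) {
  truth <- as_tibble(truth)
  diagnoses <- as_tibble(diagnoses)
  expected <- filter(truth, .data$expected_reported)
  reported <- filter(diagnoses, .data$reportable)
  key <- function(df) paste(df$participant_id, df$gene)
  recovered <- sum(key(expected) %in% key(reported))
  false_reports <- sum(!key(reported) %in% key(truth))
  tibble(
    n_expected = nrow(expected),
    n_recovered = recovered,
    sensitivity = if (nrow(expected) == 0L) NA_real_ else recovered / nrow(expected),
    n_false_reports = false_reports
  )
}
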
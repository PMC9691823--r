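test_that("eligibility excludes unaffected relatives and solved-other participants", {
  participants <- tibble::tibble(
    participant_id = c("P1", "P2", "P3", "P4", "P5"),
    affected = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    solved_status = c("unsolved", "unsolved", "solved_other_gene",
                      "partially_solved_other_gene", "solved_target_gene")
  )
  out <- eligible_participants(participants)
  expect_setequal(out$participant_id, c("P1", "P5"))
})

alleles_tbl <- function(...) {
  tibble::tibble(...)
}

test_that("candidate assembly follows the inheritance model", {
  kb <- panel_kb()
  # two het frameshifts in a recessive gene -> one compound-het candidate
  a <- alleles_tbl(
    participant_id = "P1", gene = "ALMS1",
    allele_id = c("v1", "v2"), zygosity = "het", source = "snv_sublist"
  )
  cand <- assemble_candidates(a, kb)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_alleles, 2L)
  expect_setequal(cand$allele_ids[[1]], c("v1", "v2"))

  # het SNV + rare coding SV -> one candidate with an sv-source allele
  b <- alleles_tbl(
    participant_id = "P1", gene = "ALMS1",
    allele_id = c("v1", "sv1"), zygosity = "het",
    source = c("snv_sublist", "sv")
  )
  cand_b <- assemble_candidates(b, kb)
  expect_equal(nrow(cand_b), 1L)
  expect_true("sv" %in% cand_b$sources[[1]])

  # single het in a recessive gene -> no candidate
  c1 <- alleles_tbl(
    participant_id = "P1", gene = "ALMS1",
    allele_id = "v1", zygosity = "het", source = "snv_sublist"
  )
  expect_equal(nrow(assemble_candidates(c1, kb)), 0L)

  # homozygous deep-intronic splice allele -> candidate on its own
  d <- alleles_tbl(
    participant_id = "P1", gene = "CEP290",
    allele_id = "spl1", zygosity = "hom", source = "splice"
  )
  cand_d <- assemble_candidates(d, kb)
  expect_equal(nrow(cand_d), 1L)
  expect_equal(cand_d$n_alleles, 1L)

  # X-linked gene: het female / hemi male single-allele candidates
  e <- alleles_tbl(
    participant_id = c("P1", "P2"), gene = "OFD1",
    allele_id = c("x1", "x2"), zygosity = c("het", "hemi"), source = "snv_sublist"
  )
  cand_e <- assemble_candidates(e, kb)
  expect_equal(nrow(cand_e), 2L)
  expect_true(all(cand_e$n_alleles == 1L))

  # three het alleles -> all three pairs emitted
  f <- alleles_tbl(
    participant_id = "P1", gene = "ALMS1",
    allele_id = c("v1", "v2", "v3"), zygosity = "het", source = "snv_sublist"
  )
  expect_equal(nrow(assemble_candidates(f, kb)), 3L)
})

trio_ped <- tibble::tibble(
  family_id = "F1",
  participant_id = c("P1", "DAD", "MUM"),
  father_id = c("DAD", NA, NA),
  mother_id = c("MUM", NA, NA),
  sex = c("female", "male", "female"),
  affected = c(TRUE, FALSE, FALSE)
)

comphet_candidate <- function() {
  kb <- panel_kb()
  assemble_candidates(alleles_tbl(
    participant_id = "P1", gene = "ALMS1",
    allele_id = c("v1", "v2"), zygosity = "het", source = "snv_sublist"
  ), kb)
}

test_that("segregation phases compound hets and detects de novo alleles", {
  cand <- comphet_candidate()
  genotyped <- c("P1", "DAD", "MUM")
  # one allele per parent -> in trans
  carriers <- tibble::tibble(
    participant_id = c("P1", "P1", "DAD", "MUM"),
    allele_id = c("v1", "v2", "v1", "v2")
  )
  seg <- segregate(cand, carriers, trio_ped, genotyped)
  expect_equal(seg$phase, "in_trans")
  expect_setequal(seg$origins[[1]], c("paternal", "maternal"))

  # both alleles in the mother, father genotyped and negative -> cis, excluded
  carriers_cis <- tibble::tibble(
    participant_id = c("P1", "P1", "MUM", "MUM"),
    allele_id = c("v1", "v2", "v1", "v2")
  )
  seg_cis <- segregate(cand, carriers_cis, trio_ped, genotyped)
  expect_equal(seg_cis$phase, "in_cis_excluded")

  # allele absent in both genotyped parents -> de novo
  carriers_dn <- tibble::tibble(
    participant_id = c("P1", "P1", "MUM"),
    allele_id = c("v1", "v2", "v2")
  )
  seg_dn <- segregate(cand, carriers_dn, trio_ped, genotyped)
  expect_equal(sort(seg_dn$origins[[1]]), c("de_novo", "maternal"))
  expect_equal(seg_dn$phase, "in_trans") # de novo + maternal is trans

  # no parents genotyped -> unphased, origins unknown
  seg_unk <- segregate(cand, carriers[1:2, ], trio_ped, "P1")
  expect_equal(seg_unk$phase, "unphased")
  expect_equal(seg_unk$origins[[1]], c("unknown", "unknown"))
})

test_that("homozygous segregation recognises bi-parental inheritance and inconsistency", {
  kb <- panel_kb()
  cand <- assemble_candidates(alleles_tbl(
    participant_id = "P1", gene = "ALMS1",
    allele_id = "v1", zygosity = "hom", source = "snv_sublist"
  ), kb)
  genotyped <- c("P1", "DAD", "MUM")
  both <- tibble::tibble(
    participant_id = c("P1", "DAD", "MUM"), allele_id = "v1"
  )
  seg <- segregate(cand, both, trio_ped, genotyped)
  expect_equal(seg$segregation, "bi_parental")
  expect_equal(seg$phase, "in_trans")
  # hom child but one genotyped parent lacks the allele -> warning, unknown
  one <- tibble::tibble(participant_id = c("P1", "MUM"), allele_id = "v1")
  expect_warning(
    seg_bad <- segregate(cand, one, trio_ped, genotyped),
    "Mendelian"
  )
  expect_equal(seg_bad$origins[[1]], "unknown")
})

test_that("phenotype matching counts features once via descendant closure", {
  kb <- panel_kb()
  obo <- mini_ontology()
  closures <- feature_closures(kb, obo)
  # empty profile: nothing matches
  m0 <- phenotype_match(character(), "ALMS1", kb, obo, closures)
  expect_equal(m0$major_count, 0L)
  expect_equal(m0$minor_count, 0L)
  # a term strictly below the retinal-dystrophy anchor matches the major
  # feature for a retinal gene, flagging the ophthalmic system
  rd <- setdiff(closures[["retinal_dystrophy"]], "HP:0000556")[1]
  m1 <- phenotype_match(rd, "ALMS1", kb, obo, closures)
  expect_equal(m1$major_count, 1L)
  expect_equal(m1$systems[[1]], "Ophthalmic")
  # two distinct terms under the same feature count once
  rd2 <- setdiff(closures[["retinal_dystrophy"]], "HP:0000556")[2]
  m2 <- phenotype_match(c(rd, rd2), "ALMS1", kb, obo, closures)
  expect_equal(m2$major_count, 1L)
  # unknown terms are ignored, not fatal
  m3 <- phenotype_match(c(rd, "HP:1234567"), "ALMS1", kb, obo, closures)
  expect_equal(m3$major_count, 1L)
})

test_that("phenotype matching equals a brute-force term-by-feature scan", {
  kb <- panel_kb()
  obo <- mini_ontology()
  closures <- feature_closures(kb, obo)
  withr::local_seed(99)
  for (rep in 1:20) {
    gene <- sample(kb$genes$symbol, 1)
    terms <- sample(obo$terms$id, sample(0:6, 1))
    m <- phenotype_match(terms, gene, kb, obo, closures)
    gf <- features_for_gene(kb, gene)
    # brute force: a feature matches if any term lies in the brute closure
    hit <- vapply(gf$feature_id, function(f) {
      anchors <- kb$features$hpo_terms[[match(f, kb$features$feature_id)]]
      any(terms %in% brute_closure(obo$edges, anchors))
    }, logical(1))
    expect_equal(m$major_count, sum(hit & gf$weight == "major"))
    expect_equal(m$minor_count, sum(hit & gf$weight == "minor"))
  }
})

test_that("adding HPO terms never decreases the major count or reportability", {
  kb <- panel_kb()
  obo <- mini_ontology()
  closures <- feature_closures(kb, obo)
  withr::local_seed(7)
  for (rep in 1:25) {
    gene <- sample(kb$genes$symbol, 1)
    base <- sample(obo$terms$id, sample(0:4, 1))
    extra <- c(base, sample(obo$terms$id, sample(1:4, 1)))
    m_base <- phenotype_match(base, gene, kb, obo, closures)
    m_ext <- phenotype_match(extra, gene, kb, obo, closures)
    expect_gte(m_ext$major_count, m_base$major_count)
    expect_gte(m_ext$minor_count, m_base$minor_count)
    if (decide_reportable(m_base$major_count)) {
      expect_true(decide_reportable(m_ext$major_count))
    }
  }
})

test_that("reportability requires at least one major key feature", {
  expect_true(decide_reportable(1L))
  expect_false(decide_reportable(0L)) # minors alone never suffice
  expect_equal(decide_reportable(c(2L, 0L)), c(TRUE, FALSE))
  expect_error(decide_reportable(-1L), "non-negative")
})

test_that("confidence tiers follow the recessive and X-linked rules", {
  ar <- "autosomal_recessive"
  xl <- "x_linked"
  expect_equal(classify_confidence(c("pathogenic", "pathogenic"), c("het", "het"), ar),
               "confident")
  expect_equal(classify_confidence(c("likely_pathogenic", "pathogenic"), c("het", "het"), ar),
               "confident")
  expect_equal(classify_confidence(c("pathogenic", "vus"), c("het", "het"), ar),
               "probable")
  expect_equal(classify_confidence(c("vus", "vus"), c("het", "het"), ar), "possible")
  # homozygote counts as two alleles of its class
  expect_equal(classify_confidence("vus", "hom", ar), "possible")
  expect_equal(classify_confidence("pathogenic", "hom", ar), "confident")
  # X-linked: single allele, no probable tier
  expect_equal(classify_confidence("pathogenic", "hemi", xl), "confident")
  expect_equal(classify_confidence("vus", "het", xl), "possible")
  # benign alleles invalidate the candidate
  expect_error(classify_confidence(c("pathogenic", "benign"), c("het", "het"), ar),
               "invalid")
  expect_error(classify_confidence("likely_benign", "hom", ar), "invalid")
  # incomplete recessive genotype is an error
  expect_error(classify_confidence("vus", "het", ar), "two allele")
})

test_that("upgrading any allele class never lowers the confidence tier", {
  tier_rank <- c(possible = 1, probable = 2, confident = 3)
  upgrade <- list(vus = "likely_pathogenic", likely_pathogenic = "pathogenic",
                  pathogenic = "pathogenic")
  withr::local_seed(13)
  for (rep in 1:300) {
    classes <- sample(c("pathogenic", "likely_pathogenic", "vus"), 2, replace = TRUE)
    base <- classify_confidence(classes, c("het", "het"), "autosomal_recessive")
    i <- sample(1:2, 1)
    classes2 <- classes
    classes2[i] <- upgrade[[classes[i]]]
    up <- classify_confidence(classes2, c("het", "het"), "autosomal_recessive")
    expect_gte(tier_rank[[up]], tier_rank[[base]])
  }
  # X-linked single allele
  for (cl in c("vus", "likely_pathogenic")) {
    base <- classify_confidence(cl, "het", "x_linked")
    up <- classify_confidence(upgrade[[cl]], "het", "x_linked")
    expect_gte(tier_rank[[up]], tier_rank[[base]])
  }
})

test_that("the pipeline recovers a planted compound het end to end", {
  kb <- panel_kb()
  obo <- mini_ontology()
  closures <- feature_closures(kb, obo)
  exons <- synthetic_exons()
  e1 <- exons[exons$gene == "ALMS1" & exons$exon_no == 2, ]
  e2 <- exons[exons$gene == "ALMS1" & exons$exon_no == 7, ]
  variants <- annotated_variants(tibble::tibble(
    chrom = e1$chrom, pos = c(e1$start + 5L, e2$start + 5L),
    ref = "A", alt = "T", gene = "ALMS1",
    consequence = "frameshift_variant", clinsig = "pathogenic",
    cohort_af = 1e-5
  ))
  genotypes <- tibble::tibble(
    variant_id = c(variants$variant_id, variants$variant_id),
    participant_id = c("P1", "P1", "MUM", "DAD"),
    zygosity = "het"
  )
  meta <- tibble::tibble(
    participant_id = c("P1", "DAD", "MUM"),
    proband = c(TRUE, FALSE, FALSE),
    solved_status = "unsolved",
    recruitment_category = c("Rod-cone dystrophy", "Relative", "Relative")
  )
  hpo <- tibble::tibble(
    participant_id = "P1",
    hpo_id = closures[["obesity"]][1] # major feature of the Alstrom gene
  )
  acmg <- tibble::tibble(
    participant_id = "P1", variant_id = variants$variant_id,
    acmg_class = c("pathogenic", "vus")
  )
  cohort <- make_cohort(variants, genotypes, ped = trio_ped, meta = meta,
                        hpo = hpo, acmg = acmg)
  dx <- run_pipeline(cohort, kb, obo)
  expect_equal(nrow(dx), 1L)
  expect_equal(dx$gene, "ALMS1")
  expect_equal(dx$phase, "in_trans")
  expect_true(dx$reportable)
  expect_equal(dx$confidence, "probable") # pathogenic + vus
  # allele-wise: v1 maternal, v2 paternal
  expect_setequal(strsplit(dx$segregation, "/")[[1]], c("maternal", "paternal"))
})

test_that("a cohort of only unaffected relatives yields an empty table", {
  kb <- panel_kb()
  obo <- mini_ontology()
  ped <- dplyr::mutate(trio_ped, affected = FALSE)
  meta <- tibble::tibble(
    participant_id = ped$participant_id, proband = FALSE,
    solved_status = "unsolved", recruitment_category = "x"
  )
  variants <- annotated_variants(tibble::tibble(
    chrom = "chr2", pos = 73000010L, ref = "A", alt = "T", gene = "ALMS1",
    consequence = "frameshift_variant", clinsig = "pathogenic", cohort_af = 1e-5
  ))
  genotypes <- tibble::tibble(
    variant_id = variants$variant_id, participant_id = "P1", zygosity = "hom"
  )
  cohort <- make_cohort(variants, genotypes, ped = ped, meta = meta)
  dx <- run_pipeline(cohort, kb, obo)
  expect_equal(nrow(dx), 0L)
})
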
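test_that("exclude_common applies strict boundaries and canonical filter", {
  v <- annotated_variants(tibble::tibble(
    chrom = "chr2", pos = 1:5, ref = "A", alt = "T", gene = "ALMS1",
    cohort_af = c(2.54e-05, 0.5, 0.002, 0.0019999, 1e-4),
    popdb_af = c(NA, 0.1, 1e-5, NA, 0.002),
    canonical = c(TRUE, TRUE, TRUE, TRUE, TRUE)
  ))
  out <- exclude_common(v)
  # novel (absent popdb AF) and rare retained; 0.5 excluded; exactly 0.002
  # excluded on either frequency (the cut-off itself is excluded)
  expect_equal(out$pos, c(1L, 4L))
  # non-canonical call is dropped regardless of rarity
  v2 <- dplyr::mutate(v[1, ], canonical = FALSE)
  expect_equal(nrow(exclude_common(v2)), 0L)
})

test_that("exclude_common is idempotent, monotone, and order-preserving", {
  v <- random_variants(300, seed = 11)
  t0 <- threshold_config()
  once <- exclude_common(v, t0)
  expect_identical(exclude_common(once, t0), once)
  expect_identical(once$variant_id, v$variant_id[v$variant_id %in% once$variant_id])
  # raising the threshold never removes a retained variant
  t_loose <- threshold_config(cohort_af_max = 0.01, popdb_af_max = 0.01)
  loose <- exclude_common(v, t_loose)
  expect_true(all(once$variant_id %in% loose$variant_id))
})

test_that("priority classes follow the three sublist definitions", {
  v <- annotated_variants(tibble::tibble(
    chrom = "chr2", pos = 1:4, ref = "A", alt = "T", gene = "ALMS1",
    consequence = c("frameshift_variant", "missense_variant",
                    "synonymous_variant", "missense_variant"),
    clinsig = c("pathogenic", "absent", "benign", "conflicting"),
    missense_class = c("absent", "deleterious", "absent", "tolerated")
  ))
  p <- classify_priority(v)
  # pathogenic frameshift carries both classes
  expect_true(p$clinvar_pathogenic[1] && p$high_impact[1])
  expect_false(p$deleterious_missense[1])
  # deleterious missense, no assertion
  expect_equal(
    c(p$clinvar_pathogenic[2], p$high_impact[2], p$deleterious_missense[2]),
    c(FALSE, FALSE, TRUE)
  )
  # benign synonymous: no classes
  expect_false(p$priority_any[3])
  # conflicting assertions are not ClinVar-pathogenic
  expect_false(p$clinvar_pathogenic[4])
  expect_false(p$deleterious_missense[4]) # tolerated missense
})

test_that("classify_priority agrees with a literal re-derivation on random variants", {
  v <- random_variants(1000, seed = 7)
  p <- classify_priority(v)
  hi_terms <- c(
    "stop_gained", "stop_lost", "start_lost", "splice_acceptor_variant",
    "splice_donor_variant", "frameshift_variant", "transcript_ablation",
    "transcript_amplification"
  )
  for (i in seq_len(nrow(v))) {
    terms <- strsplit(v$consequence[i], "&", fixed = TRUE)[[1]]
    expect_identical(p$clinvar_pathogenic[i],
                     v$clinsig[i] %in% c("pathogenic", "likely_pathogenic"))
    expect_identical(p$high_impact[i], any(terms %in% hi_terms))
    expect_identical(
      p$deleterious_missense[i],
      "missense_variant" %in% terms && v$missense_class[i] == "deleterious"
    )
  }
})

test_that("rarity filtering and classification commute", {
  v <- random_variants(400, seed = 23)
  t0 <- threshold_config()
  a <- classify_priority(exclude_common(v, t0))
  b <- exclude_common(classify_priority(v), t0)
  expect_equal(a, b)
})

# write a small annotated VCF for reader tests
write_test_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=RPANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  path
}

ann <- function(allele, gene, canonical = "YES", cons = "missense_variant",
                caf = "1e-05", paf = "0") {
  paste(allele, gene, "NM_000001.1", canonical, cons, caf, paf,
        "", "deleterious", "", "", "", "", "c.1A>T", "p.X1Y", sep = "|")
}

test_that("annotated VCF reader splits alleles and honours the gene set", {
  path <- write_test_vcf(c(
    paste("chr2", "100", ".", "A", "T", ".", "PASS",
          paste0("RPANN=", ann("T", "ALMS1")), "GT", "0/1", "0/0", sep = "\t"),
    # tri-allelic record: one entry per alt allele
    paste("chr2", "200", ".", "G", "A,C", ".", "PASS",
          paste0("RPANN=", ann("A", "ALMS1"), ",", ann("C", "ALMS1")),
          "GT", "1/2", "0/1", sep = "\t"),
    # record in a non-target gene
    paste("chr7", "300", ".", "C", "G", ".", "PASS",
          paste0("RPANN=", ann("G", "OTHER")), "GT", "0/1", "0/0", sep = "\t"),
    # non-canonical transcript call
    paste("chr2", "400", ".", "C", "G", ".", "PASS",
          paste0("RPANN=", ann("G", "ALMS1", canonical = "")), "GT", "1/1", "0/0", sep = "\t")
  ))
  v <- read_annotated_vcf(path, gene_set = c("ALMS1", "CEP290"))
  expect_equal(nrow(v), 3L) # 1 biallelic + 2 from the tri-allelic split
  expect_setequal(v$alt[v$pos == 200], c("A", "C"))
  expect_true(all(v$gene == "ALMS1"))
  expect_true(all(v$canonical))

  gt <- read_vcf_genotypes(path)
  expect_equal(
    gt$zygosity[gt$variant_id == "chr2:100:A:T" & gt$participant_id == "S1"], "het"
  )
  # 1/2 genotype: het for each alt allele
  expect_setequal(
    gt$variant_id[gt$participant_id == "S1" & grepl(":200:", gt$variant_id)],
    c("chr2:200:G:A", "chr2:200:G:C")
  )
  expect_equal(gt$zygosity[gt$variant_id == "chr2:400:C:G"], "hom")
  expect_setequal(read_vcf_samples(path), c("S1", "S2"))
})

test_that("reader errors on a VCF without the annotation field", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"), collapse = "\t"),
    paste("chr1", "1", ".", "A", "T", ".", ".", "DP=3", sep = "\t")
  ), path)
  expect_error(read_annotated_vcf(path, "ALMS1"), "RPANN")
})
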
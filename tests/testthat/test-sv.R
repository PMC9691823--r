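test_that("identical calls cluster together; types stay stratified", {
  calls <- sv_calls(tibble::tibble(
    participant_id = c("P1", "P2", "P3"),
    chrom = "chr2",
    start = c(1000L, 1000L, 1000L),
    end = c(5000L, 5000L, 5000L),
    svtype = c("DEL", "DEL", "DUP")
  ))
  db <- build_sv_database(calls)
  expect_equal(nrow(db$clusters), 2L) # DEL cluster + DUP cluster
  del <- dplyr::filter(db$clusters, svtype == "DEL")
  expect_equal(del$n_participants, 2L)
})

test_that("occurrence counts distinct participants, not calls", {
  calls <- sv_calls(tibble::tibble(
    participant_id = c("P1", "P1", "P2"), # P1 called twice (two callers)
    chrom = "chr2", start = 1000L, end = 5000L, svtype = "DEL",
    caller = c("manta", "canvas", "manta")
  ))
  db <- build_sv_database(calls)
  expect_equal(db$clusters$n_calls, 3L)
  expect_equal(db$clusters$n_participants, 2L)
})

test_that("clustering equals the brute-force all-pairs oracle", {
  for (case in list(c(n = 200, seed = 1), c(n = 100, seed = 2), c(n = 50, seed = 3))) {
    calls <- random_sv_calls(case[["n"]], seed = case[["seed"]])
    db <- build_sv_database(calls)
    oracle <- brute_sv_clusters(calls)
    expect_true(same_partition(db$members$cluster_id, oracle))
    # partition conserves calls
    expect_equal(sum(db$clusters$n_calls), nrow(calls))
  }
})

test_that("insertion calls cluster by start-position window", {
  calls <- sv_calls(tibble::tibble(
    participant_id = c("P1", "P2", "P3"),
    chrom = "chr1", svtype = "INS",
    start = c(1000L, 1040L, 1200L), end = c(1000L, 1040L, 1200L)
  ))
  db <- build_sv_database(calls, ins_window = 50L)
  expect_equal(nrow(db$clusters), 2L) # 1000+1040 merge; 1200 separate
})

test_that("rare_svs applies the strict occurrence cut-off", {
  calls <- sv_calls(dplyr::bind_rows(
    tibble::tibble(participant_id = paste0("A", 1:10), chrom = "chr1",
                   start = 100L, end = 900L, svtype = "DEL"),
    tibble::tibble(participant_id = paste0("B", 1:9), chrom = "chr1",
                   start = 5000L, end = 9000L, svtype = "DEL")
  ))
  db <- build_sv_database(calls)
  rare <- rare_svs(db, max_count = 10L)
  expect_equal(nrow(rare), 1L) # count 10 excluded, count 9 retained
  expect_equal(rare$n_participants, 9L)
  # monotone: tightening the cut-off never adds a cluster
  expect_true(all(rare_svs(db, 5L)$cluster_id %in% rare$cluster_id))
  empty <- build_sv_database(calls[0, ])
  expect_equal(nrow(rare_svs(empty)), 0L)
})

test_that("coding overlap uses inclusive 1-based boundaries", {
  exons <- tibble::tibble(
    gene = "G1", chrom = "chr1", start = c(1000L, 3000L), end = c(1200L, 3200L)
  )
  svs <- tibble::tibble(
    chrom = "chr1",
    start = c(900L, 1500L, 500L, 3200L),
    end = c(3100L, 2500L, 1000L, 3500L)
  )
  out <- overlaps_coding(svs, exons)
  # spans both exons; wholly intronic; ends exactly at an exon first base;
  # starts exactly at an exon last base
  expect_equal(out$overlaps_coding, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$genes_hit[1], "G1")
})

test_that("BED exon intervals are converted to 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t1200\tG1", path) # BED half-open [999, 1200)
  exons <- read_exon_bed(path)
  expect_equal(exons$start, 1000L)
  expect_equal(exons$end, 1200L)
  expect_equal(exons$gene, "G1")
})

test_that("read support is a strict majority-fraction screen", {
  svs <- sv_calls(tibble::tibble(
    participant_id = "P1", chrom = "chr1", start = 1L, end = 10L,
    svtype = "DEL", read_fraction = c(0.31, 0.30, NA)
  ))
  expect_equal(supported(svs), c(TRUE, FALSE, FALSE))
})

test_that("SV analysis gate requires a heterozygous first hit on the right sublists", {
  pv <- tibble::tibble(
    participant_id = c("P1", "P2", "P3", "P4"),
    zygosity = c("het", "het", "hom", "het"),
    clinvar_pathogenic = c(TRUE, FALSE, TRUE, FALSE),
    high_impact = c(TRUE, FALSE, FALSE, TRUE),
    deleterious_missense = c(FALSE, TRUE, FALSE, FALSE)
  )
  gate <- sv_gate(pv)
  expect_true(gate$sv_gate[gate$participant_id == "P1"]) # het pathogenic
  expect_false(gate$sv_gate[gate$participant_id == "P2"]) # deleterious-missense only
  expect_false(gate$sv_gate[gate$participant_id == "P3"]) # hom only: complete genotype
  expect_true(gate$sv_gate[gate$participant_id == "P4"]) # het high impact
})

test_that("SV VCF reader consumes SVTYPE/END and skips breakends", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=RPRF,Number=1,Type=Float,Description=\"rf\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "P1", "P2"), collapse = "\t"),
    paste("chr2", "1000", ".", "N", "<DEL>", ".", "PASS",
          "SVTYPE=DEL;END=5000;RPRF=0.45", "GT", "0/1", "0/0", sep = "\t"),
    paste("chr2", "9000", ".", "N", "N[chr5:100[", ".", "PASS",
          "SVTYPE=BND", "GT", "0/1", "0/0", sep = "\t")
  ), path)
  calls <- read_sv_vcf(path)
  expect_equal(nrow(calls), 1L) # BND skipped
  expect_equal(calls$end, 5000L)
  expect_equal(calls$read_fraction, 0.45)
  expect_equal(calls$participant_id, "P1")
})

test_that("SV table TSV round-trips through write/read", {
  calls <- random_sv_calls(20, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(calls, -sv_id), path)
  back <- read_sv_table(path)
  expect_equal(dplyr::select(back, -sv_id), dplyr::select(calls, -sv_id))
})
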
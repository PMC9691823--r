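# Cohort structural-variant aggregation and rarity screening.

SV_TYPES <- c("DEL", "DUP", "INV", "INS", "CPX")

#' Construct and validate an SV call table
#'
#' @param df Data frame with columns `participant_id`, `chrom`, `start`,
#'   `end` (1-based inclusive; insertions have `end == start`), `svtype`
#'   (`DEL`, `DUP`, `INV`, `INS`, `CPX`), and optionally `caller`,
#'   `read_fraction` (in \[0, 1\], `NA` = absent), `genotype`
#'   (`het`/`hom`/`unknown`).
#' @return Validated tibble with an `sv_id` column prepended.
#' @export
sv_calls <- function(df) {
  df <- as_tibble(df)
  need <- c("participant_id", "chrom", "start", "end", "svtype")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop_validation("missing SV columns: ", paste(miss, collapse = ", "))
  if (!"caller" %in% names(df)) df$caller <- NA_character_
  if (!"read_fraction" %in% names(df)) df$read_fraction <- NA_real_
  if (!"genotype" %in% names(df)) df$genotype <- "unknown"
  if (any(!df$svtype %in% SV_TYPES)) {
    stop_validation("svtype must be one of ", paste(SV_TYPES, collapse = ", "))
  }
  if (any(df$start > df$end)) stop_validation("SV start must be <= end")
  rf <- df$read_fraction
  if (any(!is.na(rf) & (rf < 0 | rf > 1))) stop_validation("read_fraction must be in [0, 1]")
  if (any(!df$genotype %in% c("het", "hom", "unknown"))) {
    stop_validation("SV genotype must be het, hom or unknown")
  }
  df$sv_id <- paste(df$participant_id, df$chrom, df$start, df$end, df$svtype, sep = ":")
  select(df, "sv_id", dplyr::everything())
}

#' Read SV calls from a 6+ column TSV
#'
#' Expected columns: `participant_id`, `chrom`, `start`, `end`, `svtype`,
#' `caller`, and optionally `read_fraction`, `genotype`. Lines starting
#' with `#` are ignored.
#'
#' @param path TSV path.
#' @return Validated [sv_calls()] tibble.
#' @export
read_sv_table <- function(path) {
  check_file_exists(path)
  sv_calls(readr::read_tsv(path, comment = "#", show_col_types = FALSE))
}

#' Read SV calls from a VCF with SVTYPE/END INFO keys
#'
#' Breakend (`BND`) records are skipped with a logged count. The sample
#' whose genotype carries the alt allele is taken as the call's
#' participant; one call row is emitted per carrier sample. Supporting-read
#' fraction is read from a `RPRF` INFO key when present.
#'
#' @param path VCF path.
#' @return Validated [sv_calls()] tibble.
#' @export
read_sv_vcf <- function(path) {
  check_file_exists(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  svtype <- vcfR::extract.info(vcf, element = "SVTYPE")
  endpos <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "END")))
  rf <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "RPRF")))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  n_bnd <- sum(svtype == "BND", na.rm = TRUE)
  if (n_bnd > 0L) log_stage("read_sv_vcf", skipped_bnd = n_bnd)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    if (is.na(svtype[i]) || svtype[i] == "BND") next
    start <- as.integer(fix[i, "POS"])
    end <- if (!is.na(endpos[i])) endpos[i] else start
    for (s in colnames(gt)) {
      g <- gt[i, s]
      if (is.na(g)) next
      alleles <- stringr::str_split_1(g, "[/|]")
      dose <- sum(alleles == "1")
      if (dose == 0L) next
      rows[[length(rows) + 1L]] <- tibble(
        participant_id = s, chrom = fix[i, "CHROM"],
        start = start, end = max(start, end),
        svtype = svtype[i], caller = NA_character_,
        read_fraction = rf[i],
        genotype = if (dose >= 2L || length(alleles) == 1L) "hom" else "het"
      )
    }
  }
  if (length(rows)) sv_calls(bind_rows(rows)) else {
    sv_calls(tibble(
      participant_id = character(), chrom = character(),
      start = integer(), end = integer(), svtype = character()
    ))
  }
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1)))
}

#' Aggregate SV calls into a cohort database
#'
#' Single-linkage clustering of calls of identical type on the same
#' chromosome: deletions, duplications, inversions and complex events
#' cluster when their pairwise reciprocal overlap meets
#' `reciprocal_overlap_min`; insertions cluster when their start positions
#' lie within `ins_window` bp. Each cluster's occurrence count is the
#' number of distinct participants among its member calls.
#'
#' @param calls An [sv_calls()] tibble.
#' @param reciprocal_overlap_min Minimum reciprocal overlap, default 0.8.
#' @param ins_window Insertion start-distance window in bp, default 50.
#' @return An object of class `sv_database`: list with `clusters` (tibble
#'   `cluster_id`, `chrom`, `svtype`, `start`, `end` of the representative
#'   spanning interval, `n_calls`, `n_participants`) and `members` (the
#'   input calls plus their `cluster_id`).
#' @export
build_sv_database <- function(calls, reciprocal_overlap_min = 0.8, ins_window = 50L) {
  calls <- sv_calls(calls)
  if (nrow(calls) == 0L) {
    return(structure(
      list(
        clusters = tibble(
          cluster_id = integer(), chrom = character(), svtype = character(),
          start = integer(), end = integer(), n_calls = integer(), n_participants = integer()
        ),
        members = mutate(calls, cluster_id = integer())
      ),
      class = "sv_database"
    ))
  }
  calls$.row <- seq_len(nrow(calls))
  groups <- split(calls, paste(calls$chrom, calls$svtype, sep = "\r"))
  membership <- integer(nrow(calls))
  next_id <- 0L
  for (grp in groups) {
    n <- nrow(grp)
    if (n == 1L) {
      next_id <- next_id + 1L
      membership[grp$.row] <- next_id
      next
    }
    is_ins <- grp$svtype[1] == "INS"
    if (is_ins) {
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(grp$start - as.integer(ins_window), grp$start + as.integer(ins_window)),
        IRanges::IRanges(grp$start, grp$start)
      )
      from <- S4Vectors::queryHits(hits)
      to <- S4Vectors::subjectHits(hits)
      keep <- from < to
      from <- from[keep]; to <- to[keep]
    } else {
      ir <- IRanges::IRanges(grp$start, grp$end)
      hits <- IRanges::findOverlaps(ir, ir)
      from <- S4Vectors::queryHits(hits)
      to <- S4Vectors::subjectHits(hits)
      keep <- from < to
      from <- from[keep]; to <- to[keep]
      if (length(from) > 0L) {
        ro <- reciprocal_overlap(grp$start[from], grp$end[from], grp$start[to], grp$end[to])
        ok <- ro >= reciprocal_overlap_min
        from <- from[ok]; to <- to[ok]
      }
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n))
    )
    comp <- igraph::components(g)$membership
    membership[grp$.row] <- next_id + as.integer(comp)
    next_id <- next_id + max(comp)
  }
  members <- calls %>%
    mutate(cluster_id = membership) %>%
    select(-".row")
  clusters <- members %>%
    group_by(.data$cluster_id) %>%
    summarise(
      chrom = first(.data$chrom),
      svtype = first(.data$svtype),
      start = min(.data$start),
      end = max(.data$end),
      n_calls = n(),
      n_participants = n_distinct(.data$participant_id),
      .groups = "drop"
    ) %>%
    arrange(.data$cluster_id)
  log_stage("build_sv_database", n_calls = nrow(members), n_clusters = nrow(clusters))
  structure(list(clusters = clusters, members = members), class = "sv_database")
}

#' @export
print.sv_database <- function(x, ...) {
  cat(
    "<sv_database> ", nrow(x$members), " calls in ",
    nrow(x$clusters), " clusters\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sv_database <- function(x, ...) x$clusters

#' @exportS3Method generics::glance
glance.sv_database <- function(x, ...) {
  tibble(
    n_calls = nrow(x$members),
    n_clusters = nrow(x$clusters),
    n_participants = n_distinct(x$members$participant_id),
    max_cluster_count = if (nrow(x$clusters)) max(x$clusters$n_participants) else NA_integer_
  )
}

#' Rare SV clusters
#'
#' Clusters occurring in fewer than `max_count` distinct participants;
#' clusters at or above the cut-off are considered common and excluded.
#'
#' @param db An [sv_database][build_sv_database].
#' @param max_count Exclusive occurrence cut-off (default 10).
#' @return The rare rows of `db$clusters`.
#' @export
rare_svs <- function(db, max_count = 10L) {
  stopifnot(inherits(db, "sv_database"))
  out <- filter(db$clusters, .data$n_participants < max_count)
  log_stage("rare_svs", n_in = nrow(db$clusters), n_out = nrow(out))
  out
}

#' Read coding-exon intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read (via `rtracklayer`). The BED name
#' column must carry the gene symbol.
#'
#' @param path BED path.
#' @return Tibble with `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_exon_bed <- function(path) {
  check_file_exists(path)
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    gene = as.character(gr$name),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr)
  )
}

#' Test SV intervals for coding overlap
#'
#' An SV overlaps coding sequence when its (1-based inclusive) interval
#' intersects at least one coding exon of a target gene; touching an exon
#' boundary base counts.
#'
#' @param svs Data frame of SV intervals (`chrom`, `start`, `end`; e.g.
#'   clusters from [rare_svs()] or calls from [sv_calls()]).
#' @param exons Exon table from [read_exon_bed()] (or equivalent, 1-based
#'   inclusive, with a `gene` column).
#' @return `svs` with logical `overlaps_coding` and a `genes_hit`
#'   comma-separated column appended.
#' @export
overlaps_coding <- function(svs, exons) {
  svs <- as_tibble(svs)
  exons <- as_tibble(exons)
  if (nrow(svs) == 0L) {
    return(mutate(svs, overlaps_coding = logical(), genes_hit = character()))
  }
  hit_genes <- vector("list", nrow(svs))
  for (chr in unique(svs$chrom)) {
    si <- which(svs$chrom == chr)
    ei <- which(exons$chrom == chr)
    if (length(ei) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(svs$start[si], svs$end[si]),
      IRanges::IRanges(exons$start[ei], exons$end[ei])
    )
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    for (k in seq_along(q)) {
      idx <- si[q[k]]
      hit_genes[[idx]] <- c(hit_genes[[idx]], exons$gene[ei[s[k]]])
    }
  }
  svs$overlaps_coding <- lengths(hit_genes) > 0L
  svs$genes_hit <- purrr::map_chr(
    hit_genes, ~ if (length(.x)) paste(sort(unique(.x)), collapse = ",") else NA_character_
  )
  svs
}

#' Read-support screen for SV calls
#'
#' An SV is considered potentially causative when it is supported by a
#' strict majority fraction of reads above the threshold (default > 0.30).
#' Calls with absent read fraction fail the screen (conservative), with a
#' logged count.
#'
#' @param svs An [sv_calls()] tibble (needs a `read_fraction` column).
#' @param thresholds A [threshold_config()].
#' @return Logical vector, one element per row of `svs`.
#' @export
supported <- function(svs, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  rf <- svs$read_fraction
  n_absent <- sum(is.na(rf))
  if (n_absent > 0L) log_stage("supported", absent_read_fraction = n_absent)
  !is.na(rf) & rf > thresholds$sv_read_fraction_min
}

#' Gate participants into the SV analysis
#'
#' SV analysis is only pursued for participants who already carry at least
#' one heterozygous variant in a target gene on the ClinVar-pathogenic or
#' high-impact sublists (a plausible first hit of a biallelic genotype).
#' Participants whose heterozygous variants are only deleterious missenses
#' are gated out, as are participants whose only prioritised variant is
#' homozygous (already a complete genotype).
#'
#' @param participant_variants Tibble joining genotypes to prioritised
#'   variants: columns `participant_id`, `zygosity`, and the
#'   [classify_priority()] logical columns.
#' @return Tibble `participant_id`, `sv_gate` (logical), one row per
#'   participant present in the input.
#' @export
sv_gate <- function(participant_variants) {
  pv <- as_tibble(participant_variants)
  need <- c("participant_id", "zygosity", "clinvar_pathogenic", "high_impact")
  miss <- setdiff(need, names(pv))
  if (length(miss) > 0L) stop_validation("missing columns: ", paste(miss, collapse = ", "))
  pv %>%
    group_by(.data$participant_id) %>%
    summarise(
      sv_gate = any(.data$zygosity == "het" & (.data$clinvar_pathogenic | .data$high_impact)),
      .groups = "drop"
    )
}

#' Write an SV cluster table to TSV
#'
#' @param db An [sv_database][build_sv_database] or a cluster tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_clusters <- function(db, path) {
  clusters <- if (inherits(db, "sv_database")) db$clusters else as_tibble(db)
  readr::write_tsv(clusters, path)
  invisible(path)
}
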
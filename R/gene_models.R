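#' Synthetic gene models for the packaged ciliopathy panel
#'
#' A compact synthetic exon layout for the nine panel genes, used by the
#' cohort generator and tests: each gene has 10 exons of 200 bp separated
#' by 5 kb introns, placed on its real chromosome but at synthetic
#' coordinates (these are not the real gene structures; the pipeline never
#' depends on real coordinates, only on consistent intervals between the
#' variant, SV and exon files).
#'
#' @return Tibble with `gene`, `chrom`, `tx_start`, `n_exons`, `exon_len`,
#'   `intron_len`.
#' @export
synthetic_gene_models <- function() {
  tibble(
    gene = c("BBS1", "BBS10", "ALMS1", "OFD1", "DYNC2H1", "WDR34", "NPHP1", "TMEM67", "CEP290"),
    chrom = c("chr11", "chr12", "chr2", "chrX", "chr11", "chr9", "chr2", "chr8", "chr12"),
    tx_start = c(66e6, 76e6, 73e6, 13e6, 103e6, 128e6, 110e6, 93e6, 88e6),
    n_exons = 10L,
    exon_len = 200L,
    intron_len = 5000L
  )
}

#' Synthetic exon intervals for the packaged panel
#'
#' Expands [synthetic_gene_models()] into 1-based inclusive exon intervals.
#'
#' @return Tibble `gene`, `chrom`, `start`, `end`, `exon_no`.
#' @export
synthetic_exons <- function() {
  synthetic_gene_models() %>%
    mutate(exons = purrr::pmap(
      list(.data$gene, .data$chrom, .data$tx_start, .data$n_exons, .data$exon_len, .data$intron_len),
      function(gene, chrom, tx_start, n_exons, exon_len, intron_len) {
        starts <- tx_start + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
        tibble(
          gene = gene, chrom = chrom,
          start = as.integer(starts), end = as.integer(starts + exon_len - 1L),
          exon_no = seq_len(n_exons)
        )
      }
    )) %>%
    pull(.data$exons) %>%
    bind_rows()
}

#' Write exon intervals as a BED file
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param exons Tibble `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_exon_bed <- function(exons, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", exons$chrom, exons$start - 1L, exons$end, exons$gene)
  readr::write_lines(lines, path)
  invisible(path)
}
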
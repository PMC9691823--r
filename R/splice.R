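#' Screen rare variants for predicted splice effects
#'
#' Retains variants whose maximum splice delta score (acceptor gain,
#' acceptor loss, donor gain, donor loss) is strictly above the threshold
#' (default > 0.5, the predictor's recommended cut-off), excluding variants
#' already asserted benign (and, by conservative default, likely benign) in
#' the clinical-significance field. Variants with no delta scores cannot be
#' assessed and are not retained (logged count). Input is expected to be
#' rarity-filtered already; output is always a subset of input with row
#' order preserved.
#'
#' @param variants Annotated-variant tibble (see [annotated_variants()]).
#' @param thresholds A [threshold_config()]; `splice_delta_min` sets the
#'   cut-off and `exclude_likely_benign` switches between conservative
#'   (benign + likely benign excluded, default) and benign-only exclusion.
#' @return The retained rows of `variants`, with a `max_splice_delta`
#'   column appended.
#' @export
#' @examples
#' v <- annotated_variants(tibble::tibble(
#'   chrom = "chr12", pos = c(100L, 200L), ref = "G", alt = "T",
#'   gene = "CEP290", ds_ag = c(0.64, 0.2)
#' ))
#' splice_candidates(v)
splice_candidates <- function(variants, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  variants <- as_tibble(variants)
  deltas <- as.matrix(variants[, c("ds_ag", "ds_al", "ds_dg", "ds_dl")])
  max_delta <- apply(deltas, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  n_absent <- sum(is.na(max_delta))
  if (n_absent > 0L) log_stage("splice_candidates", absent_deltas = n_absent)
  benign_set <- if (thresholds$exclude_likely_benign) {
    c("benign", "likely_benign")
  } else {
    "benign"
  }
  keep <- !is.na(max_delta) &
    max_delta > thresholds$splice_delta_min &
    !variants$clinsig %in% benign_set
  out <- variants[keep, , drop = FALSE]
  out$max_splice_delta <- max_delta[keep]
  log_stage("splice_candidates", n_in = nrow(variants), n_out = nrow(out))
  out
}
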
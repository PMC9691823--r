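#' Disease model for allele-frequency threshold derivation
#'
#' Bundles the epidemiological parameters from which the maximum credible
#' population allele frequency of a causal variant is derived. The defaults
#' are the packaged ciliopathy panel model: biallelic inheritance,
#' prevalence 1 in 500, allelic heterogeneity 0.1, genetic heterogeneity
#' 0.2, penetrance 1, confidence 0.95, reference population of 121,412
#' individuals.
#'
#' @param prevalence Disease prevalence as a proportion of individuals,
#'   in (0, 1).
#' @param allelic_heterogeneity Maximum proportion of disease-causing
#'   alleles accounted for by any single allele, in (0, 1].
#' @param genetic_heterogeneity Maximum proportion of cases attributable to
#'   the gene under consideration, in (0, 1].
#' @param penetrance Penetrance of the genotype, in (0, 1].
#' @param mode `"biallelic"` or `"monoallelic"`.
#' @param confidence Confidence level used for the allele-count adjustment,
#'   in (0, 1).
#' @param reference_population_size Number of individuals in the reference
#'   population database.
#' @return An object of class `disease_model` (a validated named list).
#' @export
#' @examples
#' max_credible_af(disease_model()) # ciliopathy default: 0.002
disease_model <- function(prevalence = 1 / 500,
                          allelic_heterogeneity = 0.1,
                          genetic_heterogeneity = 0.2,
                          penetrance = 1,
                          mode = c("biallelic", "monoallelic"),
                          confidence = 0.95,
                          reference_population_size = 121412) {
  mode <- match.arg(mode)
  if (!is_proportion(prevalence)) {
    stop_validation("prevalence must be in (0, 1)")
  }
  if (!is_proportion(allelic_heterogeneity, hi_open = FALSE)) {
    stop_validation("allelic_heterogeneity must be in (0, 1]")
  }
  if (!is_proportion(genetic_heterogeneity, hi_open = FALSE)) {
    stop_validation("genetic_heterogeneity must be in (0, 1]")
  }
  if (!is_proportion(penetrance, hi_open = FALSE)) {
    stop_validation("penetrance must be in (0, 1]")
  }
  if (!is_proportion(confidence)) {
    stop_validation("confidence must be in (0, 1)")
  }
  if (!is.numeric(reference_population_size) || length(reference_population_size) != 1L ||
      !is.finite(reference_population_size) || reference_population_size <= 0) {
    stop_validation("reference_population_size must be a positive count")
  }
  structure(
    list(
      prevalence = prevalence,
      allelic_heterogeneity = allelic_heterogeneity,
      genetic_heterogeneity = genetic_heterogeneity,
      penetrance = penetrance,
      mode = mode,
      confidence = confidence,
      reference_population_size = reference_population_size
    ),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  cat(
    "<disease_model> ", x$mode,
    ", prevalence ", signif(x$prevalence, 4),
    ", allelic het ", x$allelic_heterogeneity,
    ", genetic het ", x$genetic_heterogeneity,
    ", penetrance ", x$penetrance, "\n",
    sep = ""
  )
  invisible(x)
}

#' Maximum credible population allele frequency
#'
#' Closed-form maximum credible population allele frequency for a causal
#' variant under the given disease model. For a biallelic (recessive)
#' architecture the disease genotype frequency is at most
#' `prevalence * genetic_heterogeneity / penetrance`; under Hardy-Weinberg
#' the causal allele frequency is its square root, and the most frequent
#' single allele accounts for at most `allelic_heterogeneity` of that:
#'
#' \deqn{af_{max} = \sqrt{prev \times g / pen} \times a}
#'
#' For a monoallelic (dominant) architecture the allele frequency is half
#' the carrier frequency:
#'
#' \deqn{af_{max} = prev \times g \times a / (2 \, pen)}
#'
#' With the packaged ciliopathy model (prevalence 1/500, allelic
#' heterogeneity 0.1, genetic heterogeneity 0.2, penetrance 1, biallelic)
#' this yields exactly 0.002, the rarity cut-off used throughout the
#' pipeline.
#'
#' @param model A [disease_model()].
#' @return A single allele frequency.
#' @export
max_credible_af <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  af <- switch(model$mode,
    biallelic = sqrt(model$prevalence * model$genetic_heterogeneity / model$penetrance) *
      model$allelic_heterogeneity,
    monoallelic = model$prevalence * model$genetic_heterogeneity *
      model$allelic_heterogeneity / (2 * model$penetrance)
  )
  if (!is.finite(af) || af < 0) stop_validation("non-finite allele frequency")
  af
}

#' Maximum tolerated allele count in a reference population
#'
#' Confidence-adjusted complement of [max_credible_af()]: the largest allele
#' count `c` that is still consistent with the maximum credible allele
#' frequency, i.e. the largest integer `c` such that observing at least `c`
#' alleles among `2 * n_individuals` chromosomes has probability greater
#' than `1 - confidence` under a Poisson model with rate
#' `2 * n_individuals * af_max`.
#'
#' The pipeline's default filters apply the allele-frequency cut-off
#' directly; this count is provided for workflows that filter a reference
#' database by observed allele counts instead.
#'
#' @param af_max Maximum credible allele frequency (>= 0).
#' @param n_individuals Number of individuals in the reference population.
#' @param confidence Confidence level in (0, 1).
#' @return A single non-negative integer allele count.
#' @export
max_tolerated_ac <- function(af_max, n_individuals, confidence = 0.95) {
  if (!is.numeric(af_max) || length(af_max) != 1L || !is.finite(af_max) || af_max < 0) {
    stop_validation("af_max must be a single non-negative number")
  }
  if (!is.numeric(n_individuals) || n_individuals <= 0) {
    stop_validation("n_individuals must be positive")
  }
  if (!is_proportion(confidence)) stop_validation("confidence must be in (0, 1)")
  if (af_max == 0) return(0L)
  lambda <- 2 * n_individuals * af_max
  alpha <- 1 - confidence
  # want largest c with P(X >= c) > alpha, i.e. ppois(c - 1, lambda) < 1 - alpha;
  # qpois gives the neighbourhood, then settle the boundary exactly
  c0 <- qpois(confidence, lambda)
  cand <- max(0L, c0 - 2L):(c0 + 2L)
  ok <- ppois(cand - 1, lambda) < 1 - alpha # == P(X >= cand) > alpha
  as.integer(max(cand[ok]))
}
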
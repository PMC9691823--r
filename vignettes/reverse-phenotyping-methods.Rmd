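---
title: "Methods: a reverse-phenotyping diagnostic workflow for ciliopathy genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reverse-phenotyping diagnostic workflow for ciliopathy genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revphen)
options(revphen.quiet = TRUE)
```

## The problem

Large sequenced rare-disease cohorts are usually analysed *forwards*:
clinician-entered phenotype terms select a virtual gene panel, and only
variants on that panel are prioritised. When phenotype entry is sparse or
wrong — a frequent failure mode, with many participants carrying only one
or two Human Phenotype Ontology (HPO) terms — the correct gene is never
examined and the diagnosis is missed. Multisystemic ciliopathies
(Bardet-Biedl, Alström, Joubert, Meckel-Gruber, orofaciodigital and Jeune
syndromes, and nephronophthisis) are especially exposed: they are
genetically heterogeneous, clinically overlapping, and frequently
recruited under single-system categories.

`revphen` implements the complementary *reverse phenotyping* strategy for
a curated panel of nine ciliopathy genes (*BBS1, BBS10, ALMS1, OFD1,
DYNC2H1, WDR34, NPHP1, TMEM67, CEP290*; all autosomal recessive except
X-linked *OFD1*). It starts from genotypes — every rare, plausibly
damaging variant in the panel — assembles inheritance-consistent candidate
genotypes, and only then asks whether each carrier's recorded clinical
features are compatible with the implicated gene.

## Pipeline stages and their parameters

### Rarity threshold: maximum credible population allele frequency

The rarity cut-off is not arbitrary: it is the *maximum credible
population allele frequency* for a causal allele under a disease model.
For a biallelic architecture with prevalence $P$, genetic heterogeneity
$g$ (share of cases attributable to one gene), allelic heterogeneity $a$
(share of the gene's disease alleles contributed by its most frequent
allele) and penetrance $f$,

$$ \mathrm{af}_{max} = \sqrt{P \cdot g / f}\; \cdot a, $$

and for a monoallelic architecture $\mathrm{af}_{max} = P g a / (2f)$.
The packaged ciliopathy model (`disease_model()`: prevalence 1/500,
$a = 0.1$, $g = 0.2$, $f = 1$, biallelic) gives exactly `r
max_credible_af(disease_model())`, the default for both the within-cohort
and the population-database frequency filters. `max_tolerated_ac()`
additionally provides the confidence-adjusted maximum tolerated allele
count (the largest count whose Poisson tail probability among $2N$
chromosomes still exceeds $1-\text{confidence}$); the pipeline's default
filters apply the frequency cut-off directly, which matches how the
workflow's filters are specified, and the allele-count form is offered
for count-based reference databases.

**Boundary semantics.** All retention boundaries are strict and fixed
package-wide: a variant at exactly allele frequency 0.002 is *excluded*
(the workflow's filtering step states the exclusion as "≥ 0.002"; a later
step paraphrases the complement as "≤ 0.002", an internal inconsistency we
resolve in favour of the exclusion wording), a splice delta of exactly 0.5
is excluded, an SV cluster seen in exactly 10 participants is excluded,
and a supporting-read fraction of exactly 0.30 fails the support screen.

### Priority sublists

After rarity and canonical-transcript filtering, variants enter three
independent, possibly overlapping sublists: clinical-assertion pathogenic
or likely pathogenic ("conflicting" assertions do not qualify); the eight
high-impact consequence terms (stop gained/lost, start lost, splice
acceptor/donor, frameshift, transcript ablation/amplification); and
missense predicted deleterious. Classification is frequency-independent,
so filtering and classification commute (tested).

### Structural-variant rarity screen

Cohort SV calls are aggregated into a database by single-linkage
clustering of same-type, same-chromosome calls with reciprocal overlap
≥ 0.8 (insertions: start positions within 50 bp); a cluster's occurrence
count is its number of *distinct participants*. The aggregation rule is
not part of the published workflow description, so these defaults follow
common SV-database practice and are exposed in `threshold_config()`;
counting participants rather than calls was chosen because two callers
frequently emit the same event for one genome. Clusters in ≥ 10
participants are excluded as common; remaining rare SVs are kept if they
intersect a coding exon of a panel gene (1-based inclusive intervals; BED
input converted from half-open on read) and are supported by > 30% of
reads (absent support fails conservatively, with a logged count).
Breakend records are skipped with a logged count; complex events are
representable as `CPX` intervals, but resolving their internal
architecture is out of scope (in the motivating study that required manual
read-level inspection).

SV analysis is *gated*: it is only run for participants who already carry
a heterozygous variant on the pathogenic or high-impact sublists — a
plausible first hit looking for its second — while participants whose only
heterozygous hits are deleterious missenses are excluded from SV follow-up
(they are numerous and would almost all be classified as uncertain).

### Splice screen

Rare variants with any of the four splice delta scores (acceptor/donor ×
gain/loss) strictly above 0.5 are retained, excluding variants already
asserted benign. The workflow's description excludes only "benign";
`revphen` additionally drops likely-benign by default (conservative), with
`threshold_config(exclude_likely_benign = FALSE)` restoring the literal
behaviour. Delta scores are consumed from annotation, never computed.

### Candidate assembly, segregation, phenotype match, confidence

Eligible participants are affected and not already solved (fully or
partially) with an alternative gene. For recessive genes a candidate is a
homozygous prioritised allele or a pair of heterozygous prioritised
alleles (SV and splice candidates count as alleles); all pairs are
emitted, and when more than one candidate exists for a (participant,
gene), the one with the highest summed ACMG severity (P/LP = 2, VUS = 1;
resolved phase breaks ties) is reported — a single reported candidate per
participant-gene pair keeps the output one row per putative diagnosis.
For X-linked genes a single heterozygous (female) or hemizygous (male)
allele suffices; the rule is applied to any `x_linked` gene in the
knowledge base, generalising the panel's single X-linked exemplar.

Segregation against genotyped parents assigns each allele maternal,
paternal, de novo (both parents genotyped, neither carries) or unknown
origin. A compound het with one maternal and one paternal allele is in
trans; two alleles traced to one parent with both parents genotyped is in
cis and the candidate is dropped. Pairs without parental data stay
"unphased" and are retained — unphased compound hets are a routine,
reportable configuration in practice. Mendelian inconsistencies warn and
degrade to unknown rather than failing.

Reverse phenotyping matches the participant's HPO set against the gene's
key clinical features through descendant closure: a feature matches when
any participant term lies at or below one of the feature's linked terms.
Each feature counts once regardless of how many terms hit it — feature
counts in the motivating study's tables can exceed one per body system,
which implies per-feature rather than per-system counting. A candidate is
**reportable** iff at least one *major* feature matches. Confidence then
follows the ACMG classes of the alleles (curator inputs, never computed
here): two P/LP → confident; P/LP + VUS → probable; two VUS → possible;
X-linked single allele P/LP → confident, VUS → possible (no probable
tier); a homozygous allele counts twice; any benign/likely-benign allele
invalidates the candidate. Alleles without a curated class default to VUS
(conservative: they can never raise a tier).

## The knowledge base

`load_knowledge_base()` reads a versioned YAML document encoding the
panel: 9 genes, 8 syndrome columns, 43 key clinical features grouped into
11 body systems, and 98 (syndrome, feature) weights, each major (feature
present in > 50% of affected individuals or a characteristic diagnostic
feature) or minor. A gene's feature set pools all its syndromes with
weight = max(major > minor), because feature counts are recorded per
participant per gene, not per syndrome. Footnoted features — features of
gene-specific syndrome variants such as the *NPHP1/CEP290/TMEM67*
Joubert-plus syndromes — carry an explicit gene restriction on the weight
row, so *OFD1* (also a Joubert gene) does not inherit them.

The HPO linkage is a curated **stand-in**: the original study's
supplementary table of acceptable linked terms is not reproduced in its
main text, so each feature is mapped to one or two anchor terms (real HPO
identifiers where well established) and the package bundles a ~150-term
miniature *synthetic* ontology extract (`hpo_mini.obo`; the `HP:97*`/
`HP:98*`/`HP:989*` ranges are synthetic) sufficient for closure
semantics. Pointing the ontology argument at a full HPO `.obo` release
enables real-ontology operation unchanged.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code that defines the study
conditions under which the pipeline is validated. It emulates:

* **sparse phenotyping** — HPO terms per participant are Poisson with
  mean `hpo_sparsity = 2` (profiles of one or two terms, sometimes none),
  matching the sparse-entry failure mode that motivates reverse
  phenotyping;
* **planted diagnoses** of every mechanism class the pipeline must
  recover: homozygous SNV, compound-het SNV, SNV + rare coding SV,
  SNV + deep-intronic splice variant, X-linked single allele, each with
  curator ACMG classes;
* **phenotype noise** — with probability `phenotype_noise` a planted
  participant receives no major-feature term and the diagnosis becomes
  unreportable; the default 0.3 reflects that a substantial minority of
  genuine molecular diagnoses in this setting lack reportable phenotype
  support (in the motivating study roughly 11 of 29 novel diagnoses);
* **decoys** — common variants with allele frequencies drawn log-uniform
  over [1e-6, 0.05] so both sides of the 0.002 boundary are exercised,
  singleton heterozygous deleterious missenses, common SV clusters above
  the 10-occurrence cut-off, wholly intronic noise SVs, unaffected
  parents, and participants solved with other genes.

The truth table derives expected reportability from the *actually
sampled* terms, so recovery scoring (`score_recovery()`) is exact:
sensitivity over expected-reportable plants, and false reports as
reportable output rows absent from the truth table. Gene coordinates are
synthetic (10 × 200 bp exons, 5 kb introns, real chromosome assignments);
the pipeline only ever relies on internal consistency between the
variant, SV and exon files. Singleton decoys are never placed in a
participant who carries a planted diagnosis: feature sets overlap between
panel genes, so a planted participant's legitimate phenotype terms could
otherwise validate an unrelated single-allele X-linked decoy — a
collision, not a pipeline property. What passing these tests does *not*
show: performance on real annotation noise (caller discordance,
mis-annotated consequences, population stratification of frequencies),
on real HPO usage patterns, or on complex SV architectures.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere inside the package; BED is
  converted on read (via `rtracklayer`), VCF positions are taken as given
  with no re-normalisation; multi-allelic records are split per alt
  allele against the annotation's `Allele` subfield.
* Canonical-transcript status is taken from the annotation flag; there is
  no independent transcript election.
* Absent population frequency is treated as 0 (a novel variant is rare);
  absent splice deltas and absent SV read fractions fail their screens
  conservatively, with logged counts.
* `max_tolerated_ac()` settles the Poisson boundary by exact comparison
  around the quantile (verified against a brute-force scan of the
  survival function in tests).
* All generator randomness flows through one seeded Mersenne-Twister
  stream; outputs are byte-identical per seed and the seed is recorded in
  each output header.
* Fixture integrity: the packaged diagnosis tables are checked against an
  MD5 manifest on load. Two fixture rows carry printed confidence labels
  that differ from a mechanical application of the confidence rule to
  their printed ACMG classes (rule-derived: possible and probable
  respectively); the fixture stores both labels, the engine implements
  the stated rule, and the aggregate tier counts are identical either way.

## Problem sizes used by the test suite

The suite validates clustering against a quadratic brute-force oracle up
to 500 random calls, closure expansion against a fixed-point oracle on
random DAGs up to 100 nodes, monotonicity suites (allele-frequency
threshold, HPO superset, ACMG upgrade) on 1,000 random instances each,
and end-to-end recovery on seeded cohorts of up to 200 participants with
10 planted diagnoses, zero phenotype noise and one planted cis pair —
conditions under which recovery is complete (sensitivity 1.0, no false
reports) by construction of the generator's guarantees.

## Known limitations

* ACMG evidence-code derivation is out of scope by design: classes are
  curator inputs, and the headline cohort-scale counts of the motivating
  study depend on a access-controlled cohort that cannot be re-analysed
  here.
* The HPO linkage fixture is a stand-in, not the study's supplementary
  linkage table; closure semantics, not term choices, are what the tests
  pin down.
* No per-ancestry frequency handling, no X-linked refinement of the
  allele-count bound, no semantic-similarity phenotype scoring (matching
  is deliberately major/minor counting), no complex-SV architecture
  resolution, and no clinical reporting workflow mechanics.

## A worked run

```{r example}
kb <- load_fixture("table1")
obo <- read_obo(system.file("extdata", "hpo_mini.obo", package = "revphen"))
cfg <- simulation_config(n_participants = 30, phenotype_noise = 0,
                         planted_cis = 1, seed = 42)
dir <- tempfile("cohort")
g <- generate_cohort(cfg, dir)
cohort <- read_cohort(dir, kb$genes$symbol)
dx <- run_pipeline(cohort, kb, obo)
dx[, c("participant_id", "gene", "zygosity", "phase", "acmg_classes",
       "major_count", "reportable", "confidence")]
score_recovery(g$truth, dx)
```

```{r replay}
glance(replay_fixture(load_fixture("table2")))
```
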
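# shared test helpers: fixture builders and independent brute-force oracles

options(revphen.quiet = TRUE)

pkg_extdata <- function(file) system.file("extdata", file, package = "revphen")

mini_ontology <- function() read_obo(pkg_extdata("hpo_mini.obo"))

panel_kb <- function() load_fixture("table1")

# write a toy OBO file from an edge list (child -> parent); returns path
write_toy_obo <- function(edges, extra_roots = character()) {
  ids <- unique(c(edges$child, edges$parent, extra_roots))
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  lines <- c("format-version: 1.2", "")
  for (id in ids) {
    parents <- edges$parent[edges$child == id]
    lines <- c(
      lines, "[Term]", paste0("id: ", id), paste0("name: term ", id),
      if (length(parents)) paste0("is_a: ", parents), ""
    )
  }
  writeLines(lines, path)
  path
}

# brute-force descendant closure on an edge list (child -> parent):
# repeatedly add children of anything in the set until a fixed point
brute_closure <- function(edges, terms) {
  out <- terms
  repeat {
    add <- edges$child[edges$parent %in% out]
    new <- setdiff(add, out)
    if (length(new) == 0L) break
    out <- c(out, new)
  }
  sort(unique(out))
}

# quadratic all-pairs + flood-fill connected-components oracle for SV
# clustering, independent of IRanges/igraph
brute_sv_clusters <- function(calls, ro_min = 0.8, ins_window = 50) {
  n <- nrow(calls)
  linked <- function(i, j) {
    if (calls$chrom[i] != calls$chrom[j] || calls$svtype[i] != calls$svtype[j]) {
      return(FALSE)
    }
    if (calls$svtype[i] == "INS") {
      return(abs(calls$start[i] - calls$start[j]) <= ins_window)
    }
    ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j]) + 1
    if (ov <= 0) return(FALSE)
    min(ov / (calls$end[i] - calls$start[i] + 1),
        ov / (calls$end[j] - calls$start[j] + 1)) >= ro_min
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j && comp[i] != comp[j] && linked(i, j)) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# same-partition check between two integer labelings
same_partition <- function(a, b) {
  identical(
    unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1))]),
    unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1))])
  )
}

# random annotated-variant tibble for property tests
random_variants <- function(n, seed) {
  withr::local_seed(seed)
  cons_pool <- c(
    high_impact_consequences(), "missense_variant", "synonymous_variant",
    "intron_variant", "5_prime_UTR_variant"
  )
  annotated_variants(tibble::tibble(
    chrom = sample(paste0("chr", c(1:22, "X")), n, replace = TRUE),
    pos = sample.int(1e6, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = sample(c("ALMS1", "CEP290", "BBS1"), n, replace = TRUE),
    canonical = sample(c(TRUE, TRUE, FALSE), n, replace = TRUE),
    consequence = vapply(
      seq_len(n),
      function(i) paste(sample(cons_pool, sample(1:3, 1)), collapse = "&"),
      character(1)
    ),
    cohort_af = ifelse(runif(n) < 0.2, NA, 10^runif(n, -6, log10(0.05))),
    popdb_af = ifelse(runif(n) < 0.2, NA, 10^runif(n, -6, log10(0.05))),
    clinsig = sample(
      c("pathogenic", "likely_pathogenic", "vus", "likely_benign",
        "benign", "conflicting", "absent"),
      n, replace = TRUE
    ),
    missense_class = sample(c("deleterious", "tolerated", "absent"), n, replace = TRUE),
    ds_ag = ifelse(runif(n) < 0.5, NA, runif(n)),
    ds_al = ifelse(runif(n) < 0.5, NA, runif(n))
  ))
}

# random SV call tibble for clustering property tests
random_sv_calls <- function(n, seed, n_chrom = 2) {
  withr::local_seed(seed)
  start <- sample.int(50000, n, replace = TRUE)
  svtype <- sample(c("DEL", "DUP", "INV", "INS"), n, replace = TRUE)
  len <- sample.int(5000, n, replace = TRUE)
  sv_calls(tibble::tibble(
    participant_id = sample(paste0("P", 1:20), n, replace = TRUE),
    chrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
    start = start,
    end = ifelse(svtype == "INS", start, start + len),
    svtype = svtype,
    caller = sample(c("manta", "canvas"), n, replace = TRUE),
    read_fraction = runif(n)
  ))
}

# minimal in-memory cohort wrapper for diagnosis-engine tests
make_cohort <- function(variants, genotypes, sv_calls_tbl = NULL, ped, meta,
                        hpo = NULL, acmg = NULL, exons = synthetic_exons(),
                        samples = NULL) {
  structure(
    list(
      variants = variants,
      genotypes = genotypes,
      samples = samples %||% unique(c(genotypes$participant_id, ped$participant_id)),
      sv_calls = sv_calls_tbl %||% sv_calls(tibble::tibble(
        participant_id = character(), chrom = character(),
        start = integer(), end = integer(), svtype = character()
      )),
      ped = ped,
      meta = meta,
      hpo = hpo %||% tibble::tibble(participant_id = character(), hpo_id = character()),
      acmg = acmg %||% tibble::tibble(
        participant_id = character(), variant_id = character(), acmg_class = character()
      ),
      exons = exons
    ),
    class = "rp_cohort"
  )
}

`%||%` <- rlang::`%||%`
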
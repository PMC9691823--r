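# internal helpers shared across modules

# abort with a consistent class so callers/tests can distinguish validation
# failures (exit code 2 at the CLI) from I/O failures (exit code 3)
stop_validation <- function(msg, ...) {
  rlang::abort(paste0(msg, ...), class = "revphen_validation_error")
}

stop_io <- function(msg, ...) {
  rlang::abort(paste0(msg, ...), class = "revphen_io_error")
}

check_file_exists <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_io("file not found: ", as.character(path)[1])
  }
  invisible(path)
}

is_proportion <- function(x, lo_open = TRUE, hi_open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) return(FALSE)
  lo <- if (lo_open) x > 0 else x >= 0
  hi <- if (hi_open) x < 1 else x <= 1
  lo && hi
}

# single-line structured log record; suppress with options(revphen.quiet = TRUE)
log_stage <- function(stage, ...) {
  if (isTRUE(getOption("revphen.quiet", FALSE))) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0(
    "[revphen] stage=", stage,
    if (length(kv)) paste0(" ", paste0(names(kv), "=", unlist(kv), collapse = " ")) else ""
  )
  rlang::inform(msg)
  invisible(NULL)
}

# run an expression under a temporary, fully specified RNG state so that
# generator output is byte-identical for a given seed regardless of the
# session's RNG settings
with_rp_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind[1:2]))
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
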
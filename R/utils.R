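# Internal helpers shared across modules.

# Canonical identifier form: trimmed, lower-cased. Every comparison of gene,
# protein or alias names in the package goes through this.
canonical_id <- function(x) {
  tolower(trimws(as.character(x)))
}

# Canonical undirected pair key "a--b" with a <= b lexicographically.
# Gene identifiers must not contain the separator "--".
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

split_pair_key <- function(keys) {
  parts <- strsplit(keys, "--", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) {
    data.frame(gene_a = p[[1]], gene_b = p[[2]], stringsAsFactors = FALSE)
  }))
}

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Classed conditions so the CLI can map failures to exit codes:
#   configuration errors -> 2, data/format/validation errors -> 3.
abort_config <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("gimotif_config_error", "gimotif_error", "error")))
}

abort_format <- function(msg) {
  stop(errorCondition(msg, class = c("gimotif_format_error", "gimotif_error", "error")))
}

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("gimotif_validation_error", "gimotif_error", "error")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("gimotif_io_error", "gimotif_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
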
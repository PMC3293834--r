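# Fixture builders shared across test files. Everything is generated in
# code; no fixture files are stored.

make_edges <- function(a, b, species = "sp1", kind = "genetic", db = "test") {
  data.frame(
    gene_a = a, gene_b = b, species = species, source_db = db,
    interaction_kind = kind, stringsAsFactors = FALSE
  )
}

# A path graph g1 - g2 - ... - gn.
path_edges <- function(genes) {
  make_edges(genes[-length(genes)], genes[-1])
}

# n_edges distinct random undirected edges over the given genes.
random_edges <- function(genes, n_edges) {
  total <- length(genes) * (length(genes) - 1) / 2
  stopifnot(n_edges <= total)
  idx <- which(upper.tri(diag(length(genes))), arr.ind = TRUE)
  pick <- idx[sample.int(nrow(idx), n_edges), , drop = FALSE]
  make_edges(genes[pick[, 1]], genes[pick[, 2]])
}

# A small, fast world configuration for property-style loops.
tiny_world_cfg <- function(seed, ...) {
  args <- list(
    n_genes = 40, n_species = 2, background_edge_prob = 0.02,
    n_positive_motifs = 15, p_pos_gi_edge = 0.4, p_neg_gi_edge = 0.1,
    n_negative_pairs = 10, homolog_cluster_rate = 0.6,
    gi_conservation_rate = 0.3, p_ppi_given_gi = 0.5, alias_rate = 0.2,
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(world_config, args)
}

# Independent Mann-Whitney AUC oracle: concordant pairs + half ties over
# all positive x negative score pairs.
mann_whitney_auc <- function(scores, labels) {
  sp <- scores[labels]
  sn <- scores[!labels]
  tot <- 0
  for (p in sp) {
    for (q in sn) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(sp) * length(sn))
}

# Exhaustive cross-product interaction oracle on an edge data frame.
brute_force_interaction <- function(edges, set_a, set_b) {
  keys <- pair_key(tolower(edges$gene_a), tolower(edges$gene_b))
  found <- FALSE
  for (a in tolower(set_a)) {
    for (b in tolower(set_b)) {
      if (pair_key(a, b) %in% keys) found <- TRUE
    }
  }
  found
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
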
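# Homolog-cluster lookups backing the GI-HomoloGene filter: a gene maps to
# at most one cluster; cluster members carry species (taxon) tags.

#' Build a homolog map from HomoloGene-style records
#'
#' @param records Data frame as returned by [read_homologene()] (may be
#'   empty). A gene appearing in more than one cluster keeps its first
#'   cluster; the surplus records are dropped with a warning.
#' @return An object of class `homolog_map`.
#' @export
build_homolog_map <- function(records = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    return(structure(
      list(
        gene_to_cluster = setNames(character(0), character(0)),
        members = list()
      ),
      class = "homolog_map"
    ))
  }
  records$gene_id <- canonical_id(records$gene_id)
  dup_pair <- duplicated(paste(records$cluster_id, records$gene_id, sep = "\r"))
  records <- records[!dup_pair, , drop = FALSE]
  multi <- duplicated(records$gene_id)
  if (any(multi)) {
    warning(sprintf(
      "%d gene(s) listed in more than one cluster; keeping the first cluster each",
      length(unique(records$gene_id[multi]))
    ))
    records <- records[!multi, , drop = FALSE]
  }
  gene_to_cluster <- setNames(as.character(records$cluster_id), records$gene_id)
  members <- split(
    data.frame(gene_id = records$gene_id, taxon = as.character(records$taxon),
               stringsAsFactors = FALSE),
    records$cluster_id
  )
  structure(
    list(gene_to_cluster = gene_to_cluster, members = members),
    class = "homolog_map"
  )
}

#' @export
print.homolog_map <- function(x, ...) {
  cat(sprintf(
    "<homolog_map> %d genes in %d clusters\n",
    length(x$gene_to_cluster), length(x$members)
  ))
  invisible(x)
}

#' Members of a gene's homolog cluster
#'
#' Returns every member of the cluster containing `gene`, including the gene
#' itself, with its taxon tag. A gene absent from the map falls back to a
#' singleton cluster with unknown taxon (`NA`), so filters built on top
#' reduce to a direct lookup for unmapped genes instead of failing.
#'
#' @param map A `homolog_map`.
#' @param gene A gene id.
#' @return Data frame with columns `gene_id` and `taxon`.
#' @export
cluster_members <- function(map, gene) {
  stopifnot(inherits(map, "homolog_map"))
  g <- canonical_id(gene)
  cl <- map$gene_to_cluster[g]
  if (length(cl) == 0 || is.na(cl)) {
    return(data.frame(gene_id = g, taxon = NA_character_, stringsAsFactors = FALSE))
  }
  map$members[[cl]]
}

#' Test for a conserved (homologous) interaction between two genes
#'
#' Checks whether any member A of the cluster of `s` interacts with any
#' member B of the cluster of `t` in the network. With
#' `require_same_species = TRUE` (the default) a pair only qualifies if A and
#' B carry the same known taxon; members with unknown taxon never satisfy
#' the constraint. The interacting pair may be `s` and `t` themselves, so on
#' taxon-annotated data this is at least as permissive as a direct lookup.
#'
#' @param map A `homolog_map`.
#' @param network A `gi_network`.
#' @param s,t Gene ids (source and target).
#' @param require_same_species Logical; enforce that witnesses share a taxon.
#' @return A list with elements `found` (logical) and `witness` (character
#'   vector of canonical pair keys).
#' @export
homologous_interaction <- function(map, network, s, t, require_same_species = TRUE) {
  stopifnot(inherits(map, "homolog_map"), inherits(network, "gi_network"))
  A <- cluster_members(map, s)
  B <- cluster_members(map, t)
  witness <- character(0)
  for (i in seq_len(nrow(A))) {
    a <- A$gene_id[i]
    if (!exists(a, envir = network$adj, inherits = FALSE)) next
    hits <- intersect(get(a, envir = network$adj), B$gene_id)
    if (length(hits) == 0) next
    if (require_same_species) {
      ta <- A$taxon[i]
      if (is.na(ta)) next
      tb <- B$taxon[match(hits, B$gene_id)]
      hits <- hits[!is.na(tb) & tb == ta]
    }
    if (length(hits) > 0) {
      witness <- c(witness, pair_key(rep(a, length(hits)), hits))
    }
  }
  witness <- sort(unique(witness))
  list(found = length(witness) > 0, witness = witness)
}
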
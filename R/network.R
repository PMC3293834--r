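# Canonical undirected interaction graph with alias resolution and bounded
# neighborhood expansion. The adjacency index and alias index are stored in
# hashed environments so that the per-motif filter lookups stay O(degree)
# even on tables of tens of thousands of predictions; the igraph object is
# kept alongside for shortest-path queries (evidence scores, test oracles).

#' Build a genetic-interaction network
#'
#' Assembles the canonical undirected graph the filters query: nodes are
#' canonical gene ids (union of all edge endpoints), edges are unweighted and
#' undirected, and an alias index maps every known name (case-insensitively)
#' to its canonical gene id(s). Every canonical id is its own alias. Alias
#' records whose canonical id never appears in an edge are retained — they may
#' still resolve queries — and counted in a message.
#'
#' @param edges Edge data frame as returned by [read_edge_list()] (may be
#'   empty).
#' @param aliases Optional alias data frame as returned by
#'   [read_alias_table()].
#' @return An object of class `gi_network`.
#' @examples
#' edges <- data.frame(gene_a = "cdc28", gene_b = "cln2",
#'                     species = "yeast", source_db = "demo",
#'                     interaction_kind = "genetic")
#' net <- build_network(edges)
#' resolve_gene(net, "CDC28")
#' @export
build_network <- function(edges, aliases = NULL) {
  edges <- canonicalize_edges(edges)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))

  adj <- new.env(hash = TRUE, parent = emptyenv())
  for (g in nodes) assign(g, character(0), envir = adj)
  if (nrow(edges) > 0) {
    fwd <- split(edges$gene_b, edges$gene_a)
    rev <- split(edges$gene_a, edges$gene_b)
    for (g in names(fwd)) assign(g, unique(fwd[[g]]), envir = adj)
    for (g in names(rev)) {
      assign(g, unique(c(get(g, envir = adj), rev[[g]])), envir = adj)
    }
  }

  graph <- if (length(nodes) == 0) {
    igraph::make_empty_graph(directed = FALSE)
  } else {
    igraph::graph_from_data_frame(
      edges[, c("gene_a", "gene_b"), drop = FALSE],
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
    )
  }

  alias_index <- new.env(hash = TRUE, parent = emptyenv())
  for (g in nodes) assign(g, g, envir = alias_index)
  n_orphan_alias <- 0L
  if (!is.null(aliases) && nrow(aliases) > 0) {
    canon <- canonical_id(aliases$canonical_id)
    alias <- canonical_id(aliases$alias)
    n_orphan_alias <- length(setdiff(unique(canon), nodes))
    for (i in seq_along(alias)) {
      prev <- if (exists(alias[i], envir = alias_index, inherits = FALSE)) {
        get(alias[i], envir = alias_index)
      } else {
        character(0)
      }
      assign(alias[i], unique(c(prev, canon[i])), envir = alias_index)
      # the canonical id must resolve to itself even when it has no edges
      if (!exists(canon[i], envir = alias_index, inherits = FALSE)) {
        assign(canon[i], canon[i], envir = alias_index)
      }
    }
    if (n_orphan_alias > 0) {
      message(sprintf(
        "build_network: %d alias canonical id(s) absent from the edge set (retained)",
        n_orphan_alias
      ))
    }
  }

  edge_meta <- if (nrow(edges) > 0) {
    data.frame(
      pair = pair_key(edges$gene_a, edges$gene_b),
      species = edges$species,
      source_db = edges$source_db,
      interaction_kind = edges$interaction_kind,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(pair = character(), species = character(),
               source_db = character(), interaction_kind = character(),
               stringsAsFactors = FALSE)
  }

  structure(
    list(
      nodes = nodes,
      adj = adj,
      graph = graph,
      alias_index = alias_index,
      edge_meta = edge_meta,
      n_edges = nrow(edges)
    ),
    class = "gi_network"
  )
}

#' @export
print.gi_network <- function(x, ...) {
  cat(sprintf(
    "<gi_network> %d nodes, %d edges, %d alias entries\n",
    length(x$nodes), x$n_edges, length(ls(x$alias_index))
  ))
  invisible(x)
}

#' Resolve a protein or gene name to canonical gene ids
#'
#' Looks a name up in the network's alias index, case-insensitively after
#' trimming whitespace. Returns all canonical ids carrying that alias — an
#' ambiguous alias yields more than one id, and downstream filters succeed if
#' any candidate interacts — or `character(0)` for an unknown name.
#'
#' @param network A `gi_network`.
#' @param name A single non-empty protein or gene name.
#' @return Character vector of canonical gene ids (possibly empty).
#' @export
resolve_gene <- function(network, name) {
  stopifnot(inherits(network, "gi_network"))
  if (length(name) != 1 || is.na(name) || trimws(name) == "") {
    abort_validation("resolve_gene: name must be a single non-empty string")
  }
  key <- canonical_id(name)
  if (exists(key, envir = network$alias_index, inherits = FALSE)) {
    get(key, envir = network$alias_index)
  } else {
    character(0)
  }
}

#' Test for an interaction between two gene sets
#'
#' Returns whether any gene in `set_a` has an edge to any gene in `set_b`,
#' together with every witnessing pair as canonical `"a--b"` keys (sorted,
#' deduplicated). Symmetric in its two arguments; empty sets never interact.
#'
#' @param network A `gi_network`.
#' @param set_a,set_b Character vectors of gene ids (canonicalised
#'   internally).
#' @return A list with elements `found` (logical) and `witness` (character
#'   vector of pair keys).
#' @export
has_interaction <- function(network, set_a, set_b) {
  stopifnot(inherits(network, "gi_network"))
  set_a <- unique(canonical_id(set_a))
  set_b <- unique(canonical_id(set_b))
  witness <- character(0)
  if (length(set_a) > 0 && length(set_b) > 0) {
    # iterate the smaller set for speed; adjacency is symmetric
    if (length(set_b) < length(set_a)) {
      tmp <- set_a; set_a <- set_b; set_b <- tmp
    }
    for (a in set_a) {
      if (!exists(a, envir = network$adj, inherits = FALSE)) next
      hits <- intersect(get(a, envir = network$adj), set_b)
      if (length(hits) > 0) {
        witness <- c(witness, pair_key(rep(a, length(hits)), hits))
      }
    }
  }
  witness <- sort(unique(witness))
  list(found = length(witness) > 0, witness = witness)
}

#' Cumulative graph neighborhood of a gene set
#'
#' Returns all genes at graph distance at most `radius` from any seed gene
#' (the ball of radius `radius`, including the seed itself). Seed ids absent
#' from the network are retained in the result so that filters degrade
#' gracefully on genes missing from the GI sources; they contribute no
#' neighbors.
#'
#' @param network A `gi_network`.
#' @param seed Character vector of gene ids.
#' @param radius Non-negative integer expansion radius.
#' @return Character vector of gene ids.
#' @export
neighborhood <- function(network, seed, radius) {
  stopifnot(inherits(network, "gi_network"))
  if (length(radius) != 1 || is.na(radius) || radius < 0 || radius != floor(radius)) {
    abort_validation("neighborhood: radius must be a single non-negative integer")
  }
  seed <- unique(canonical_id(seed))
  result <- seed
  frontier <- seed[vapply(seed, exists, logical(1),
                          envir = network$adj, inherits = FALSE)]
  r <- 0L
  while (r < radius && length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, get, envir = network$adj),
                         use.names = FALSE))
    new <- setdiff(nxt, result)
    result <- c(result, new)
    frontier <- new
    r <- r + 1L
  }
  result
}
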
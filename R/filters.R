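# The three genetic-interaction filters, the generic network (PPI) filter,
# external-flag filters, and include/exclude/union/intersection composition.
#
# Semantics fixed here once, used everywhere:
#  * A motif whose source or target cannot be resolved FAILS (with an
#    explanatory note) rather than erroring; filters run over thousands of
#    predictions and must not abort on one bad row.
#  * The GI-node filter passes at iteration i (i = 1..N, N the node count)
#    iff an edge joins the cumulative radius-i balls around the resolved
#    source and target sets — equivalently, for distinct resolved genes,
#    iff their shortest-path distance is at most 2N+1.

new_decision <- function(motif_id, filter, passed, witness = character(0), note = "") {
  data.frame(
    motif_id = motif_id,
    filter = filter,
    passed = passed,
    witness = paste(sort(unique(witness)), collapse = ";"),
    note = note,
    stringsAsFactors = FALSE
  )
}

empty_decisions <- function() {
  data.frame(
    motif_id = character(), filter = character(), passed = logical(),
    witness = character(), note = character(), stringsAsFactors = FALSE
  )
}

motif_fields <- function(motif) {
  # accept a one-row motif_predictions data frame or a plain list
  list(
    motif_id = as.character(motif$motif_id %||% "m1"),
    source = as.character(motif$source_protein),
    target = as.character(motif$target_protein)
  )
}

#' Specify one filter for [apply_filters()]
#'
#' @param kind One of `"gi"` (direct genetic-interaction lookup),
#'   `"gi_node"` (neighborhood expansion up to `node_count` iterations),
#'   `"gi_homologene"` (ortholog-cluster extrapolation), `"network_generic"`
#'   (direct lookup against a caller-supplied network, typically
#'   protein-protein interactions), or `"external_flag"` (read a precomputed
#'   boolean from the prediction's `external_flags`).
#' @param name Filter name used in decisions and reports; defaults to the
#'   kind (for `external_flag` it must name the flag to read).
#' @param node_count Expansion iterations for `gi_node`; must be >= 1.
#'   Values above 2 trade selectivity for sensitivity steeply and values
#'   above 4 trigger a warning. Default 2.
#' @param require_same_species For `gi_homologene`: require witnesses to
#'   share a taxon (default `TRUE`).
#' @param polarity `"include"` retains motifs that pass; `"exclude"` negates
#'   the verdict so that motifs *without* supporting interactions are
#'   retained.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("gi", "gi_node", "gi_homologene",
                                 "network_generic", "external_flag"),
                        name = NULL, node_count = 2L,
                        require_same_species = TRUE,
                        polarity = c("include", "exclude")) {
  kind <- match.arg(kind)
  polarity <- match.arg(polarity)
  if (kind == "gi_node") {
    if (length(node_count) != 1 || is.na(node_count) || node_count < 1 ||
        node_count != floor(node_count)) {
      abort_validation("filter_spec: node_count must be an integer >= 1")
    }
    if (node_count > 4) {
      warning("node_count > 4: expect very poor selectivity; node counts above 2 are rarely useful")
    }
  }
  if (is.null(name)) {
    name <- if (kind == "gi_node") sprintf("gi_node%d", as.integer(node_count)) else kind
  }
  if (kind == "external_flag" && (is.null(name) || name == "external_flag")) {
    abort_validation("filter_spec: external_flag specs must be named after the flag they read")
  }
  structure(
    list(name = name, kind = kind, node_count = as.integer(node_count),
         require_same_species = isTRUE(require_same_species),
         polarity = polarity),
    class = "filter_spec"
  )
}

resolve_or_note <- function(network, src, tgt) {
  s <- resolve_gene(network, src)
  t <- resolve_gene(network, tgt)
  note <- ""
  if (length(s) == 0 && length(t) == 0) {
    note <- "source unresolved; target unresolved"
  } else if (length(s) == 0) {
    note <- "source unresolved"
  } else if (length(t) == 0) {
    note <- "target unresolved"
  }
  list(s = s, t = t, note = note)
}

#' Basic genetic-interaction filter
#'
#' Retains a putative minimotif if its source protein S and target protein T
#' (each resolved through the alias index to a set of candidate gene ids)
#' have a direct edge in the GI network. A motif whose source or target
#' cannot be resolved fails with a note. A motif whose source equals its
#' target passes only if a self-loop edge exists.
#'
#' @param motif One prediction: a one-row data frame from
#'   [read_minimotif_table()] or a list with `motif_id`, `source_protein`,
#'   `target_protein`.
#' @param network A `gi_network` of genetic interactions.
#' @param filter_name Name recorded in the decision (default `"gi"`).
#' @return A one-row decision data frame (`motif_id`, `filter`, `passed`,
#'   `witness`, `note`).
#' @export
basic_gi_filter <- function(motif, network, filter_name = "gi") {
  m <- motif_fields(motif)
  r <- resolve_or_note(network, m$source, m$target)
  if (nzchar(r$note)) {
    return(new_decision(m$motif_id, filter_name, FALSE, note = r$note))
  }
  hit <- has_interaction(network, r$s, r$t)
  new_decision(m$motif_id, filter_name, hit$found, witness = hit$witness)
}

#' GI-node filter: neighborhood-expansion lookup
#'
#' Iteratively expands the resolved source and target gene sets to their
#' cumulative graph neighborhoods (radius i at iteration i) and retains the
#' motif at the first iteration i (1 <= i <= `node_count`) at which any edge
#' joins the two balls; the witness edges come from that iteration. If no
#' interaction is found after `node_count` iterations the motif is filtered
#' out.
#'
#' @inheritParams basic_gi_filter
#' @param node_count Number of expansion iterations N (>= 1); values of 3-4
#'   yield very poor selectivity, so 2 is the default.
#' @return A one-row decision data frame.
#' @export
gi_node_filter <- function(motif, network, node_count = 2L, filter_name = NULL) {
  if (length(node_count) != 1 || is.na(node_count) || node_count < 1 ||
      node_count != floor(node_count)) {
    abort_validation("gi_node_filter: node_count must be an integer >= 1")
  }
  if (node_count > 4) {
    warning("node_count > 4: expect very poor selectivity")
  }
  if (is.null(filter_name)) filter_name <- sprintf("gi_node%d", as.integer(node_count))
  m <- motif_fields(motif)
  r <- resolve_or_note(network, m$source, m$target)
  if (nzchar(r$note)) {
    return(new_decision(m$motif_id, filter_name, FALSE, note = r$note))
  }
  for (i in seq_len(node_count)) {
    ball_s <- neighborhood(network, r$s, i)
    ball_t <- neighborhood(network, r$t, i)
    hit <- has_interaction(network, ball_s, ball_t)
    if (hit$found) {
      return(new_decision(m$motif_id, filter_name, TRUE, witness = hit$witness,
                          note = sprintf("iteration %d", i)))
    }
  }
  new_decision(m$motif_id, filter_name, FALSE)
}

#' GI-HomoloGene filter: ortholog-cluster extrapolation
#'
#' Looks the resolved source and target genes up in their homolog clusters
#' and retains the motif if any member A of the source cluster interacts
#' with any member B of the target cluster — extrapolating a GI observed
#' between homologs in another species to the query pair. With
#' `require_same_species = TRUE` (default) A and B must share a known taxon.
#' Genes absent from the homolog map fall back to singleton clusters, so the
#' filter degrades to the basic lookup rather than failing. Unlike the other
#' filters, a source or target absent from the GI network is not an automatic
#' failure here: its canonical name is still looked up in the homolog map,
#' because a gene with no recorded GI of its own may well have homologs that
#' interact — the case this filter exists for.
#'
#' @inheritParams basic_gi_filter
#' @param map A `homolog_map` from [build_homolog_map()].
#' @param require_same_species Logical (default `TRUE`).
#' @return A one-row decision data frame.
#' @export
gi_homologene_filter <- function(motif, network, map, require_same_species = TRUE,
                                 filter_name = "gi_homologene") {
  stopifnot(inherits(map, "homolog_map"))
  m <- motif_fields(motif)
  r <- resolve_or_note(network, m$source, m$target)
  s_cand <- if (length(r$s) > 0) r$s else canonical_id(m$source)
  t_cand <- if (length(r$t) > 0) r$t else canonical_id(m$target)
  witness <- character(0)
  for (s in s_cand) {
    for (t in t_cand) {
      hit <- homologous_interaction(map, network, s, t, require_same_species)
      witness <- c(witness, hit$witness)
    }
  }
  new_decision(m$motif_id, filter_name, length(witness) > 0, witness = witness)
}

#' Generic network filter (e.g. protein-protein interactions)
#'
#' The same direct-edge lookup as [basic_gi_filter()] applied to any network
#' the caller supplies — typically a physical (protein-protein) interaction
#' network, giving the classic PPI filter. Only the recorded filter name
#' distinguishes it in reports.
#'
#' @inheritParams basic_gi_filter
#' @param network A `gi_network` built from the caller's edge list
#'   (typically `interaction_kind = "physical"`).
#' @return A one-row decision data frame.
#' @export
generic_network_filter <- function(motif, network, filter_name = "network_generic") {
  basic_gi_filter(motif, network, filter_name = filter_name)
}

#' Combine several decisions on one motif
#'
#' Union passes iff any constituent passes; intersection iff all pass. The
#' combined witness is the union of constituent witnesses and the combined
#' name joins the constituent names with `"|"` (union) or `"&"`
#' (intersection).
#'
#' @param decisions Decision data frame whose rows all reference the same
#'   motif.
#' @param mode `"union"` or `"intersection"`.
#' @return A one-row decision data frame.
#' @export
combine_decisions <- function(decisions, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (is.null(decisions) || nrow(decisions) == 0) {
    abort_validation("combine_decisions: empty decision list")
  }
  ids <- unique(decisions$motif_id)
  if (length(ids) != 1) {
    abort_validation("combine_decisions: all decisions must reference the same motif")
  }
  passed <- if (mode == "union") any(decisions$passed) else all(decisions$passed)
  witness <- unlist(strsplit(decisions$witness[decisions$passed], ";", fixed = TRUE))
  witness <- witness[nzchar(witness)]
  if (!passed) witness <- character(0)
  sep <- if (mode == "union") "|" else "&"
  new_decision(ids, paste(decisions$filter, collapse = sep), passed, witness = witness)
}

# ---- vectorised cores -------------------------------------------------------
# apply_filters runs these over whole prediction tables; the exported
# per-motif functions above share their semantics (asserted in the tests).

core_basic <- function(src, tgt, network) {
  n <- length(src)
  passed <- logical(n); witness <- character(n); note <- character(n)
  for (i in seq_len(n)) {
    r <- resolve_or_note(network, src[i], tgt[i])
    if (nzchar(r$note)) {
      note[i] <- r$note
      next
    }
    hit <- has_interaction(network, r$s, r$t)
    passed[i] <- hit$found
    witness[i] <- paste(hit$witness, collapse = ";")
  }
  list(passed = passed, witness = witness, note = note)
}

core_gi_node <- function(src, tgt, network, node_count) {
  n <- length(src)
  passed <- logical(n); witness <- character(n); note <- character(n)
  for (i in seq_len(n)) {
    r <- resolve_or_note(network, src[i], tgt[i])
    if (nzchar(r$note)) {
      note[i] <- r$note
      next
    }
    for (k in seq_len(node_count)) {
      hit <- has_interaction(network,
                             neighborhood(network, r$s, k),
                             neighborhood(network, r$t, k))
      if (hit$found) {
        passed[i] <- TRUE
        witness[i] <- paste(hit$witness, collapse = ";")
        note[i] <- sprintf("iteration %d", k)
        break
      }
    }
  }
  list(passed = passed, witness = witness, note = note)
}

core_homologene <- function(src, tgt, network, map, require_same_species) {
  n <- length(src)
  passed <- logical(n); witness <- character(n); note <- character(n)
  for (i in seq_len(n)) {
    r <- resolve_or_note(network, src[i], tgt[i])
    s_cand <- if (length(r$s) > 0) r$s else canonical_id(src[i])
    t_cand <- if (length(r$t) > 0) r$t else canonical_id(tgt[i])
    w <- character(0)
    for (s in s_cand) {
      for (t in t_cand) {
        w <- c(w, homologous_interaction(map, network, s, t, require_same_species)$witness)
      }
    }
    w <- sort(unique(w))
    passed[i] <- length(w) > 0
    witness[i] <- paste(w, collapse = ";")
  }
  list(passed = passed, witness = witness, note = note)
}

#' Apply a battery of filters to a prediction table
#'
#' Runs every `filter_spec` against every prediction, yielding one decision
#' per (prediction, filter). Specs with `polarity = "exclude"` negate the
#' verdict — retaining the motifs *without* supporting interactions — and
#' move the witness into the note. `external_flag` specs read the named
#' boolean from each prediction's `external_flags` (a missing flag fails
#' with a note). Specs that need a resource that was not supplied raise a
#' configuration error before any filtering starts.
#'
#' @param predictions A `motif_predictions` data frame.
#' @param specs A single `filter_spec` or a list of them.
#' @param network `gi_network` of genetic interactions (required by `gi`,
#'   `gi_node`, `gi_homologene` specs).
#' @param ppi_network Optional `gi_network` for `network_generic` specs.
#' @param homolog_map Optional `homolog_map` for `gi_homologene` specs.
#' @return A decision data frame with columns `motif_id`, `filter`,
#'   `passed`, `witness`, `note`.
#' @export
apply_filters <- function(predictions, specs, network = NULL,
                          ppi_network = NULL, homolog_map = NULL) {
  if (inherits(specs, "filter_spec")) specs <- list(specs)
  if (length(specs) == 0) {
    abort_config("apply_filters: at least one filter_spec is required")
  }
  for (sp in specs) {
    if (!inherits(sp, "filter_spec")) {
      abort_config("apply_filters: specs must be filter_spec objects")
    }
    if (sp$kind %in% c("gi", "gi_node", "gi_homologene") && is.null(network)) {
      abort_config(sprintf("filter '%s' requires a GI network", sp$name))
    }
    if (sp$kind == "gi_homologene" && is.null(homolog_map)) {
      abort_config(sprintf("filter '%s' requires a homolog map", sp$name))
    }
    if (sp$kind == "network_generic" && is.null(ppi_network)) {
      abort_config(sprintf("filter '%s' requires a physical-interaction network", sp$name))
    }
  }
  src <- as.character(predictions$source_protein)
  tgt <- as.character(predictions$target_protein)
  ids <- as.character(predictions$motif_id)
  out <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    res <- switch(
      sp$kind,
      gi = core_basic(src, tgt, network),
      gi_node = core_gi_node(src, tgt, network, sp$node_count),
      gi_homologene = core_homologene(src, tgt, network, homolog_map,
                                      sp$require_same_species),
      network_generic = core_basic(src, tgt, ppi_network),
      external_flag = {
        flags <- predictions$external_flags
        passed <- vapply(seq_along(ids), function(i) {
          f <- flags[[i]]
          !is.null(f) && sp$name %in% names(f) && isTRUE(f[[sp$name]])
        }, logical(1))
        note <- vapply(seq_along(ids), function(i) {
          f <- flags[[i]]
          if (is.null(f) || !(sp$name %in% names(f))) "flag missing" else ""
        }, character(1))
        list(passed = passed, witness = character(length(ids)), note = note)
      }
    )
    if (identical(sp$polarity, "exclude")) {
      had_witness <- nzchar(res$witness)
      res$note <- ifelse(
        had_witness,
        paste0("excluded; witness: ", res$witness),
        ifelse(nzchar(res$note), res$note, "excluded")
      )
      res$witness <- character(length(ids))
      res$passed <- !res$passed
      res$witness <- rep("", length(ids))
    }
    out[[j]] <- data.frame(
      motif_id = ids,
      filter = sp$name,
      passed = res$passed,
      witness = if (length(res$witness)) res$witness else rep("", length(ids)),
      note = if (length(res$note)) res$note else rep("", length(ids)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
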
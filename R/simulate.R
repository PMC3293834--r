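# Synthetic-world simulator: builds a complete, internally consistent test
# bed (GI network, PPI network, alias table, homolog clusters, positive
# motifs, random-pair negatives) with planted statistical structure, so the
# filters and the evaluation harness can be exercised end-to-end without any
# external downloads. Every planting decision is recorded in ground_truth.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for a synthetic world
#'
#' The defaults encode the benchmark conditions the package's evaluation is
#' built around: ~3000 true source/target pairs of which 21.2% have a direct
#' GI edge, 27,000 random-pair negatives of which 2.9% accidentally collide
#' with a GI edge, and a 29% cross-species GI conservation rate (the
#' approximate conservation observed between closely related budding
#' yeasts). Gene count and species count are set to a yeast-proteome-like
#' scale that keeps accidental pair collisions negligible while remaining
#' fast to simulate.
#'
#' @param n_genes Total genes across all species (default 6000).
#' @param n_species Number of species the genes are partitioned into
#'   (default 3).
#' @param background_edge_prob Per-pair probability of a background GI edge
#'   within a species (Erdős–Rényi; default 2e-4).
#' @param n_positive_motifs True motifs to plant (default 3000).
#' @param p_pos_gi_edge Probability that a true motif's (S, T) pair receives
#'   a GI edge (default 0.212); overridden per activity by
#'   `per_activity_gi_rates` when supplied.
#' @param p_neg_gi_edge Probability that a random negative pair collides
#'   with a GI edge (default 0.029).
#' @param n_negative_pairs Random pairs in the negative set (default 27000).
#' @param homolog_cluster_rate Fraction of genes placed into cross-species
#'   homolog clusters (default 0.3). Every gene additionally gets a
#'   singleton cluster record, so homolog-map taxon information is complete.
#' @param gi_conservation_rate Probability that a motif-planted GI edge is
#'   replicated between the homologs of its endpoints in another species
#'   (default 0.29).
#' @param p_ppi_given_gi Probability that a planted GI pair also receives a
#'   physical (PPI) edge (default 0.4).
#' @param per_activity_gi_rates Optional named vector of per-activity edge
#'   rates, e.g. `c(binds = 0.19, modifies = 0.56)`; activities not named
#'   fall back to `p_pos_gi_edge`. `NULL` (default) uses the global rate for
#'   all activities.
#' @param activity_mix Named proportions of activities among positive motifs
#'   (default binds 0.6, modifies 0.35, traffics 0.05).
#' @param alias_rate Fraction of genes given one synthetic alias
#'   (default 0.2); motifs over aliased genes use the alias as their protein
#'   name half of the time, exercising alias resolution.
#' @param seed Integer RNG seed; the whole world is a deterministic function
#'   of the configuration including this seed.
#' @return A validated list of class `world_config`.
#' @export
world_config <- function(n_genes = 6000, n_species = 3,
                         background_edge_prob = 2e-4,
                         n_positive_motifs = 3000, p_pos_gi_edge = 0.212,
                         p_neg_gi_edge = 0.029, n_negative_pairs = 27000,
                         homolog_cluster_rate = 0.3,
                         gi_conservation_rate = 0.29,
                         p_ppi_given_gi = 0.4,
                         per_activity_gi_rates = NULL,
                         activity_mix = c(binds = 0.6, modifies = 0.35, traffics = 0.05),
                         alias_rate = 0.2, seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_species = as.integer(n_species),
    background_edge_prob = background_edge_prob,
    n_positive_motifs = as.integer(n_positive_motifs),
    p_pos_gi_edge = p_pos_gi_edge, p_neg_gi_edge = p_neg_gi_edge,
    n_negative_pairs = as.integer(n_negative_pairs),
    homolog_cluster_rate = homolog_cluster_rate,
    gi_conservation_rate = gi_conservation_rate,
    p_ppi_given_gi = p_ppi_given_gi,
    per_activity_gi_rates = per_activity_gi_rates,
    activity_mix = activity_mix,
    alias_rate = alias_rate, seed = as.integer(seed)
  )
  probs <- c(cfg$background_edge_prob, cfg$p_pos_gi_edge, cfg$p_neg_gi_edge,
             cfg$homolog_cluster_rate, cfg$gi_conservation_rate,
             cfg$p_ppi_given_gi, cfg$alias_rate, cfg$per_activity_gi_rates)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_validation("world_config: all probabilities must lie in [0, 1]")
  }
  if (cfg$n_genes < 2 || cfg$n_species < 1 ||
      cfg$n_positive_motifs < 0 || cfg$n_negative_pairs < 0) {
    abort_validation("world_config: counts must be non-negative (and n_genes >= 2, n_species >= 1)")
  }
  if (is.null(names(cfg$activity_mix)) ||
      !all(names(cfg$activity_mix) %in% ACTIVITIES)) {
    abort_validation("world_config: activity_mix must be named with valid activities")
  }
  class(cfg) <- c("world_config", "list")
  cfg
}

# Deterministically allocate `n` draws across species proportionally to
# their pair capacities (largest-remainder method), capping at capacity.
allocate_pairs <- function(n, capacities) {
  total <- sum(capacities)
  if (n > total) {
    abort_validation(sprintf(
      "infeasible configuration: %d pairs requested but only %.0f distinct same-species pairs exist",
      n, total
    ))
  }
  raw <- n * capacities / total
  alloc <- floor(raw)
  rem <- n - sum(alloc)
  if (rem > 0) {
    ord <- order(raw - alloc, decreasing = TRUE)
    for (i in ord) {
      if (rem == 0) break
      if (alloc[i] < capacities[i]) {
        alloc[i] <- alloc[i] + 1
        rem <- rem - 1
      }
    }
  }
  # spill any capacity overruns (possible when a species is tiny)
  over <- alloc > capacities
  if (any(over)) {
    spill <- sum(alloc[over] - capacities[over])
    alloc[over] <- capacities[over]
    while (spill > 0) {
      room <- which(alloc < capacities)
      if (length(room) == 0) break
      alloc[room[1]] <- alloc[room[1]] + 1
      spill <- spill - 1
    }
  }
  as.integer(alloc)
}

#' Simulate a complete synthetic world
#'
#' Partitions genes across species, plants true motifs (same-species source/
#' target pairs with a GI edge at the configured per-activity or global
#' rate), draws random-pair negatives with the configured accidental-edge
#' rate, adds background edges (Erdős–Rényi within each species), builds
#' homolog clusters (a singleton per gene plus cross-species pairs at
#' `homolog_cluster_rate`), replicates motif-planted edges between homologs
#' at `gi_conservation_rate`, mirrors planted GI pairs into a PPI edge list
#' at `p_ppi_given_gi`, and synthesises aliases. Everything is reproducible
#' from the config seed and every planting decision is recorded in
#' `ground_truth`.
#'
#' @param config A [world_config()].
#' @return An object of class `synthetic_world`: a list with `gi_edges`,
#'   `ppi_edges`, `alias_table`, `homolog_records`, `positive_motifs`,
#'   `negative_pairs`, `ground_truth`, `config`.
#' @export
simulate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, simulate_world_impl(config))
}

simulate_world_impl <- function(cfg) {
  species <- sprintf("sp%d", seq_len(cfg$n_species))
  per <- rep(cfg$n_genes %/% cfg$n_species, cfg$n_species)
  per[seq_len(cfg$n_genes %% cfg$n_species)] <- per[seq_len(cfg$n_genes %% cfg$n_species)] + 1
  genes_by_sp <- lapply(seq_len(cfg$n_species), function(i) {
    sprintf("%s.g%05d", species[i], seq_len(per[i]))
  })
  names(genes_by_sp) <- species
  all_genes <- unlist(genes_by_sp, use.names = FALSE)
  species_of <- setNames(rep(species, per), all_genes)
  capacities <- vapply(genes_by_sp, function(g) possible_pair_count(length(g)), numeric(1))

  mix <- cfg$activity_mix / sum(cfg$activity_mix)

  # ---- positive motifs ----
  pos_alloc <- allocate_pairs(cfg$n_positive_motifs, capacities)
  pos_list <- lapply(seq_along(species), function(i) {
    if (pos_alloc[i] == 0) return(NULL)
    p <- sample_distinct_pairs(genes_by_sp[[i]], pos_alloc[i])
    p$species <- species[i]
    p
  })
  pos <- do.call(rbind, pos_list)
  if (is.null(pos)) {
    pos <- data.frame(source = character(), target = character(),
                      species = character(), stringsAsFactors = FALSE)
  }
  n_pos <- nrow(pos)
  activity <- if (n_pos > 0) {
    sample(names(mix), n_pos, replace = TRUE, prob = mix)
  } else {
    character(0)
  }
  rate_of <- function(act) {
    r <- cfg$per_activity_gi_rates
    if (!is.null(r) && act %in% names(r)) r[[act]] else cfg$p_pos_gi_edge
  }
  planted <- if (n_pos > 0) {
    stats::runif(n_pos) < vapply(activity, rate_of, numeric(1))
  } else {
    logical(0)
  }

  # ---- negative pairs ----
  neg_alloc <- allocate_pairs(cfg$n_negative_pairs, capacities)
  neg_list <- lapply(seq_along(species), function(i) {
    if (neg_alloc[i] == 0) return(NULL)
    p <- sample_distinct_pairs(genes_by_sp[[i]], neg_alloc[i])
    p$species <- species[i]
    p
  })
  neg <- do.call(rbind, neg_list)
  if (is.null(neg)) {
    neg <- data.frame(source = character(), target = character(),
                      species = character(), stringsAsFactors = FALSE)
  }
  n_neg <- nrow(neg)
  collision <- if (n_neg > 0) stats::runif(n_neg) < cfg$p_neg_gi_edge else logical(0)
  neg_activity <- if (n_neg > 0) {
    sample(names(mix), n_neg, replace = TRUE, prob = mix)
  } else {
    character(0)
  }

  # ---- homolog clusters: a singleton per gene + cross-species merges ----
  cluster_of <- setNames(sprintf("hc%05d", seq_along(all_genes)), all_genes)
  k_cross <- floor(cfg$homolog_cluster_rate * cfg$n_genes / 2)
  if (cfg$n_species >= 2 && k_cross > 0) {
    pools <- lapply(genes_by_sp, sample)  # shuffled, consumed front-to-back
    cursor <- setNames(rep(1L, cfg$n_species), species)
    for (step in seq_len(k_cross)) {
      open <- species[cursor[species] <= per]
      if (length(open) < 2) break
      sp_pair <- sample(open, 2)
      g <- pools[[sp_pair[1]]][cursor[sp_pair[1]]]
      h <- pools[[sp_pair[2]]][cursor[sp_pair[2]]]
      cursor[sp_pair[1]] <- cursor[sp_pair[1]] + 1L
      cursor[sp_pair[2]] <- cursor[sp_pair[2]] + 1L
      cluster_of[h] <- cluster_of[g]
    }
  }
  homolog_records <- data.frame(
    cluster_id = unname(cluster_of),
    taxon = unname(species_of[names(cluster_of)]),
    gene_id = names(cluster_of),
    symbol = toupper(names(cluster_of)),
    stringsAsFactors = FALSE
  )

  # ---- conserved copies of motif-planted edges ----
  homolog_partner <- function(g) {
    members <- names(cluster_of)[cluster_of == cluster_of[g]]
    members[members != g]
  }
  conserved <- logical(n_pos)
  cons_edges <- list()
  if (n_pos > 0 && cfg$gi_conservation_rate > 0 && cfg$n_species >= 2) {
    for (i in which(planted)) {
      pa <- homolog_partner(pos$source[i])
      pb <- homolog_partner(pos$target[i])
      if (length(pa) == 0 || length(pb) == 0) next
      common <- intersect(species_of[pa], species_of[pb])
      common <- setdiff(common, pos$species[i])
      if (length(common) == 0) next
      if (stats::runif(1) < cfg$gi_conservation_rate) {
        sp2 <- if (length(common) == 1) common else sample(common, 1)
        a2 <- pa[species_of[pa] == sp2][1]
        b2 <- pb[species_of[pb] == sp2][1]
        conserved[i] <- TRUE
        cons_edges[[length(cons_edges) + 1]] <- data.frame(
          gene_a = a2, gene_b = b2, species = sp2,
          source_db = "synthetic_conserved", interaction_kind = "genetic",
          stringsAsFactors = FALSE
        )
      }
    }
  }

  # ---- background edges (Erdős–Rényi within each species) ----
  bg_list <- lapply(seq_along(species), function(i) {
    npairs <- capacities[i]
    if (cfg$background_edge_prob == 0 || npairs == 0) return(NULL)
    cnt <- stats::rbinom(1, size = npairs, prob = cfg$background_edge_prob)
    if (cnt == 0) return(NULL)
    p <- sample_distinct_pairs(genes_by_sp[[i]], cnt)
    data.frame(gene_a = p$source, gene_b = p$target, species = species[i],
               source_db = "synthetic_background", interaction_kind = "genetic",
               stringsAsFactors = FALSE)
  })

  planted_edge_df <- function(sel, df, db) {
    if (sum(sel) == 0) return(NULL)
    data.frame(
      gene_a = df$source[sel], gene_b = df$target[sel],
      species = df$species[sel], source_db = db,
      interaction_kind = "genetic", stringsAsFactors = FALSE
    )
  }
  gi_parts <- c(
    list(planted_edge_df(planted, pos, "synthetic"),
         planted_edge_df(collision, neg, "synthetic_collision")),
    cons_edges, bg_list
  )
  gi_parts <- gi_parts[!vapply(gi_parts, is.null, logical(1))]
  gi_edges <- if (length(gi_parts) > 0) {
    canonicalize_edges(do.call(rbind, gi_parts))
  } else {
    empty_edges()
  }

  # ---- PPI edges mirroring planted GI pairs ----
  ppi_sel <- if (n_pos > 0) planted & (stats::runif(n_pos) < cfg$p_ppi_given_gi) else logical(0)
  ppi_df <- planted_edge_df(ppi_sel, pos, "synthetic")
  ppi_edges <- if (!is.null(ppi_df)) {
    ppi_df$interaction_kind <- "physical"
    canonicalize_edges(ppi_df)
  } else {
    empty_edges()
  }

  # ---- aliases ----
  n_alias <- round(cfg$alias_rate * cfg$n_genes)
  aliased <- if (n_alias > 0) sample(all_genes, n_alias) else character(0)
  alias_table <- if (length(aliased) > 0) {
    data.frame(
      canonical_id = aliased,
      alias = paste0(toupper(aliased), ".A1"),
      species = unname(species_of[aliased]),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(canonical_id = character(), alias = character(),
               species = character(), stringsAsFactors = FALSE)
  }
  alias_of <- setNames(alias_table$alias, alias_table$canonical_id)

  # motifs refer to a gene by its alias half of the time (when it has one)
  display_name <- function(g) {
    if (!is.na(alias_of[g]) && stats::runif(1) < 0.5) unname(alias_of[g]) else g
  }
  src_names <- vapply(pos$source, display_name, character(1), USE.NAMES = FALSE)
  tgt_names <- vapply(pos$target, display_name, character(1), USE.NAMES = FALSE)

  sub_activity <- rep("", n_pos)
  mod <- activity == "modifies"
  if (any(mod)) {
    sub_activity[mod] <- sample(c("phosphorylates", "cleaves"), sum(mod),
                                replace = TRUE, prob = c(0.8, 0.2))
  }
  sequences <- if (n_pos > 0) {
    vapply(seq_len(n_pos), function(i) paste(sample(AA, 8, replace = TRUE), collapse = ""),
           character(1))
  } else {
    character(0)
  }
  positive_motifs <- data.frame(
    motif_id = sprintf("m%05d", seq_len(n_pos)),
    sequence = sequences,
    source_protein = src_names,
    target_protein = tgt_names,
    activity = activity,
    sub_activity = sub_activity,
    stringsAsFactors = FALSE
  )
  positive_motifs$external_flags <- replicate(n_pos, logical(0), simplify = FALSE)
  class(positive_motifs) <- c("motif_predictions", "data.frame")

  negative_pairs <- data.frame(
    pair_id = sprintf("neg%05d", seq_len(n_neg)),
    source = neg$source,
    target = neg$target,
    label = rep("negative", n_neg),
    activity = neg_activity,
    stringsAsFactors = FALSE
  )

  ground_truth <- list(
    positives = data.frame(
      motif_id = positive_motifs$motif_id,
      source_gene = pos$source, target_gene = pos$target,
      species = pos$species, activity = activity,
      planted_edge = planted, conserved_copy = conserved, ppi_edge = ppi_sel,
      stringsAsFactors = FALSE
    ),
    negatives = data.frame(
      pair_id = negative_pairs$pair_id,
      source = neg$source, target = neg$target,
      collision_edge = collision,
      stringsAsFactors = FALSE
    )
  )

  structure(
    list(
      gi_edges = gi_edges, ppi_edges = ppi_edges, alias_table = alias_table,
      homolog_records = homolog_records, positive_motifs = positive_motifs,
      negative_pairs = negative_pairs, ground_truth = ground_truth,
      config = cfg
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    paste0("<synthetic_world> %d genes / %d species | %d GI edges, %d PPI edges | ",
           "%d positive motifs (%d with planted edge), %d negative pairs (%d collisions)\n"),
    x$config$n_genes, x$config$n_species, nrow(x$gi_edges), nrow(x$ppi_edges),
    nrow(x$positive_motifs), sum(x$ground_truth$positives$planted_edge),
    nrow(x$negative_pairs), sum(x$ground_truth$negatives$collision_edge)
  ))
  invisible(x)
}

#' Write a synthetic world to disk in the package's file formats
#'
#' Emits `gi_edges.tsv` and `ppi_edges.tsv` (generic edge-list dialect),
#' `aliases.tsv`, `homologene.data` (HomoloGene-style flat file),
#' `predictions.tsv` (minimotif table) and `negatives.tsv` (minimotif-table
#' schema, so it reads back through [read_minimotif_table()]). Output is
#' byte-deterministic for a given world.
#'
#' @param world A `synthetic_world`.
#' @param directory Output directory (created if missing).
#' @return Named character vector of the six paths written.
#' @export
world_to_files <- function(world, directory) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_io(sprintf("cannot create directory %s", directory))
  }
  paths <- c(
    gi_edges = file.path(directory, "gi_edges.tsv"),
    ppi_edges = file.path(directory, "ppi_edges.tsv"),
    aliases = file.path(directory, "aliases.tsv"),
    homologene = file.path(directory, "homologene.data"),
    predictions = file.path(directory, "predictions.tsv"),
    negatives = file.path(directory, "negatives.tsv")
  )
  write_generic_edges <- function(df, path) {
    lines <- c(
      "# gene_a\tgene_b\tspecies\tkind",
      if (nrow(df) > 0) {
        paste(df$gene_a, df$gene_b, df$species, df$interaction_kind, sep = "\t")
      }
    )
    writeLines(lines, path)
  }
  write_generic_edges(world$gi_edges, paths[["gi_edges"]])
  write_generic_edges(world$ppi_edges, paths[["ppi_edges"]])
  writeLines(
    c("# canonical_id\talias\tspecies",
      if (nrow(world$alias_table) > 0) {
        paste(world$alias_table$canonical_id, world$alias_table$alias,
              world$alias_table$species, sep = "\t")
      }),
    paths[["aliases"]]
  )
  writeLines(
    if (nrow(world$homolog_records) > 0) {
      paste(world$homolog_records$cluster_id, world$homolog_records$taxon,
            world$homolog_records$gene_id, world$homolog_records$symbol,
            sep = "\t")
    } else {
      character(0)
    },
    paths[["homologene"]]
  )
  preds <- world$positive_motifs
  write.table(
    preds[, c("motif_id", "sequence", "source_protein", "target_protein",
              "activity", "sub_activity")],
    paths[["predictions"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  negs <- data.frame(
    motif_id = world$negative_pairs$pair_id,
    source_protein = world$negative_pairs$source,
    target_protein = world$negative_pairs$target,
    activity = world$negative_pairs$activity,
    stringsAsFactors = FALSE
  )
  write.table(negs, paths[["negatives"]], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
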
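# Readers and writers for every file format the toolkit touches. All
# heterogeneous interaction sources are normalised into one canonical edge
# table so the filters never see source-specific quirks.

ACTIVITIES <- c("binds", "modifies", "traffics")

empty_edges <- function() {
  data.frame(
    gene_a = character(), gene_b = character(), species = character(),
    source_db = character(), interaction_kind = character(),
    stringsAsFactors = FALSE
  )
}

# Canonicalise an edge table: lower-case ids, lexicographic pair order,
# deduplicate on (pair, interaction_kind) keeping the first occurrence.
canonicalize_edges <- function(df) {
  if (nrow(df) == 0) {
    return(empty_edges())
  }
  a <- canonical_id(df$gene_a)
  b <- canonical_id(df$gene_b)
  df$gene_a <- pmin(a, b)
  df$gene_b <- pmax(a, b)
  df$species <- canonical_id(df$species)
  df$interaction_kind <- canonical_id(df$interaction_kind)
  key <- paste(df$gene_a, df$gene_b, df$interaction_kind, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read an interaction edge list
#'
#' Parses a tab-separated interaction file into the canonical undirected edge
#' table used throughout the package. Two dialects are supported:
#'
#' * `"generic"`: headerless TSV with columns `gene_a`, `gene_b` and optional
#'   `species` and `kind` ("genetic" or "physical"); lines starting with `#`
#'   are skipped.
#' * `"biogrid_tab"`: header-bearing TSV in the style of BioGRID TAB exports;
#'   only the columns `Official Symbol Interactor A`/`B`, `Experimental
#'   System Type` and (when present) `Organism Interactor A` are used.
#'
#' Edges are undirected: each pair is stored lexicographically ordered and
#' duplicates (in either orientation) are collapsed. Identifiers are compared
#' case-insensitively after trimming whitespace. Rows with a blank interactor
#' are skipped with a warning; self-loop edges are retained (a motif whose
#' source equals its target is legal input) and their count is reported via
#' [message()].
#'
#' @param path Path to the file.
#' @param dialect `"generic"` or `"biogrid_tab"`.
#' @param kind Optional filter: keep only edges whose `interaction_kind`
#'   equals this value (e.g. `"genetic"`).
#' @return A data frame with columns `gene_a`, `gene_b`, `species`,
#'   `source_db`, `interaction_kind`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("cdc28\tcln2", "CLN2\tCDC28", "cdc28\tswi4"), f)
#' read_edge_list(f) # two unique undirected edges
#' @export
read_edge_list <- function(path, dialect = c("generic", "biogrid_tab"), kind = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_io(sprintf("edge list file not found: %s", path))
  }
  df <- if (dialect == "generic") {
    read_edge_list_generic(path)
  } else {
    read_edge_list_biogrid(path)
  }
  blank <- trimws(df$gene_a) == "" | trimws(df$gene_b) == ""
  if (any(blank)) {
    warning(sprintf("skipped %d row(s) with blank interactors in %s", sum(blank), path))
    df <- df[!blank, , drop = FALSE]
  }
  df <- canonicalize_edges(df)
  n_self <- sum(df$gene_a == df$gene_b)
  if (n_self > 0) {
    message(sprintf("read_edge_list: retained %d self-loop edge(s)", n_self))
  }
  if (!is.null(kind)) {
    df <- df[df$interaction_kind == canonical_id(kind), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

read_edge_list_generic <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(empty_edges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 2)) {
    abort_format(sprintf(
      "generic edge list %s: row %d has fewer than 2 tab-separated columns",
      path, which(ncols < 2)[1]
    ))
  }
  get_col <- function(i, default = "") {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, character(1))
  }
  data.frame(
    gene_a = get_col(1),
    gene_b = get_col(2),
    species = get_col(3),
    source_db = "generic",
    interaction_kind = ifelse(nzchar(get_col(4)), get_col(4), "genetic"),
    stringsAsFactors = FALSE
  )
}

read_edge_list_biogrid <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
  required <- c(
    "Official Symbol Interactor A",
    "Official Symbol Interactor B",
    "Experimental System Type"
  )
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "biogrid_tab file %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  species <- if ("Organism Interactor A" %in% names(tab)) {
    as.character(tab[["Organism Interactor A"]])
  } else {
    ""
  }
  if (nrow(tab) == 0) {
    return(empty_edges())
  }
  data.frame(
    gene_a = as.character(tab[[required[1]]]),
    gene_b = as.character(tab[[required[2]]]),
    species = species,
    source_db = "biogrid",
    interaction_kind = as.character(tab[[required[3]]]),
    stringsAsFactors = FALSE
  )
}

#' Read a minimotif prediction table
#'
#' Reads a header-bearing TSV of putative minimotifs. Required columns are
#' `source_protein` (the protein containing the motif) and `target_protein`
#' (the protein that binds/modifies/traffics it). Optional columns:
#' `motif_id`, `sequence`, `activity` (one of `binds`, `modifies`,
#' `traffics`), `sub_activity`, and any number of boolean columns prefixed
#' `flag_` holding precomputed verdicts of external filters (for example a
#' frequency-score or cellular-function filter); these land in the
#' `external_flags` list-column with the prefix stripped.
#'
#' A missing `activity` defaults to `"binds"` with a warning. An activity
#' token outside the closed vocabulary is a validation error naming the
#' offending rows.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `motif_predictions` with columns `motif_id`,
#'   `sequence`, `source_protein`, `target_protein`, `activity`,
#'   `sub_activity` and list-column `external_flags`.
#' @export
read_minimotif_table <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("minimotif table not found: %s", path))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, quote = "")
  required <- c("source_protein", "target_protein")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "minimotif table %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  n <- nrow(tab)
  motif_id <- if ("motif_id" %in% names(tab)) as.character(tab$motif_id) else sprintf("m%d", seq_len(n))
  sequence <- if ("sequence" %in% names(tab)) as.character(tab$sequence) else rep("", n)
  sub_activity <- if ("sub_activity" %in% names(tab)) as.character(tab$sub_activity) else rep("", n)
  if ("activity" %in% names(tab)) {
    activity <- trimws(tolower(as.character(tab$activity)))
    blank <- is.na(activity) | activity == ""
    if (any(blank)) {
      warning(sprintf("%d row(s) missing activity; defaulting to 'binds'", sum(blank)))
      activity[blank] <- "binds"
    }
    bad <- which(!activity %in% ACTIVITIES)
    if (length(bad) > 0) {
      shown <- head(bad, 10)
      abort_validation(sprintf(
        "unrecognized activity token in %d row(s) of %s (rows %s); allowed: %s",
        length(bad), path, paste(shown, collapse = ", "),
        paste(ACTIVITIES, collapse = ", ")
      ))
    }
  } else {
    warning("minimotif table has no 'activity' column; defaulting to 'binds'")
    activity <- rep("binds", n)
  }
  flag_cols <- grep("^flag_", names(tab), value = TRUE)
  external_flags <- lapply(seq_len(n), function(i) {
    flags <- vapply(flag_cols, function(cl) parse_flag(tab[[cl]][i]), logical(1))
    names(flags) <- sub("^flag_", "", flag_cols)
    flags
  })
  out <- data.frame(
    motif_id = motif_id,
    sequence = sequence,
    source_protein = as.character(tab$source_protein),
    target_protein = as.character(tab$target_protein),
    activity = activity,
    sub_activity = sub_activity,
    stringsAsFactors = FALSE
  )
  out$external_flags <- external_flags
  blank <- trimws(out$source_protein) == "" | trimws(out$target_protein) == ""
  if (any(blank)) {
    abort_validation(sprintf(
      "minimotif table %s: blank source/target protein in row(s) %s",
      path, paste(head(which(blank), 10), collapse = ", ")
    ))
  }
  class(out) <- c("motif_predictions", "data.frame")
  out
}

parse_flag <- function(v) {
  if (is.logical(v)) return(isTRUE(v))
  if (is.numeric(v)) return(!is.na(v) && v != 0)
  tolower(trimws(as.character(v))) %in% c("1", "true", "t", "yes", "y")
}

#' Read a HomoloGene-style flat file
#'
#' Headerless TSV with columns (cluster id, taxon id, gene id, gene symbol,
#' further columns ignored). Rows with fewer than four columns are a format
#' error. Duplicate (cluster, gene) pairs are collapsed.
#'
#' @param path Path to the flat file.
#' @return A data frame with columns `cluster_id`, `taxon`, `gene_id`,
#'   `symbol`; gene ids are canonicalised (lower case, trimmed).
#' @export
read_homologene <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("homologene file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(
      cluster_id = character(), taxon = character(),
      gene_id = character(), symbol = character(), stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 4)
  if (length(short) > 0) {
    abort_format(sprintf(
      "homologene file %s: row %d has fewer than 4 columns", path, short[1]
    ))
  }
  df <- data.frame(
    cluster_id = vapply(fields, `[[`, character(1), 1),
    taxon = vapply(fields, `[[`, character(1), 2),
    gene_id = canonical_id(vapply(fields, `[[`, character(1), 3)),
    symbol = vapply(fields, `[[`, character(1), 4),
    stringsAsFactors = FALSE
  )
  df <- df[!duplicated(paste(df$cluster_id, df$gene_id, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a gene alias table
#'
#' Headerless TSV with columns (canonical id, alias, optional species);
#' `#` comment lines are skipped. Records mapping an alias to itself
#' (case-insensitively) are dropped, since every canonical id is implicitly
#' its own alias.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `canonical_id`, `alias`, `species`.
#' @export
read_alias_table <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("alias table not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(
      canonical_id = character(), alias = character(), species = character(),
      stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2)
  if (length(short) > 0) {
    abort_format(sprintf(
      "alias table %s: row %d has fewer than 2 columns", path, short[1]
    ))
  }
  df <- data.frame(
    canonical_id = canonical_id(vapply(fields, `[[`, character(1), 1)),
    alias = vapply(fields, `[[`, character(1), 2),
    species = vapply(fields, function(f) if (length(f) >= 3) f[[3]] else "", character(1)),
    stringsAsFactors = FALSE
  )
  df <- df[canonical_id(df$alias) != df$canonical_id, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a filter report
#'
#' Serialises filter decisions as a wide TSV: one row per motif, one boolean
#' column per filter plus one `<filter>_witness` column listing the
#' supporting edge(s) as `geneA--geneB;...` (empty when the motif failed).
#' The report round-trips losslessly through [read_filter_report()].
#'
#' @param decisions A decision table as returned by [apply_filters()].
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_filter_report <- function(decisions, path) {
  motifs <- unique(decisions$motif_id)
  filters <- unique(decisions$filter)
  wide <- data.frame(motif_id = motifs, stringsAsFactors = FALSE)
  for (f in filters) {
    sub <- decisions[decisions$filter == f, , drop = FALSE]
    idx <- match(motifs, sub$motif_id)
    wide[[f]] <- sub$passed[idx]
    wide[[paste0(f, "_witness")]] <- ifelse(is.na(idx), "", sub$witness[idx])
  }
  ok <- tryCatch({
    write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort_io(sprintf("cannot write filter report to %s", path))
  }
  invisible(path)
}

#' Read a filter report back into a decision table
#'
#' Inverse of [write_filter_report()]; the free-text `note` field is not
#' stored in reports and comes back empty.
#'
#' @param path Path to a report written by [write_filter_report()].
#' @return A decision data frame with columns `motif_id`, `filter`,
#'   `passed`, `witness`, `note`.
#' @export
read_filter_report <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("filter report not found: %s", path))
  }
  wide <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, quote = "")
  filters <- setdiff(names(wide), c("motif_id", grep("_witness$", names(wide), value = TRUE)))
  rows <- lapply(filters, function(f) {
    data.frame(
      motif_id = as.character(wide$motif_id),
      filter = f,
      passed = as.logical(wide[[f]]),
      witness = {
        w <- wide[[paste0(f, "_witness")]]
        if (is.null(w)) "" else ifelse(is.na(w), "", as.character(w))
      },
      note = "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      motif_id = character(), filter = character(), passed = logical(),
      witness = character(), note = character(), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
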
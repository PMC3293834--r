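# Evaluation harness: random-pair negative sets, sensitivity / selectivity /
# discrimination ratio, ROC/AUC, combination gains, activity stratification.
#
# NOTE ON TERMINOLOGY: "selectivity" here is the percentage of true
# NEGATIVES that a filter ACCEPTS — an empirical false-positive rate, so
# LOWER is better. It is not specificity. The discrimination ratio
# DR = sensitivity / selectivity is favorable when > 1. This nonstandard
# usage is kept deliberately because the whole harness (and the DR) is
# defined around it; misreading selectivity as specificity inverts every
# conclusion.

#' Number of possible unordered gene pairs
#'
#' @param n_genes Non-negative gene count.
#' @return `n_genes * (n_genes - 1) / 2`, as a double (exact for any
#'   realistic genome size).
#' @examples
#' possible_pair_count(25000) # ~312 million
#' @export
possible_pair_count <- function(n_genes) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 0) {
    abort_validation("possible_pair_count: n_genes must be a single non-negative number")
  }
  n <- as.numeric(n_genes)
  n * (n - 1) / 2
}

# Sample `n` distinct unordered pairs (i < j) of elements of `genes`,
# uniformly, reproducibly under the current RNG state. Uses rejection
# sampling, falling back to full enumeration when n is a large fraction of
# the pair space. `forbidden` is a character vector of pair keys to avoid.
sample_distinct_pairs <- function(genes, n, forbidden = character(0)) {
  m <- length(genes)
  total <- possible_pair_count(m)
  avail <- total - length(forbidden)
  if (n > avail) {
    abort_validation(sprintf(
      "requested %d pairs but only %.0f distinct pairs are available", n, avail
    ))
  }
  if (n == 0) {
    return(data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  forbidden_env <- new.env(hash = TRUE, parent = emptyenv())
  for (k in forbidden) assign(k, TRUE, envir = forbidden_env)

  if (n > 0.4 * avail || m <= 60) {
    # dense regime: enumerate, drop forbidden, take a random subset
    idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    keys <- pair_key(genes[idx[, 1]], genes[idx[, 2]])
    keep <- !keys %in% forbidden
    idx <- idx[keep, , drop = FALSE]
    pick <- sample.int(nrow(idx), n)
    chosen <- idx[pick, , drop = FALSE]
    return(data.frame(source = genes[chosen[, 1]], target = genes[chosen[, 2]],
                      stringsAsFactors = FALSE))
  }

  seen <- new.env(hash = TRUE, parent = emptyenv())
  src <- character(n); tgt <- character(n)
  got <- 0L
  while (got < n) {
    draw <- max(2L * (n - got), 100L)
    i <- sample.int(m, draw, replace = TRUE)
    j <- sample.int(m, draw, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    for (k in seq_along(i)) {
      key <- pair_key(genes[i[k]], genes[j[k]])
      if (exists(key, envir = seen, inherits = FALSE)) next
      if (exists(key, envir = forbidden_env, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      got <- got + 1L
      src[got] <- genes[i[k]]
      tgt[got] <- genes[j[k]]
      if (got == n) break
    }
  }
  data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
}

#' Generate random gene pairs as a negative set
#'
#' Randomly pairs genes to form a negative benchmark set: because known GIs
#' are a negligible fraction of all possible pairs, a uniformly random pair
#' is almost surely a non-interaction. Pairs are distinct (no repeats,
#' `source != target`) and fully reproducible from `seed`. With
#' `policy = "exclude_known"` pairs present in `known` (an edge data frame, a
#' `gi_network`, or a character vector of `"a--b"` keys) are rejected, for
#' stricter benchmarking.
#'
#' @param genes Character vector of at least two gene ids.
#' @param n Number of pairs to draw (error if it exceeds the number of
#'   distinct pairs available).
#' @param seed Integer RNG seed.
#' @param policy `"pure_random"` (default) or `"exclude_known"`.
#' @param known Known interactions to exclude (only used by
#'   `"exclude_known"`).
#' @return A data frame with columns `source`, `target`, `label`
#'   (`"negative"`).
#' @export
generate_negative_pairs <- function(genes, n, seed,
                                    policy = c("pure_random", "exclude_known"),
                                    known = NULL) {
  policy <- match.arg(policy)
  genes <- unique(canonical_id(genes))
  if (length(genes) < 2) {
    abort_validation("generate_negative_pairs: need at least 2 genes")
  }
  if (n < 0) abort_validation("generate_negative_pairs: n must be non-negative")
  forbidden <- character(0)
  if (policy == "exclude_known" && !is.null(known)) {
    forbidden <- if (inherits(known, "gi_network")) {
      known$edge_meta$pair
    } else if (is.data.frame(known)) {
      pair_key(canonical_id(known$gene_a), canonical_id(known$gene_b))
    } else {
      as.character(known)
    }
    forbidden <- unique(forbidden)
  }
  pairs <- with_seed(seed, sample_distinct_pairs(genes, n, forbidden))
  pairs$label <- rep("negative", nrow(pairs))
  pairs
}

#' Discrimination ratio
#'
#' Sensitivity divided by selectivity (both in percent). Reported to one
#' decimal by default, matching how the ratio is conventionally displayed;
#' use `digits = NULL` for full precision. A selectivity of zero yields
#' `Inf`.
#'
#' @param sensitivity,selectivity Percentages in `[0, 100]`.
#' @param digits Decimal places for rounding (default 1), or `NULL`.
#' @return The ratio (possibly `Inf`).
#' @export
discrimination_ratio <- function(sensitivity, selectivity, digits = 1) {
  if (selectivity == 0) return(Inf)
  dr <- sensitivity / selectivity
  if (is.null(digits)) dr else round(dr, digits)
}

#' Evaluate a filter against labelled verdicts
#'
#' Computes the harness's three headline metrics from the filter's verdicts
#' on a true (positive) set and a random-pair (negative) set:
#' sensitivity = percent of positives retained; selectivity = percent of
#' negatives retained (an empirical false-positive rate — lower is better);
#' discrimination ratio DR = sensitivity / selectivity, favorable above 1.
#'
#' @param pos_passed Logical vector: verdicts on the positive set.
#' @param neg_passed Logical vector: verdicts on the negative set.
#' @param filter_name Label carried into the report.
#' @return An object of class `eval_report`: a list with `filter_name`,
#'   `n_pos`, `n_neg`, `sensitivity`, `selectivity` (full-precision
#'   percentages), `dr`, and `dr_infinite`.
#' @export
evaluate_filter <- function(pos_passed, neg_passed, filter_name = "filter") {
  if (length(pos_passed) == 0 || length(neg_passed) == 0) {
    abort_validation("evaluate_filter: need at least one positive and one negative verdict")
  }
  sens <- 100 * mean(pos_passed)
  sel <- 100 * mean(neg_passed)
  structure(
    list(
      filter_name = filter_name,
      n_pos = length(pos_passed),
      n_neg = length(neg_passed),
      sensitivity = sens,
      selectivity = sel,
      dr = if (sel > 0) sens / sel else Inf,
      dr_infinite = sel == 0
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  dr <- if (x$dr_infinite) "Inf (no negatives accepted)" else sprintf("%.1f", x$dr)
  cat(sprintf(
    "<eval_report> %s: sensitivity %.1f%% (n=%d), selectivity %.1f%% (n=%d), DR %s\n",
    x$filter_name, x$sensitivity, x$n_pos, x$selectivity, x$n_neg, dr
  ))
  invisible(x)
}

#' Percent sensitivity gain of a combined filter over a base filter
#'
#' @param base_pass_count Motifs passing the base filter (> 0).
#' @param combined_pass_count Motifs passing the combination (>= base).
#' @param digits Decimal places for rounding (default 1), or `NULL`.
#' @return `100 * (combined - base) / base`.
#' @examples
#' sensitivity_gain(871, 944) # union of two complementary filters
#' @export
sensitivity_gain <- function(base_pass_count, combined_pass_count, digits = 1) {
  if (base_pass_count <= 0) {
    abort_validation("sensitivity_gain: base_pass_count must be positive")
  }
  if (combined_pass_count < base_pass_count) {
    abort_validation("sensitivity_gain: combined_pass_count must be >= base_pass_count")
  }
  g <- 100 * (combined_pass_count - base_pass_count) / base_pass_count
  if (is.null(digits)) g else round(g, digits)
}

#' Graded genetic-interaction evidence score
#'
#' A deterministic, monotone score for ranking predictions by GI support,
#' used to draw ROC curves: `1 / (1 + d)` where `d` is the shortest-path
#' distance in the GI network between the resolved source and target gene
#' sets (0 for disconnected or unresolved pairs), plus a tie-breaking bonus
#' `1e-8 * min(k, 100)` where `k` is the number of resolved candidate pairs
#' achieving distance `d`. The bonus is strictly smaller than any distance
#' gap for graphs of diameter below ~1000, so score ordering always agrees
#' with distance ordering.
#'
#' @param predictions A `motif_predictions` data frame (or any data frame
#'   with `source_protein` and `target_protein` columns).
#' @param network A `gi_network`.
#' @return Numeric vector of scores in `[0, 1]`, one per prediction.
#' @export
gi_evidence_score <- function(predictions, network) {
  stopifnot(inherits(network, "gi_network"))
  src <- as.character(predictions$source_protein)
  tgt <- as.character(predictions$target_protein)
  scores <- numeric(length(src))
  for (i in seq_along(src)) {
    s <- intersect(resolve_gene(network, src[i]), network$nodes)
    t <- intersect(resolve_gene(network, tgt[i]), network$nodes)
    if (length(s) == 0 || length(t) == 0) next
    d <- igraph::distances(network$graph, v = s, to = t)
    dm <- suppressWarnings(min(d))
    if (!is.finite(dm)) next
    k <- sum(d == dm)
    scores[i] <- 1 / (1 + dm) + 1e-8 * min(k, 100)
  }
  scores
}

#' Empirical ROC curve and AUC
#'
#' Sweeps a "pass if score >= threshold" rule over the distinct observed
#' scores (ties collapse to one threshold), anchored at (0,0) and (1,1),
#' and integrates by the trapezoidal rule. The resulting AUC equals the
#' Mann-Whitney estimate of P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores Numeric scores, higher meaning more supported.
#' @param labels Positive-class indicator: logical, 0/1, or
#'   `"positive"`/`"negative"` strings.
#' @return A list with `roc` (data frame of `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  lab <- if (is.logical(labels)) {
    labels
  } else if (is.numeric(labels)) {
    labels != 0
  } else {
    canonical_id(labels) == "positive"
  }
  if (length(scores) != length(lab)) {
    abort_validation("roc_auc: scores and labels differ in length")
  }
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0) {
    abort_validation("roc_auc: both classes must be present")
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- numeric(length(thresholds))
  fpr <- numeric(length(thresholds))
  cum_tp <- 0; cum_fp <- 0
  for (i in seq_along(thresholds)) {
    at <- scores == thresholds[i]
    cum_tp <- cum_tp + sum(lab & at)
    cum_fp <- cum_fp + sum(!lab & at)
    tpr[i] <- cum_tp / n_pos
    fpr[i] <- cum_fp / n_neg
  }
  roc <- data.frame(
    fpr = c(0, fpr),
    tpr = c(0, tpr),
    threshold = c(Inf, thresholds)
  )
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Stratify filter metrics by activity label
#'
#' Splits positive and negative verdicts by an activity (or sub-activity)
#' label and evaluates the filter within each stratum present among the
#' positives. Strata lacking negatives are skipped with a warning; strata
#' with fewer than `min_n` positives are reported but flagged `low_n`.
#'
#' @param pos Data frame with columns `passed` (logical) and the
#'   stratification key for the positive set.
#' @param neg Same-shaped data frame for the negative set.
#' @param key `"activity"` or `"sub_activity"`.
#' @param min_n Minimum stratum size before a low-n flag (default 5).
#' @param filter_name Label carried into the reports.
#' @return Named list of `eval_report` objects, one per stratum; each
#'   carries a logical attribute `low_n`.
#' @export
stratify_metrics <- function(pos, neg, key = c("activity", "sub_activity"),
                             min_n = 5, filter_name = "filter") {
  key <- match.arg(key)
  if (!key %in% names(pos) || !key %in% names(neg)) {
    abort_validation(sprintf("stratify_metrics: column '%s' missing", key))
  }
  labels <- unique(as.character(pos[[key]]))
  labels <- labels[nzchar(labels)]
  out <- list()
  for (lb in labels) {
    p <- pos$passed[pos[[key]] == lb]
    ng <- neg$passed[neg[[key]] == lb]
    if (length(ng) == 0) {
      warning(sprintf("stratum '%s' has no negatives; skipped", lb))
      next
    }
    rep_ <- evaluate_filter(p, ng, filter_name = sprintf("%s[%s=%s]", filter_name, key, lb))
    attr(rep_, "low_n") <- length(p) < min_n
    if (length(p) < min_n) {
      warning(sprintf("stratum '%s' has only %d positives (min_n = %d)", lb, length(p), min_n))
    }
    out[[lb]] <- rep_
  }
  out
}
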
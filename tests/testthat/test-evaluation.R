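test_that("pair counting matches brute-force enumeration", {
  expect_equal(possible_pair_count(2), 1)
  expect_equal(possible_pair_count(0), 0)
  set.seed(67)
  for (n in sample(2:10, 5)) {
    expect_equal(possible_pair_count(n), ncol(combn(n, 2)))
  }
  expect_error(possible_pair_count(-1), class = "gimotif_validation_error")
})

test_that("sensitivity, selectivity and DR come from direct counting", {
  # perfect filter: everything retained among positives, nothing among negatives
  rp <- evaluate_filter(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(rp$sensitivity, 100)
  expect_equal(rp$selectivity, 0)
  expect_true(rp$dr_infinite)

  set.seed(71)
  for (rep in 1:10) {
    pos <- runif(40) < 0.5
    neg <- runif(60) < 0.2
    rp <- evaluate_filter(pos, neg)
    expect_equal(rp$sensitivity, 100 * sum(pos) / 40)
    expect_equal(rp$selectivity, 100 * sum(neg) / 60)
    if (any(neg)) expect_equal(rp$dr, rp$sensitivity / rp$selectivity)
  }
  expect_error(evaluate_filter(logical(0), TRUE), class = "gimotif_validation_error")

  # one-decimal display convention for the ratio
  expect_equal(discrimination_ratio(21.2, 2.9), 7.3)
  expect_equal(discrimination_ratio(100, 0), Inf)
  expect_equal(discrimination_ratio(50, 3, digits = NULL), 50 / 3)
})

test_that("sensitivity gain is the percent increase over the base pass count", {
  expect_equal(sensitivity_gain(100, 100), 0)
  expect_equal(sensitivity_gain(50, 75), 50)
  expect_error(sensitivity_gain(0, 10), class = "gimotif_validation_error")
  expect_error(sensitivity_gain(10, 5), class = "gimotif_validation_error")
})

test_that("random negative pairs are reproducible, distinct and uniform", {
  # two genes force the single possible pair
  p <- generate_negative_pairs(c("a", "b"), 1, seed = 1)
  expect_equal(pair_key(p$source, p$target), "a--b")

  genes <- sprintf("g%03d", 1:100)
  p1 <- generate_negative_pairs(genes, 500, seed = 42)
  p2 <- generate_negative_pairs(genes, 500, seed = 42)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_negative_pairs(genes, 500, seed = 43)))
  keys <- pair_key(p1$source, p1$target)
  expect_equal(anyDuplicated(keys), 0)
  expect_true(all(p1$source != p1$target))

  expect_error(generate_negative_pairs(c("a", "b"), 2, seed = 1),
               class = "gimotif_validation_error")
  expect_error(generate_negative_pairs("a", 1, seed = 1),
               class = "gimotif_validation_error")

  # collision rate with a 50-edge planted network ~ Binomial(n, 50/C(100,2))
  edges <- with_seed(7, random_edges(genes, 50))
  keys50 <- pair_key(edges$gene_a, edges$gene_b)
  pr <- generate_negative_pairs(genes, 1000, seed = 99)
  hits <- sum(pair_key(pr$source, pr$target) %in% keys50)
  p_hit <- 50 / possible_pair_count(100)
  expected <- 1000 * p_hit
  sigma <- sqrt(1000 * p_hit * (1 - p_hit))
  expect_lt(abs(hits - expected), 3 * sigma + 1)

  # exclude_known rejects planted edges entirely
  pe <- generate_negative_pairs(genes, 1000, seed = 99, policy = "exclude_known",
                                known = edges)
  expect_equal(sum(pair_key(pe$source, pe$target) %in% keys50), 0)
})

test_that("ROC/AUC equals the Mann-Whitney oracle and handles ties", {
  # perfectly separated scores
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  # all scores identical: chance
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), class = "gimotif_validation_error")

  set.seed(73)
  for (rep in 1:15) {
    n <- sample(10:50, 1)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # force ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, mann_whitney_auc(scores, labels), tolerance = 1e-12)
    # curve is anchored and monotone in both coordinates
    expect_equal(r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[1], 0)
    expect_equal(r$roc$fpr[nrow(r$roc)], 1)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
  }
})

test_that("ROC/AUC agrees with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(79)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("the evidence score is monotone in GI path distance", {
  net <- build_network(path_edges(c("a", "b", "c", "d")))
  preds <- data.frame(
    source_protein = c("a", "a", "a", "a", "zz"),
    target_protein = c("b", "c", "d", "zz", "zz"),
    stringsAsFactors = FALSE
  )
  s <- gi_evidence_score(preds, net)
  expect_true(s[1] > s[2] && s[2] > s[3]) # closer pairs score higher
  expect_equal(s[4], 0)                    # unresolved target
  expect_equal(s[5], 0)

  # disconnected pair scores 0
  net2 <- build_network(make_edges(c("a", "c"), c("b", "d")))
  expect_equal(gi_evidence_score(
    data.frame(source_protein = "a", target_protein = "c"), net2), 0)

  # random graph: score ordering agrees with BFS distances
  set.seed(83)
  genes <- sprintf("g%02d", 1:25)
  edges <- random_edges(genes, 40)
  net3 <- build_network(edges)
  pairs <- t(replicate(20, sample(genes, 2)))
  preds3 <- data.frame(source_protein = pairs[, 1], target_protein = pairs[, 2],
                       stringsAsFactors = FALSE)
  sc <- gi_evidence_score(preds3, net3)
  d <- vapply(seq_len(20), function(i) {
    igraph::distances(net3$graph, v = pairs[i, 1], to = pairs[i, 2])[1, 1]
  }, numeric(1))
  for (i in 1:19) {
    for (j in (i + 1):20) {
      if (d[i] < d[j]) expect_gt(sc[i], sc[j])
      if (d[i] == d[j] && is.infinite(d[i])) expect_equal(sc[i], sc[j])
    }
  }
})

test_that("activity stratification recovers planted per-activity GI rates", {
  cfg <- world_config(
    n_genes = 1200, n_species = 1, background_edge_prob = 0,
    n_positive_motifs = 900, n_negative_pairs = 400,
    per_activity_gi_rates = c(modifies = 0.56, binds = 0.19),
    activity_mix = c(binds = 0.5, modifies = 0.5),
    p_neg_gi_edge = 0.03, homolog_cluster_rate = 0, gi_conservation_rate = 0,
    p_ppi_given_gi = 0, alias_rate = 0, seed = 202
  )
  w <- simulate_world(cfg)
  net <- build_network(w$gi_edges)
  dp <- apply_filters(w$positive_motifs, filter_spec("gi"), network = net)
  negs <- data.frame(
    motif_id = w$negative_pairs$pair_id,
    source_protein = w$negative_pairs$source,
    target_protein = w$negative_pairs$target, stringsAsFactors = FALSE
  )
  dn <- apply_filters(negs, filter_spec("gi"), network = net)
  pos <- data.frame(passed = dp$passed, activity = w$positive_motifs$activity,
                    stringsAsFactors = FALSE)
  neg <- data.frame(passed = dn$passed, activity = w$negative_pairs$activity,
                    stringsAsFactors = FALSE)
  strata <- stratify_metrics(pos, neg, key = "activity", filter_name = "gi")
  for (act in c("modifies", "binds")) {
    rate <- c(modifies = 0.56, binds = 0.19)[[act]]
    n_act <- sum(pos$activity == act)
    sigma <- 100 * sqrt(rate * (1 - rate) / n_act)
    expect_lt(abs(strata[[act]]$sensitivity - 100 * rate), 3 * sigma)
  }

  # single stratum equals the global report
  pos1 <- data.frame(passed = dp$passed, activity = "binds", stringsAsFactors = FALSE)
  neg1 <- data.frame(passed = dn$passed, activity = "binds", stringsAsFactors = FALSE)
  s1 <- stratify_metrics(pos1, neg1, key = "activity")
  expect_equal(s1$binds$sensitivity, evaluate_filter(dp$passed, dn$passed)$sensitivity)

  expect_error(stratify_metrics(pos, neg, key = "shoe_size"))
})
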
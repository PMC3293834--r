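motif <- function(s, t, id = "m1") {
  list(motif_id = id, source_protein = s, target_protein = t)
}

test_that("the basic GI filter retains pairs with a direct interaction", {
  net <- build_network(make_edges("s", "t"))
  d <- basic_gi_filter(motif("s", "t"), net)
  expect_true(d$passed)
  expect_equal(d$witness, "s--t")

  expect_false(basic_gi_filter(motif("s", "x"), net)$passed)

  # unresolved names fail with a note instead of erroring
  d2 <- basic_gi_filter(motif("nowhere", "t"), net)
  expect_false(d2$passed)
  expect_match(d2$note, "source unresolved")

  # self-pair passes only with a self-loop edge
  net_loop <- build_network(make_edges(c("s", "u"), c("t", "u")))
  expect_false(basic_gi_filter(motif("s", "s"), net_loop)$passed)
  expect_true(basic_gi_filter(motif("u", "u"), net_loop)$passed)
})

test_that("alias names resolve before the interaction lookup", {
  aliases <- data.frame(canonical_id = "tp53", alias = "P53", species = "human",
                        stringsAsFactors = FALSE)
  net <- build_network(make_edges("tp53", "mdm2"), aliases)
  d <- basic_gi_filter(motif("P53", "mdm2"), net)
  expect_true(d$passed)
  expect_equal(d$witness, "mdm2--tp53")
  # alias invariance: querying by canonical name gives the same verdict
  expect_equal(d$passed, basic_gi_filter(motif("tp53", "MDM2"), net)$passed)
})

test_that("the GI-node filter passes when an edge joins the expansion balls", {
  # direct edge, N = 1
  net <- build_network(make_edges("s", "t"))
  expect_true(gi_node_filter(motif("s", "t"), net, node_count = 1)$passed)

  # path s-x-y-t: at N = 1 the balls {s,x} and {t,y} are joined by x-y
  net2 <- build_network(path_edges(c("s", "x", "y", "t")))
  d <- gi_node_filter(motif("s", "t"), net2, node_count = 1)
  expect_true(d$passed)
  expect_equal(d$witness, "x--y")

  # path of length 4: not reachable at N = 1, reachable at N = 2
  net3 <- build_network(path_edges(c("s", "a", "b", "c", "t")))
  expect_false(gi_node_filter(motif("s", "t"), net3, node_count = 1)$passed)
  expect_true(gi_node_filter(motif("s", "t"), net3, node_count = 2)$passed)

  expect_error(gi_node_filter(motif("s", "t"), net, node_count = 0),
               class = "gimotif_validation_error")
  expect_warning(gi_node_filter(motif("s", "t"), net, node_count = 5),
                 "selectivity")
})

test_that("GI-node decisions equal the shortest-path <= 2N+1 oracle on random graphs", {
  set.seed(53)
  genes <- sprintf("g%02d", 1:50)
  for (rep in 1:15) {
    edges <- random_edges(genes, sample(30:90, 1))
    net <- build_network(edges)
    pair <- sample(net$nodes, 2)
    m <- motif(pair[1], pair[2])
    d_sp <- igraph::distances(net$graph, v = pair[1], to = pair[2])[1, 1]
    for (N in 1:2) {
      got <- gi_node_filter(m, net, node_count = N)$passed
      expect_equal(got, is.finite(d_sp) && d_sp <= 2 * N + 1,
                   info = sprintf("rep %d N %d d %s", rep, N, d_sp))
    }
    # nesting: basic subset of node(1) subset of node(2)
    basic <- basic_gi_filter(m, net)$passed
    n1 <- gi_node_filter(m, net, 1)$passed
    n2 <- gi_node_filter(m, net, 2)$passed
    expect_true(!basic || n1)
    expect_true(!n1 || n2)
  }
})

test_that("the GI-HomoloGene filter extrapolates interactions between homologs", {
  rec <- data.frame(
    cluster_id = c("1", "1", "2", "2"), taxon = c("yeast", "fly", "yeast", "fly"),
    gene_id = c("s", "s_fly", "t", "t_fly"), symbol = c("S", "SF", "T", "TF"),
    stringsAsFactors = FALSE
  )
  map <- build_homolog_map(rec)
  net <- build_network(make_edges("s_fly", "t_fly", species = "fly"))
  # fails the basic filter but passes through its fly homologs
  expect_false(basic_gi_filter(motif("s", "t"), net)$passed)
  d <- gi_homologene_filter(motif("s", "t"), net, map)
  expect_true(d$passed)
  expect_equal(d$witness, "s_fly--t_fly")

  # basic passes imply homologene passes when every gene carries a taxon
  net2 <- build_network(make_edges("s", "t", species = "yeast"))
  expect_true(gi_homologene_filter(motif("s", "t"), net2, map)$passed)
})

test_that("the generic network filter applies the same lookup to a PPI network", {
  gi_net <- build_network(make_edges("a", "b"))
  ppi_net <- build_network(make_edges("c", "d", kind = "physical"))
  m1 <- motif("a", "b"); m2 <- motif("c", "d")
  expect_true(basic_gi_filter(m1, gi_net)$passed)
  expect_false(generic_network_filter(m1, ppi_net)$passed)
  expect_false(basic_gi_filter(m2, gi_net)$passed)
  expect_true(generic_network_filter(m2, ppi_net)$passed)

  empty_net <- build_network(empty_edges())
  expect_false(generic_network_filter(m1, empty_net)$passed)
})

test_that("decision combination follows boolean union/intersection truth tables", {
  p <- new_decision("m1", "gi", TRUE, witness = "a--b")
  f <- new_decision("m1", "ppi", FALSE)
  expect_true(combine_decisions(rbind(p, f), "union")$passed)
  expect_false(combine_decisions(rbind(p, f), "intersection")$passed)
  expect_equal(combine_decisions(rbind(p, f), "union")$filter, "gi|ppi")

  set.seed(59)
  for (rep in 1:20) {
    vals <- runif(3) < 0.5
    dec <- do.call(rbind, lapply(1:3, function(i) {
      new_decision("m1", sprintf("f%d", i), vals[i],
                   witness = if (vals[i]) "x--y")
    }))
    expect_equal(combine_decisions(dec, "union")$passed, any(vals))
    expect_equal(combine_decisions(dec, "intersection")$passed, all(vals))
  }
  expect_error(combine_decisions(empty_decisions(), "union"),
               class = "gimotif_validation_error")
  expect_error(combine_decisions(rbind(p, new_decision("m2", "gi", TRUE, "a--b"))),
               class = "gimotif_validation_error")
})

test_that("apply_filters matches the per-motif functions and honours polarity and flags", {
  set.seed(61)
  genes <- sprintf("g%02d", 1:30)
  edges <- random_edges(genes, 50)
  net <- build_network(edges)
  rec <- data.frame(
    cluster_id = sprintf("c%d", 1:30), taxon = "sp1", gene_id = genes,
    symbol = toupper(genes), stringsAsFactors = FALSE
  )
  map <- build_homolog_map(rec)
  n <- 25
  preds <- data.frame(
    motif_id = sprintf("m%02d", 1:n), sequence = "",
    source_protein = sample(genes, n, replace = TRUE),
    target_protein = sample(genes, n, replace = TRUE),
    activity = "binds", sub_activity = "", stringsAsFactors = FALSE
  )
  preds$external_flags <- lapply(1:n, function(i) c(frequency = i %% 2 == 0))
  class(preds) <- c("motif_predictions", "data.frame")

  specs <- list(filter_spec("gi"), filter_spec("gi_node", node_count = 2),
                filter_spec("gi_homologene"),
                filter_spec("external_flag", name = "frequency"))
  dec <- apply_filters(preds, specs, network = net, homolog_map = map)
  expect_equal(nrow(dec), n * 4)

  # per-motif oracle: recompute each decision with the standalone functions
  for (i in sample(n, 8)) {
    m <- preds[i, ]
    expect_equal(dec$passed[dec$filter == "gi"][i], basic_gi_filter(m, net)$passed)
    expect_equal(dec$passed[dec$filter == "gi_node2"][i],
                 gi_node_filter(m, net, 2)$passed)
    expect_equal(dec$passed[dec$filter == "gi_homologene"][i],
                 gi_homologene_filter(m, net, map)$passed)
  }
  expect_equal(dec$passed[dec$filter == "frequency"], (1:n) %% 2 == 0)

  # exclude polarity is the exact complement of include
  dec_ex <- apply_filters(preds, filter_spec("gi", polarity = "exclude"), network = net)
  expect_equal(dec_ex$passed, !dec$passed[dec$filter == "gi"])
  expect_true(all(dec_ex$witness == ""))

  # a passing decision always carries a witness (except external flags)
  gi_dec <- dec[dec$filter %in% c("gi", "gi_node2", "gi_homologene"), ]
  expect_true(all(nzchar(gi_dec$witness[gi_dec$passed])))
  expect_true(all(gi_dec$witness[!gi_dec$passed] == ""))

  # missing flag fails with a note
  preds2 <- preds
  preds2$external_flags <- replicate(n, logical(0), simplify = FALSE)
  dec_missing <- apply_filters(preds2, filter_spec("external_flag", name = "frequency"))
  expect_false(any(dec_missing$passed))
  expect_true(all(dec_missing$note == "flag missing"))

  # missing resources are configuration errors raised before filtering
  expect_error(apply_filters(preds, filter_spec("gi")),
               class = "gimotif_config_error")
  expect_error(apply_filters(preds, filter_spec("gi_homologene"), network = net),
               class = "gimotif_config_error")
  expect_error(apply_filters(preds, filter_spec("network_generic"), network = net),
               class = "gimotif_config_error")

  # determinism: identical inputs give identical decisions
  expect_identical(dec, apply_filters(preds, specs, network = net, homolog_map = map))
})
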
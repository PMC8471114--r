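# small classified tau table + modules + activity for gating tests
gate_fixture <- function() {
  genes <- sprintf("g%02d", 1:12)
  tau <- data.frame(
    gene_id = genes,
    tau = 0.95,
    max_tissue = c(rep("liver", 8), rep("brain", 4)),
    category = factor(c(rep("TissueSpecific", 10),
                        "Mixed", "TissueSpecific"),
                      levels = c("TissueSpecific", "GroupEnriched",
                                 "ExpressedInAll", "Mixed")),
    stringsAsFactors = FALSE)
  mods <- structure(list(modules = list(
    list(id = "M1", genes = genes[1:6]),     # liver-active
    list(id = "M2", genes = genes[7:12])),   # inactive
    unassigned = character(), adjacency = NULL, beta = 6L),
    class = "coexpr_modules")
  activity <- data.frame(
    module = rep(c("M1", "M2"), each = 2),
    tissue = rep(c("liver", "brain"), 2),
    nes = c(5, -1, 0.2, 0.3),
    p = c(0.001, 0.9, 0.4, 0.6), stringsAsFactors = FALSE)
  list(tau = tau, mods = mods, activity = activity)
}

clique_edges <- function(genes, score = 0.9) {
  pairs <- combn(genes, 2)
  data.frame(protein1 = pairs[1, ], protein2 = pairs[2, ],
             combined_score = score, stringsAsFactors = FALSE)
}

test_that("PPI loading filters strictly, rescales and deduplicates", {
  df <- data.frame(protein1 = c("a", "b", "a", "x", "y"),
                   protein2 = c("b", "a", "a", "y", "z"),
                   combined_score = c(0.8, 0.9, 0.95, 0.70, 0.75))
  g <- load_ppi(df)
  # self-loop dropped; (a,b) deduplicated keeping 0.9; 0.70 excluded strictly
  expect_equal(nrow(g$edges), 2L)
  ab <- g$edges[g$edges$protein1 == "a", ]
  expect_equal(ab$combined_score, 0.9)
  expect_false(any(g$edges$protein1 == "x"))
  # STRING 0-1000 scale auto-detected
  df2 <- data.frame(protein1 = "a", protein2 = "b", combined_score = 950)
  expect_equal(load_ppi(df2)$edges$combined_score, 0.95)
  df3 <- data.frame(protein1 = "a", protein2 = "b", combined_score = 700)
  expect_equal(nrow(load_ppi(df3)$edges), 0L)
  expect_error(load_ppi(data.frame(protein1 = "a", protein2 = "b",
                                   combined_score = -1)), "negative")
})

test_that("tissue gating is conjunctive and keeps only large components", {
  fx <- gate_fixture()
  # clique over g01..g05 (all TS-liver, in active M1) + an edge to g07
  # (TS-liver but only in inactive M2) + a separate pair g09-g10
  edges <- rbind(clique_edges(sprintf("g%02d", 1:5)),
                 data.frame(protein1 = "g01", protein2 = "g07",
                            combined_score = 0.99),
                 data.frame(protein1 = "g09", protein2 = "g10",
                            combined_score = 0.95))
  ppi <- load_ppi(edges)
  net <- extract_tissue_network(ppi, fx$tau, fx$mods, fx$activity, "liver")
  expect_setequal(net$nodes, sprintf("g%02d", 1:5))
  expect_equal(nrow(net$edges), 10L)            # intact 5-clique
  expect_equal(length(net$components), 1L)
  # g07 excluded: tissue-specific but in no active module
  expect_false("g07" %in% net$nodes)
  # brain: gate empty -> valid empty network
  net_b <- extract_tissue_network(ppi, fx$tau, fx$mods, fx$activity, "brain")
  expect_length(net_b$nodes, 0)
  expect_error(extract_tissue_network(ppi, fx$tau, fx$mods, fx$activity,
                                      "kidney"), "unknown tissue")
})

test_that("components below min_component are suppressed", {
  fx <- gate_fixture()
  edges <- data.frame(protein1 = "g01", protein2 = "g02",
                      combined_score = 0.99)
  net <- extract_tissue_network(load_ppi(edges), fx$tau, fx$mods,
                                fx$activity, "liver")
  expect_length(net$nodes, 0)
  net2 <- extract_tissue_network(load_ppi(edges), fx$tau, fx$mods,
                                 fx$activity, "liver", min_component = 2)
  expect_setequal(net2$nodes, c("g01", "g02"))
})

test_that("every network edge joins gated nodes of the filtered graph", {
  fx <- gate_fixture()
  set.seed(23)
  genes <- sprintf("g%02d", 1:12)
  rnd <- data.frame(protein1 = sample(genes, 60, TRUE),
                    protein2 = sample(genes, 60, TRUE),
                    combined_score = runif(60), stringsAsFactors = FALSE)
  rnd <- rnd[rnd$protein1 != rnd$protein2, ]
  ppi <- load_ppi(rnd)
  net <- extract_tissue_network(ppi, fx$tau, fx$mods, fx$activity, "liver",
                                min_component = 2)
  gate <- intersect(sprintf("g%02d", 1:6),
                    fx$tau$gene_id[fx$tau$category == "TissueSpecific"])
  key <- paste(ppi$edges$protein1, ppi$edges$protein2)
  expect_true(all(paste(net$edges$protein1, net$edges$protein2) %in% key))
  expect_true(all(c(net$edges$protein1, net$edges$protein2) %in% gate))
})

test_that("raising min_score never adds nodes or edges", {
  fx <- gate_fixture()
  set.seed(29)
  genes <- sprintf("g%02d", 1:12)
  for (rep in 1:10) {
    rnd <- data.frame(protein1 = sample(genes, 80, TRUE),
                      protein2 = sample(genes, 80, TRUE),
                      combined_score = runif(80), stringsAsFactors = FALSE)
    rnd <- rnd[rnd$protein1 != rnd$protein2, ]
    lo <- extract_tissue_network(load_ppi(rnd, min_score = 0.3), fx$tau,
                                 fx$mods, fx$activity, "liver",
                                 min_component = 2)
    hi <- extract_tissue_network(load_ppi(rnd, min_score = 0.6), fx$tau,
                                 fx$mods, fx$activity, "liver",
                                 min_component = 2)
    expect_true(all(hi$nodes %in% lo$nodes))
    expect_true(all(paste(hi$edges$protein1, hi$edges$protein2) %in%
                    paste(lo$edges$protein1, lo$edges$protein2)))
  }
})

test_that("hub ranking uses degree, then score sum, then id", {
  # star on 4 nodes: centre has degree 3
  fx <- gate_fixture()
  star <- data.frame(protein1 = c("g01", "g01", "g01"),
                     protein2 = c("g02", "g03", "g04"),
                     combined_score = c(0.9, 0.9, 0.9))
  net <- extract_tissue_network(load_ppi(star), fx$tau, fx$mods,
                                fx$activity, "liver")
  expect_equal(net$hubs$gene_id[1], "g01")
  expect_equal(net$hubs$degree[1], 3L)
  # clique: all tie on degree; order resolved by score sum then id
  cl <- clique_edges(c("g01", "g02", "g03"), score = 0.8)
  cl$combined_score <- c(0.9, 0.9, 0.8)  # g01 incident to both 0.9 edges
  net2 <- extract_tissue_network(load_ppi(cl), fx$tau, fx$mods,
                                 fx$activity, "liver")
  expect_equal(net2$hubs$gene_id[1], "g01")
  # degree equals brute-force incidence count
  for (r in seq_len(nrow(net2$hubs))) {
    g <- net2$hubs$gene_id[r]
    expect_equal(net2$hubs$degree[r],
                 sum(net2$edges$protein1 == g) +
                   sum(net2$edges$protein2 == g))
  }
  expect_equal(nrow(network_hubs(structure(list(nodes = character(),
                                                edges = data.frame()),
                                           class = "tissue_network"))), 0L)
})
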
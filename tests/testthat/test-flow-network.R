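test_that("build_flow_network aggregates weights and routes self-loops", {
  rec <- six_record_slice()
  net <- build_flow_network(rec)
  # hand aggregation: KEN->USA 4, NOR->DNK 3, DNK->NOR 1; USA->USA domestic 5
  expect_equal(nrow(net$edges), 3)
  e <- net$edges
  expect_equal(e$weight[e$origin == "KEN" & e$holding == "USA"], 4L)
  expect_equal(e$weight[e$origin == "NOR" & e$holding == "DNK"], 3L)
  expect_equal(e$weight[e$origin == "DNK" & e$holding == "NOR"], 1L)
  expect_equal(unname(net$domestic[["USA"]]), 5L)
  expect_setequal(net$nodes, c("KEN", "USA", "NOR", "DNK"))
})

test_that("purely domestic slices have no topology", {
  rec <- data.frame(family = "Canidae", origin_country = "USA",
                    holding_country = "USA", year = 1950, count = 5,
                    source_row = 1)
  net <- build_flow_network(rec)
  expect_equal(network_size(net), 0)
  expect_equal(network_complexity(net), 0)
  expect_equal(unname(net$domestic[["USA"]]), 5L)
  expect_true(is.na(flow_reciprocity(net)))
  expect_true(is.na(giant_component_fraction(net)))
})

test_that("empty slices give a valid empty network", {
  rec <- six_record_slice()[0, ]
  net <- build_flow_network(rec)
  expect_equal(network_size(net), 0)
  expect_equal(flow_density(net), 0)
  m <- network_metrics(net)
  expect_true(is.na(m$modularity))
})

test_that("density, reciprocity, giant fraction on canonical cases", {
  mk <- function(from, to) edges_to_net(
    data.frame(origin = from, holding = to,
               weight = rep(1L, length(from)), stringsAsFactors = FALSE))
  # single edge on 2 nodes
  expect_equal(flow_density(mk("A", "B")), 0.5)
  # complete directed graph on 4 nodes
  pairs <- expand.grid(origin = LETTERS[1:4], holding = LETTERS[1:4],
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$origin != pairs$holding, ]
  pairs$weight <- 1L
  expect_equal(flow_density(edges_to_net(pairs)), 1)
  # reciprocity {A->B, B->A, A->C} = 2/3
  expect_equal(flow_reciprocity(mk(c("A", "B", "A"), c("B", "A", "C"))), 2 / 3)
  expect_equal(flow_reciprocity(mk(c("A", "B"), c("B", "C"))), 0)
  # giant fraction {A->B, C->D} = 0.5; star = 1
  expect_equal(giant_component_fraction(mk(c("A", "C"), c("B", "D"))), 0.5)
  expect_equal(giant_component_fraction(mk(LETTERS[1:5], rep("Z", 5))), 1)
  # star of 5 origins into 1 holder has 6 nodes
  expect_equal(network_size(mk(LETTERS[1:5], rep("Z", 5))), 6)
})

test_that("metrics match independent oracles on random graphs", {
  for (seed in 1:30) {
    ed <- random_edges(n_nodes = sample(3:12, 1), n_edges = sample(2:30, 1),
                       seed = seed)
    net <- edges_to_net(ed)
    expect_equal(flow_density(net), oracle_density(ed))
    expect_equal(flow_reciprocity(net), oracle_reciprocity(ed))
    expect_equal(giant_component_fraction(net), oracle_giant_fraction(ed))
  }
})

test_that("Louvain finds the planted structure in two disjoint triangles", {
  tri <- data.frame(origin = c("A", "B", "C", "D", "E", "F"),
                    holding = c("B", "C", "A", "E", "F", "D"),
                    weight = 1L)
  net <- edges_to_net(tri)
  ml <- modularity_louvain(net, seed = 1)
  expect_equal(ml$modularity, 0.5, tolerance = 1e-12)
  part <- ml$partition
  expect_equal(length(unique(part[c("A", "B", "C")])), 1)
  expect_equal(length(unique(part[c("D", "E", "F")])), 1)
  expect_false(part[["A"]] == part[["D"]])
  expect_identical(ml, modularity_louvain(net, seed = 1))
})

test_that("Louvain modularity is bounded by the exhaustive optimum", {
  for (seed in c(2, 5, 8)) {
    ed <- random_edges(n_nodes = 7, n_edges = 12, seed = seed)
    net <- edges_to_net(ed)
    ml <- modularity_louvain(net, seed = 1)
    # undirected weight-summed projection for the oracle
    a <- pmin(ed$origin, ed$holding); b <- pmax(ed$origin, ed$holding)
    und <- stats::aggregate(w ~ a + b,
                            data = data.frame(a, b, w = ed$weight), FUN = sum)
    best <- oracle_best_modularity(und, net$nodes)
    expect_gte(ml$modularity, 0 - 1e-12)
    expect_lte(ml$modularity, best + 1e-9)
  }
})

test_that("node strengths, conservation and net balance", {
  net <- build_flow_network(six_record_slice())
  ns <- node_strengths(net)
  expect_equal(sum(ns$in_strength), sum(ns$out_strength))
  expect_equal(sum(ns$in_strength), sum(net$edges$weight))
  usa <- ns[ns$country == "USA", ]
  expect_equal(usa$in_strength, 4)
  expect_equal(usa$out_strength, 0)
  expect_equal(usa$net_balance, 1)       # pure importer
  ken <- ns[ns$country == "KEN", ]
  expect_equal(ken$net_balance, -1)      # pure exporter
  expect_equal(usa$domestic, 5)
  # in 6, out 2 -> 0.5
  ed <- data.frame(origin = c("A", "A", "B"), holding = c("B", "B", "A"),
                   weight = c(1L, 1L, 6L))
  ns2 <- node_strengths(build_flow_network(data.frame(
    family = "x", origin_country = ed$origin, holding_country = ed$holding,
    year = 1950, count = ed$weight, source_row = 1:3)))
  expect_equal(ns2$net_balance[ns2$country == "A"], 0.5)
})

test_that("net balance negates when all edges are reversed", {
  ed <- random_edges(8, 15, seed = 77)
  fwd <- node_strengths(edges_to_net(ed))
  rev <- ed; names(rev)[1:2] <- c("holding", "origin")
  bwd <- node_strengths(edges_to_net(rev[, c("origin", "holding", "weight")]))
  m <- match(fwd$country, bwd$country)
  expect_equal(fwd$net_balance, -bwd$net_balance[m])
  expect_equal(fwd$net, -bwd$net[m])
})

test_that("top_k_edges is deterministic under ties", {
  ed <- data.frame(origin = c("B", "A", "C"), holding = c("X", "X", "X"),
                   weight = c(5L, 5L, 1L))
  net <- edges_to_net(ed)
  top2 <- top_k_edges(net, 2)
  expect_equal(top2$origin, c("A", "B"))   # tie broken by origin code
  expect_equal(nrow(top_k_edges(net, 200)), 3)
  expect_equal(top_k_edges(net, 1)$weight, 5L)
})

test_that("weight thresholding is monotone and recomputes the node set", {
  net <- build_flow_network(six_record_slice())
  expect_identical(apply_weight_threshold(net, 1)$edges, net$edges)
  t5 <- apply_weight_threshold(net, 5)
  expect_equal(nrow(t5$edges), 0)          # all weights < 5
  expect_equal(network_size(t5), 0)
  t3 <- apply_weight_threshold(net, 3)
  expect_setequal(t3$edges$weight, c(4L, 3L))
  expect_setequal(t3$nodes, c("KEN", "USA", "NOR", "DNK"))
  # monotonicity over a random network
  ed <- random_edges(10, 40, seed = 9)
  nets <- lapply(c(1, 3, 7, 15, 100),
                 function(w) apply_weight_threshold(edges_to_net(ed), w))
  sizes <- vapply(nets, network_size, integer(1))
  edges <- vapply(nets, network_complexity, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(diff(edges) <= 0))
  # domestic ledger untouched
  netd <- build_flow_network(six_record_slice())
  expect_identical(apply_weight_threshold(netd, 10)$domestic, netd$domestic)
})

test_that("metrics_by_slice emits one row per family x period", {
  tbl <- generate_occurrences(small_synth(seed = 14, n = 3000))
  fl <- filter_records(parse_occurrences(tbl), attr(tbl, "registry"))
  mt <- metrics_by_slice(fl$records, seed = 1)
  expect_equal(nrow(mt), 12)
  expect_setequal(unique(mt$family), c("Canidae", "Felidae", "Mustelidae"))
  expect_true(all(mt$density >= 0 & mt$density <= 1, na.rm = TRUE))
  expect_true(all(mt$reciprocity >= 0 & mt$reciprocity <= 1, na.rm = TRUE))
  expect_true(all(mt$giant_fraction > 0 & mt$giant_fraction <= 1, na.rm = TRUE))
  expect_equal(mt$edges_to_nodes, mt$edges / mt$nodes)
})

test_that("symmetrised networks have reciprocity 1", {
  ed <- random_edges(6, 10, seed = 31)
  sym <- rbind(ed, data.frame(origin = ed$holding, holding = ed$origin,
                              weight = ed$weight))
  sym <- sym[!duplicated(sym[, c("origin", "holding")]), ]
  expect_equal(flow_reciprocity(edges_to_net(sym)), 1)
})
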
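test_that("degree and strength follow their definitions", {
  st <- star_network(5)
  expect_equal(unname(node_degree(st, "hub")), 5)
  expect_equal(unname(node_degree(st, "leaf01")), 1)
  k4 <- complete_network(4)
  expect_true(all(node_degree(k4) == 3))
  expect_true(all(node_strength(k4) == 3))

  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 0.5
  adj[1, 3] <- adj[3, 1] <- -0.3
  net <- symptom_network(adj, labels = c("a", "b", "c"))
  expect_equal(unname(node_strength(net, "a")), 0.8)
  expect_equal(unname(node_degree(net, "a")), 2)

  iso <- symptom_network(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)),
                         labels = c("x", "y", "z"))
  expect_equal(unname(node_degree(iso, "z")), 0)
  expect_equal(unname(node_strength(iso, "z")), 0)
  expect_error(node_degree(st, "nope"), "unknown")

  # degree equals strength whenever all weights are unit
  for (s in 1:5) {
    net1 <- er_network(10, 0.4, seed = s)
    unit <- symptom_network((net1$adjacency != 0) * 1, labels = net1$labels)
    expect_equal(unname(node_degree(unit)), unname(node_strength(unit)))
  }
})

test_that("effective number is the inverse participation ratio", {
  expect_equal(effective_number(c(1, 0, 0)), 1)
  expect_equal(effective_number(c(0.5, 0.5)), 2)
  expect_equal(effective_number(c(0.7, 0.3)), 1 / 0.58, tolerance = 1e-6)
  expect_error(effective_number(c(0.5, 0.2)), "summing to 1")
})

test_that("module detection separates disjoint cliques and is deterministic", {
  two <- gen_planted_modules(c(5, 5))$network
  a <- detect_modules(two)
  expect_equal(a$n_modules, 2)
  expect_true(all(apply(a$membership, 1, max) > 1 - 1e-4))
  expect_true(all(abs(rowSums(a$membership) - 1) < 1e-9))
  expect_true(all(abs(rowSums(a$connection_profile) - 1) < 1e-9))
  expect_identical(detect_modules(two), detect_modules(two))
  edgeless <- symptom_network(matrix(0, 3, 3))
  expect_error(detect_modules(edgeless), "singleton")
})

test_that("overlap and bridgeness are bounded by the module count", {
  for (s in c(2, 9, 17)) {
    net <- er_network(12, 0.3, seed = s)
    a <- detect_modules(net)
    for (lbl in net$labels) {
      ov <- modular_overlap(a, lbl)
      br <- modular_bridgeness(a, lbl)
      expect_gte(ov, 1 - 1e-9); expect_lte(ov, a$n_modules + 1e-9)
      expect_gte(br, 1 - 1e-9); expect_lte(br, a$n_modules + 1e-9)
    }
  }
})

test_that("planted shared nodes maximize overlap; bridge endpoints maximize bridgeness", {
  shared <- gen_planted_modules(c(6, 6), shared_nodes = 1)
  a <- detect_modules(shared$network)
  ov <- vapply(shared$network$labels, modular_overlap, numeric(1), assignment = a)
  expect_equal(names(which.max(ov)), shared$true_overlap_nodes)

  bridged <- gen_planted_modules(c(5, 5), bridge_edges = 1)
  ab <- detect_modules(bridged$network)
  br <- vapply(bridged$network$labels, modular_bridgeness, numeric(1), assignment = ab)
  expect_true(names(which.max(br)) %in% bridged$true_bridge_nodes)

  # barbell: a bridge endpoint has strictly the highest bridgeness
  bb <- gen_planted_modules(c(4, 4), bridge_edges = 1)
  abb <- detect_modules(bb$network)
  brb <- vapply(bb$network$labels, modular_bridgeness, numeric(1), assignment = abb)
  ends <- bb$true_bridge_nodes
  others <- setdiff(bb$network$labels, ends)
  expect_gt(max(brb[ends]), max(brb[others]))
})

test_that("a connector with one edge into each of two cliques has bridgeness near 2", {
  pm <- gen_planted_modules(c(6, 6))
  net <- pm$network
  p <- length(net$labels) + 1
  adj <- matrix(0, p, p)
  adj[1:(p - 1), 1:(p - 1)] <- net$adjacency
  # connector attaches by one unit edge to each clique
  a1 <- match(pm$true_modules[[1]][1], net$labels)
  a2 <- match(pm$true_modules[[2]][1], net$labels)
  adj[p, a1] <- adj[a1, p] <- 1
  adj[p, a2] <- adj[a2, p] <- 1
  conn <- symptom_network(adj, labels = c(net$labels, "connector"))
  a <- detect_modules(conn)
  expect_equal(modular_bridgeness(a, "connector"), 2, tolerance = 0.2)
  # interior clique nodes stay near 1
  interior <- setdiff(pm$true_modules[[1]], pm$true_modules[[1]][1])[1]
  expect_equal(modular_bridgeness(a, interior), 1, tolerance = 0.15)
  expect_equal(modular_overlap(a, interior), 1, tolerance = 0.15)
})

test_that("ranking is descending with deterministic label tie-break", {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 0.6
  adj[1, 3] <- adj[3, 1] <- 0.6
  adj[2, 3] <- adj[3, 2] <- 0.2
  net <- symptom_network(adj, labels = c("A", "B", "C"))
  # strengths: A = 1.2, B = 0.8, C = 0.8 -> with equal B/C, label order
  r <- rank_nodes(net, "strength")
  expect_equal(r$order, c("A", "B", "C"))
  expect_true(all(diff(r$values) <= 1e-12))

  st <- star_network(4)
  expect_equal(rank_nodes(st, "degree")$order[1], "hub")

  k3 <- complete_network(3)
  expect_equal(rank_nodes(k3, "degree")$order, c("A", "B", "C"))
  expect_error(rank_nodes(net, "overlap"), "assignment")

  # seeded random tie-break is reproducible
  expect_identical(rank_nodes(k3, "degree", seed = 5),
                   rank_nodes(k3, "degree", seed = 5))
})

test_that("symptom_measures assembles all four measures", {
  pm <- gen_planted_modules(c(4, 4), shared_nodes = 1)
  tab <- symptom_measures(pm$network)
  expect_equal(nrow(tab), 7)
  expect_named(tab, c("symptom", "degree", "strength", "overlap",
                      "bridgeness", "module"))
  expect_equal(tab$symptom[which.max(tab$overlap)], pm$true_overlap_nodes)
})
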
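# transition_model whose cost graph equals a given dense cost matrix
# (m = 1/cost entry-wise; Inf means no edge)
tm_from_costs <- function(cost) {
  M <- 1 / cost
  M[!is.finite(cost)] <- 0
  fake_tm(M)
}

test_that("Yen on a 4-node toy digraph equals exhaustive enumeration", {
  cost <- matrix(Inf, 4, 4)
  cost[1, 2] <- 1; cost[2, 3] <- 1; cost[1, 3] <- 5
  cost[3, 4] <- 1; cost[2, 4] <- 4
  tm <- tm_from_costs(cost)
  got <- yen_k_shortest(tm, "A:1", "A:4", k = 3)
  want <- enumerate_simple_paths(cost, 1, 4)
  expect_equal(got$node_index, want$paths[1:3])
  expect_equal(got$cost, want$costs[1:3], tolerance = 1e-12)
  expect_equal(got$rank, 1:3)
  # path probability is the product of m along the edges
  expect_equal(got$probability[1], 1 * 1 * 1)
  expect_equal(got$nodes[1], "A:1->A:2->A:3->A:4")
})

test_that("Yen agrees with brute-force enumeration on 100 seeded digraphs", {
  agree <- 0
  for (seed in 1:100) {
    n <- sample(4:8, 1)
    cost <- random_cost_matrix(n, p = 0.45, seed = seed)
    src <- 1; dst <- n
    want <- enumerate_simple_paths(cost, src, dst)
    if (length(want$paths) == 0) next
    tm <- tm_from_costs(cost)
    k <- min(10, length(want$paths))
    got <- yen_k_shortest(tm, "A:1", residue_key("A", n), k = k)
    expect_equal(got$node_index, want$paths[seq_len(k)])
    expect_equal(got$cost, want$costs[seq_len(k)], tolerance = 1e-9)
    agree <- agree + 1
  }
  expect_gt(agree, 80)   # almost all random digraphs have a 1 -> n path
})

test_that("Yen rank 1 matches an independent Dijkstra implementation", {
  skip_if_not_installed("igraph")
  for (seed in c(2, 9, 23, 41)) {
    cost <- random_cost_matrix(7, p = 0.5, seed = seed)
    tm <- tm_from_costs(cost)
    adj <- ifelse(is.finite(cost), cost, 0)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed",
                                             weighted = TRUE)
    ig <- igraph::k_shortest_paths(g, from = 1, to = 7, k = 4)
    if (length(ig$vpaths) == 0) next
    got <- yen_k_shortest(tm, "A:1", "A:7", k = 4)
    expect_equal(got$node_index[[1]], as.integer(ig$vpaths[[1]]))
    # same path cost multiset for the deeper ranks
    igc <- vapply(ig$vpaths, function(p) {
      p <- as.integer(p); sum(cost[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    expect_equal(sort(got$cost), sort(igc), tolerance = 1e-9)
  }
})

test_that("a directly connected cheapest edge gives the 2-node rank-1 path", {
  cost <- matrix(Inf, 3, 3)
  cost[1, 3] <- 0.5; cost[1, 2] <- 1; cost[2, 3] <- 1
  got <- yen_k_shortest(tm_from_costs(cost), "A:1", "A:3", k = 2)
  expect_equal(got$node_index[[1]], c(1, 3))
  expect_equal(got$node_index[[2]], c(1, 2, 3))
})

test_that("path lists are duplicate-free with nondecreasing costs", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  got <- yen_k_shortest(tm, "B:1", "B:11", k = 25)
  expect_false(any(duplicated(got$nodes)))
  expect_true(all(diff(got$cost) >= -1e-12))
  expect_true(all(vapply(got$node_index, function(p)
    !any(duplicated(p)), logical(1))))
  # consecutive nodes always share a contact
  n <- as.matrix(tm$n)
  for (p in got$node_index)
    expect_true(all(n[cbind(p[-length(p)], p[-1])] > 0))
})

test_that("unreachable targets and bad queries raise errors", {
  n <- matrix(0, 4, 4); n[1, 2] <- n[2, 1] <- 1; n[3, 4] <- n[4, 3] <- 1
  tm <- tm_from_counts(n)
  expect_error(yen_k_shortest(tm, "A:1", "A:4", k = 3), "no path")
  expect_error(yen_k_shortest(tm, "A:1", "A:1", k = 1), "differ")
  expect_error(yen_k_shortest(tm, "A:1", "A:2", k = 0), "k must be")
})

test_that("k exhausts gracefully when fewer simple paths exist", {
  n <- matrix(0, 3, 3)
  n[1, 2] <- n[2, 1] <- 1; n[2, 3] <- n[3, 2] <- 1
  got <- yen_k_shortest(tm_from_counts(n), "A:1", "A:3", k = 10)
  expect_equal(nrow(got), 1)   # the chain admits a single simple path
})

test_that("chain adjacency derives from angular positions, not labels", {
  fx <- make_pore_pentamer()
  adj <- chain_adjacency(fx$model)
  b <- adj[adj$chain == "B", ]
  expect_equal(b$ccw, "C")   # chains are placed A..E counterclockwise
  expect_equal(b$cw, "A")
  # relabeling chains in reverse must flip the direction sense
  rev_model <- fx$model
  rev_model$atoms$chain <- chartr("ABCDE", "AEDCB", rev_model$atoms$chain)
  rev_model$residues$chain <- chartr("ABCDE", "AEDCB",
                                     rev_model$residues$chain)
  adj2 <- chain_adjacency(rev_model)
  expect_equal(adj2[adj2$chain == "B", ]$ccw, "A")
})

test_that("the protocol runs sources x scenarios x k queries", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  paths <- run_protocol(tm, list(site = "B:13"), fx$gate_resno, "B",
                        fx$model, k = 2)
  expect_equal(nrow(paths), 6)   # 1 source x 3 scenarios x 2 paths
  expect_setequal(unique(paths$scenario), c("intra", "ccw", "cw"))
  expect_equal(paths$target[paths$scenario == "intra"][1], "B:11")
  expect_equal(paths$target[paths$scenario == "ccw"][1], "C:11")
  expect_equal(paths$target[paths$scenario == "cw"][1], "A:11")
})

test_that("rank-1 protocol paths take the expected crossing routes", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  paths <- run_protocol(tm, list(site = c("B:13", "B:1")), fx$gate_resno,
                        "B", fx$model, k = 3)
  paths <- classify_paths(paths, fx$regions, tm)
  r1 <- paths[paths$rank == 1, ]
  expect_true(all(r1$region[r1$scenario == "intra"] == "other"))
  # the interface-proximal source crosses early at the interface pair when
  # heading counterclockwise, and through the gate ring when clockwise
  expect_equal(r1$region[r1$source == "B:13" & r1$scenario == "ccw"],
               "interface")
  expect_equal(r1$region[r1$source == "B:13" & r1$scenario == "cw"], "pore")
  # a source far from the interface descends its own column and crosses at
  # the gate ring in both directions
  expect_true(all(r1$region[r1$source == "B:1" &
                            r1$scenario != "intra"] == "pore"))
  # rank-1 equals the exhaustively enumerated cheapest path
  cost <- as.matrix(tm$cost)
  cost[cost == 0] <- Inf
  src <- match("B:13", tm$residues$key)
  dst <- match("C:11", tm$residues$key)
  want <- enumerate_simple_paths(cost, src, dst)
  got <- r1$node_index[r1$source == "B:13" & r1$scenario == "ccw"][[1]]
  expect_equal(got, want$paths[[1]])
})

test_that("scenario path sets respect the C5 symmetry of the pentamer", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  # B -> A (cw) paths must map onto C -> B paths under chains+1
  pb <- yen_k_shortest(tm, "B:13", "A:11", k = 5)
  pc <- yen_k_shortest(tm, "C:13", "B:11", k = 5)
  expect_equal(chartr("ABCDE", "BCDEA", pb$nodes), pc$nodes)
  expect_equal(pb$cost, pc$cost, tolerance = 1e-12)
})

test_that("pore-lining targets a turn apart give the same incoming route", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  to_gate <- yen_k_shortest(tm, "B:1", "B:11", k = 1)$node_index[[1]]
  below <- yen_k_shortest(tm, "B:1", "B:12", k = 1)$node_index[[1]]
  # identical up to the last 1-2 nodes
  expect_equal(below[seq_along(to_gate)], to_gate)
  expect_lte(length(below) - length(to_gate), 2)
})

test_that("region classification labels interior membership exclusively", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  paths <- yen_k_shortest(tm, "B:13", "C:11", k = 1)
  lab <- classify_paths(paths, fx$regions, tm)
  expect_equal(lab$region, "interface")
  # endpoints never classify: a 2-node path has no interior
  short <- yen_k_shortest(tm, "B:11", "C:11", k = 1)
  expect_equal(classify_paths(short, fx$regions, tm)$region, "other")
  # overlapping regions are rejected
  expect_error(classify_paths(paths, list(a = 1:5, b = 5:8), tm), "overlap")
  # empty path set: all fractions zero, no error
  empty <- paths[0, ]
  frac <- attr(classify_paths(empty, fx$regions, tm), "fractions")
  expect_true(all(frac == 0))
})

test_that("path reports count paths per scenario and region", {
  fx <- make_pore_pentamer()
  tm <- build_transition_model(count_contacts(fx$model))
  paths <- run_protocol(tm, list(site = c("B:13", "B:1")), fx$gate_resno,
                        "B", fx$model, k = 3)
  paths <- classify_paths(paths, fx$regions, tm)
  rep_ <- path_report(paths)
  expect_equal(nrow(rep_$table), 18)
  expect_equal(as.numeric(rowSums(rep_$counts)),
               as.numeric(table(paths$scenario)[rownames(rep_$counts)]))
  expect_equal(sum(rep_$counts), 18)
  single <- path_report(paths[1, ])
  expect_equal(nrow(single$table), 1)
  expect_equal(sum(single$counts), 1)
  f <- tempfile(fileext = ".tsv")
  export_paths(rep_, f)
  expect_equal(nrow(read.delim(f)), 18)
})
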
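test_that("network assembly splits interactors into connected core and bait-only", {
  conserved <- paste0("P", 1:5)
  baits <- c("b1", "b2")
  bait_edges <- tidyr::expand_grid(a = baits, b = conserved)
  known <- list(tibble::tibble(a = c("P1", "P2"), b = c("P2", "P3")))
  net <- assemble_network(conserved, baits, bait_edges, known)
  expect_setequal(net$connected_core, c("P1", "P2", "P3"))
  expect_setequal(net$bait_only, c("P4", "P5"))
  g <- glance(net)
  expect_equal(g$n_connected_core + g$n_bait_only, length(conserved))

  # self-interactions are dropped; known edges outside the conserved set too
  known2 <- list(tibble::tibble(a = c("P1", "P1", "P9"),
                                b = c("P1", "P2", "P1")))
  net2 <- assemble_network(conserved, baits, bait_edges, known2)
  expect_equal(sum(net2$edges$source == "known"), 1)
})

test_that("modularity follows the Newman-Girvan formula", {
  tri <- two_triangles()
  memb_all <- setNames(rep(1, 6), c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(modularity_score(tri, memb_all), 0)

  memb_split <- setNames(c(1, 1, 1, 2, 2, 2),
                         c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(modularity_score(tri, memb_split), 0.5)

  memb_bad <- setNames(c(1, 1, 2, 2, 2, 2),
                       c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_lt(modularity_score(tri, memb_bad), 0.5)

  expect_error(modularity_score(tri[0, ], memb_all), "empty edge set")
})

test_that("modularity agrees with the igraph implementation on random graphs", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(5:9, 1)
    g <- igraph::sample_gnp(n, 0.5)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("v", seq_len(n))
    memb <- sample(1:3, n, replace = TRUE)
    edges <- igraph::as_data_frame(g)[, c("from", "to")]
    mine <- modularity_score(edges, setNames(memb, igraph::V(g)$name))
    theirs <- igraph::modularity(g, memb)
    expect_equal(mine, theirs, tolerance = 1e-12)
  }
})

test_that("exact community search attains the brute-force optimum", {
  # independent oracle: canonicalized label enumeration + igraph modularity
  check_graph <- function(edges) {
    nodes <- sort(unique(c(edges$a, edges$b)))
    part <- detect_communities(edges, exact_limit = 10)
    expect_equal(part$method, "exact")
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    best <- max(vapply(all_partitions_bruteforce(length(nodes)), function(p) {
      igraph::modularity(g, p)
    }, numeric(1)))
    expect_equal(part$Q, best, tolerance = 1e-12)
  }
  check_graph(two_triangles())
  set.seed(31)
  for (i in 1:3) {
    g <- igraph::sample_gnp(6, 0.5)
    while (igraph::ecount(g) == 0) g <- igraph::sample_gnp(6, 0.5)
    igraph::V(g)$name <- paste0("v", 1:6)
    df <- igraph::as_data_frame(g)
    check_graph(tibble::tibble(a = df$from, b = df$to))
  }
})

test_that("exact search recovers planted structure and trivial cases", {
  part <- detect_communities(two_triangles())
  expect_equal(part$Q, 0.5)
  lab <- setNames(part$assignment$community, part$assignment$node)
  expect_equal(length(unique(lab[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(lab[c("b1", "b2", "b3")])), 1)
  expect_false(lab[["a1"]] == lab[["b1"]])

  single <- detect_communities(tibble::tibble(a = "A", b = "B"))
  expect_equal(nrow(single$assignment), 2)
  expect_equal(length(unique(single$assignment$community)), 1)
  expect_equal(single$Q, 0)
})

test_that("the greedy path recovers well-separated cliques on larger graphs", {
  part <- detect_communities(three_cliques(), exact_limit = 5)
  expect_equal(part$method, "greedy")
  lab <- setNames(part$assignment$community, part$assignment$node)
  for (pre in c("x", "y", "z")) {
    expect_equal(length(unique(lab[paste0(pre, 1:4)])), 1)
  }
  expect_equal(length(unique(lab)), 3)
  expect_equal(part$Q, modularity_score(three_cliques(),
                                        part$assignment))
})

test_that("communities are detected on the known-edge subgraph of a network", {
  conserved <- c("a1", "a2", "a3", "b1", "b2", "b3")
  net <- assemble_network(conserved, "bait",
                          tidyr::expand_grid(a = "bait", b = conserved),
                          list(two_triangles()))
  part <- detect_communities(net)
  expect_equal(part$Q, 0.5)  # bait hub edges excluded from the degree null
  expect_false("bait" %in% part$assignment$node)
})
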
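
# normalize an edge table to sorted unordered pairs without self-edges
canonical_edges <- function(edges) {
  edges <- as_tibble(edges)
  names(edges)[1:2] <- c("a", "b")
  edges |>
    filter(.data$a != .data$b) |>
    mutate(lo = pmin(.data$a, .data$b), hi = pmax(.data$a, .data$b)) |>
    distinct(.data$lo, .data$hi) |>
    rename(a = "lo", b = "hi")
}

#' Assemble the conserved-interactor network
#'
#' Builds the network whose nodes are the baits plus the conserved
#' interactors. Bait-prey edges from the AP-MS scoring are tagged `apms`;
#' known protein-protein interactions (e.g. complex-derived pairs and
#' literature compendia) are restricted to pairs with both endpoints in
#' the conserved set and tagged `known`. Self-interactions are removed.
#' Non-bait nodes split into the `connected_core` (at least one known
#' edge) and `bait_only` nodes that remain attached solely to the baits.
#'
#' @param conserved Character vector of conserved prey identifiers.
#' @param baits Character vector of bait identifiers.
#' @param bait_edges Data frame of (bait, prey) pairs (first two columns).
#' @param known_edge_sets List of data frames of known edges (first two
#'   columns are the endpoints), e.g. from [complexes_to_pairs()].
#' @return A `ppi_network`: list with `nodes` (tibble: `node`, `is_bait`),
#'   `edges` (tibble: `a`, `b`, `source`), `connected_core`, `bait_only`.
#' @export
assemble_network <- function(conserved, baits, bait_edges,
                             known_edge_sets = list()) {
  bait_edges <- as_tibble(bait_edges)
  names(bait_edges)[1:2] <- c("a", "b")
  bad <- !(bait_edges$a %in% baits & bait_edges$b %in% conserved)
  bait_edges <- canonical_edges(bait_edges[!bad, , drop = FALSE]) |>
    mutate(source = "apms")

  known <- purrr::map_dfr(known_edge_sets, canonical_edges) |>
    filter(.data$a %in% conserved, .data$b %in% conserved) |>
    distinct() |>
    mutate(source = "known")

  nodes <- tibble(node = c(baits, setdiff(conserved, baits)),
                  is_bait = c(rep(TRUE, length(baits)),
                              rep(FALSE, length(setdiff(conserved, baits)))))
  known_nodes <- unique(c(known$a, known$b))
  non_bait <- nodes$node[!nodes$is_bait]
  structure(list(
    nodes = nodes,
    edges = bind_rows(bait_edges, known),
    connected_core = sort(intersect(non_bait, known_nodes)),
    bait_only = sort(setdiff(non_bait, known_nodes))
  ), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes (%d baits), %d apms + %d known edges\n",
              nrow(x$nodes), sum(x$nodes$is_bait),
              sum(x$edges$source == "apms"), sum(x$edges$source == "known")))
  cat(sprintf("  connected core: %d interactors; bait-only: %d\n",
              length(x$connected_core), length(x$bait_only)))
  invisible(x)
}

#' One-row summary of a PPI network
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts and the connected-core vs
#'   bait-only split of the non-bait interactors.
#' @export
glance.ppi_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes),
         n_baits = sum(x$nodes$is_bait),
         n_interactors = sum(!x$nodes$is_bait),
         n_apms_edges = sum(x$edges$source == "apms"),
         n_known_edges = sum(x$edges$source == "known"),
         n_connected_core = length(x$connected_core),
         n_bait_only = length(x$bait_only))
}

# extract the known-edge subgraph of a ppi_network, or accept a plain
# two-column edge table
known_edge_table <- function(network) {
  if (inherits(network, "ppi_network")) {
    e <- filter(network$edges, .data$source == "known")
    canonical_edges(e[, c("a", "b")])
  } else {
    canonical_edges(network)
  }
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)`: the fraction of edges falling
#' within each community minus its expectation under the degree-preserving
#' random-graph null. Computed on the unweighted known-edge graph when a
#' `ppi_network` is supplied.
#'
#' @param network A `ppi_network` (its known edges are used) or a
#'   two-column edge data frame.
#' @param membership Named vector mapping node to community label, or a
#'   data frame with columns `node` and `community`.
#' @return Modularity Q in \[-1, 1\].
#' @export
modularity_score <- function(network, membership) {
  edges <- known_edge_table(network)
  if (nrow(edges) == 0) abort("modularity is undefined on an empty edge set.")
  if (is.data.frame(membership)) {
    membership <- setNames(membership$community, membership$node)
  }
  missing_nodes <- setdiff(unique(c(edges$a, edges$b)), names(membership))
  if (length(missing_nodes) > 0) {
    abort(paste0("partition does not cover nodes: ",
                 paste(head(missing_nodes, 3), collapse = ", ")))
  }
  m <- nrow(edges)
  comm <- factor(membership)
  k <- nlevels(comm)
  ca <- as.integer(comm[match(edges$a, names(membership))])
  cb <- as.integer(comm[match(edges$b, names(membership))])
  e_c <- tabulate(ca[ca == cb], nbins = k)
  deg <- table(factor(c(edges$a, edges$b), levels = names(membership)))
  d_c <- as.numeric(rowsum(as.numeric(deg), as.integer(comm)))
  sum(e_c / m - (d_c / (2 * m))^2)
}

# enumerate all set partitions of n items as restricted-growth strings
# (lexicographic order); n <= 12 or so
enumerate_partitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

#' Partition a network into communities by modularity maximization
#'
#' On small graphs (up to `exact_limit` nodes) the global optimum is found
#' by exhaustive search over all set partitions, enumerated as
#' restricted-growth strings in lexicographic order; among ties the first
#' (lexicographically smallest canonical labeling) is kept. Larger graphs
#' use the deterministic greedy agglomerative (fast-greedy) modularity
#' heuristic. Only the known-edge subgraph is clustered — bait hub edges
#' would dominate the degree null.
#'
#' @param network A `ppi_network` or two-column edge data frame.
#' @param exact_limit Node count up to which the exhaustive search is used
#'   (default 10; Bell(10) = 115,975 partitions).
#' @return A `community_partition`: list with `assignment` (tibble `node`,
#'   `community`), `Q`, and `method` (`"exact"` or `"greedy"`).
#' @export
detect_communities <- function(network, exact_limit = 10) {
  edges <- known_edge_table(network)
  if (nrow(edges) == 0) abort("community detection needs at least one known edge.")
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  if (n <= exact_limit) {
    parts <- enumerate_partitions(n)
    ia <- match(edges$a, nodes)
    ib <- match(edges$b, nodes)
    deg <- tabulate(c(ia, ib), n)
    m <- nrow(edges)
    best_q <- -Inf
    best <- NULL
    for (p in parts) {
      k <- max(p)
      within <- p[ia] == p[ib]
      e_c <- tabulate(p[ia][within], k)
      d_c <- tabulate(rep.int(p, deg), k)
      q <- sum(e_c) / m - sum((d_c / (2 * m))^2)
      if (q > best_q + 1e-12) {
        best_q <- q
        best <- p
      }
    }
    assignment <- tibble(node = nodes, community = best)
    method <- "exact"
    q <- modularity_score(edges, setNames(best, nodes))
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    cl <- igraph::cluster_fast_greedy(g)
    assignment <- tibble(node = cl$names,
                         community = as.integer(igraph::membership(cl))) |>
      arrange(.data$node)
    method <- "greedy"
    q <- modularity_score(edges, setNames(assignment$community,
                                          assignment$node))
  }
  structure(list(assignment = assignment, Q = q, method = method),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d nodes in %d communities, Q = %.4f (%s)\n",
              nrow(x$assignment), length(unique(x$assignment$community)),
              x$Q, x$method))
  invisible(x)
}

#' Tidy a community partition
#'
#' @param x A `community_partition`.
#' @param ... Unused.
#' @return Tibble with `node` and `community`.
#' @export
tidy.community_partition <- function(x, ...) x$assignment

#' One-row summary of a community partition
#'
#' @param x A `community_partition`.
#' @param ... Unused.
#' @return Tibble with the number of communities, modularity Q, and the
#'   search method used.
#' @export
glance.community_partition <- function(x, ...) {
  tibble(n_nodes = nrow(x$assignment),
         n_communities = length(unique(x$assignment$community)),
         Q = x$Q, method = x$method)
}

#' Attach unconnected interactors to annotated communities
#'
#' Interactors with no known edges cannot be placed by modularity. As a
#' labelling heuristic, each such node joins the community whose most
#' enriched annotation term (smallest adjusted p) annotates the node; nodes
#' annotated by no community's top term — or by the top terms of several
#' communities — stay unassigned (`NA`).
#'
#' @param partition A `community_partition`.
#' @param network The `ppi_network` (supplies the bait-only nodes).
#' @param annotation_map Named list mapping term to protein set.
#' @param background Character vector: the annotation background population.
#' @return The partition with unconnected nodes appended to `assignment`
#'   (community `NA` when unassigned).
#' @export
assign_unconnected <- function(partition, network, annotation_map, background) {
  stopifnot(inherits(partition, "community_partition"),
            inherits(network, "ppi_network"))
  lonely <- setdiff(network$bait_only, partition$assignment$node)
  if (length(lonely) == 0) return(partition)
  comms <- split(partition$assignment$node, partition$assignment$community)
  top_terms <- purrr::imap(comms, function(members, cid) {
    enr <- enrich_annotations(intersect(members, background), background,
                              annotation_map)
    if (nrow(enr) == 0) return(NA_character_)
    enr$term[which.min(enr$p_adjusted)]
  })
  assigned <- purrr::map_int(lonely, function(nd) {
    hits <- which(vapply(top_terms, function(tt) {
      !is.na(tt) && nd %in% annotation_map[[tt]]
    }, logical(1)))
    if (length(hits) == 1L) as.integer(names(comms)[hits]) else NA_integer_
  })
  partition$assignment <- bind_rows(
    partition$assignment,
    tibble(node = lonely, community = assigned)
  )
  partition
}
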
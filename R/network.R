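#' Build a score-thresholded functional network over a query set
#'
#' Induces the subgraph of the functional-association edge table on the
#' query proteins, keeping only edges with `combined_score` strictly greater
#' than `min_score` (0.4 is the conventional medium-confidence floor).
#' Query proteins absent from the edge table's vocabulary are recorded as
#' unmapped.
#'
#' @param query Character vector of accessions, or a data frame with an
#'   `accession` column (an optional `direction` column — `up`/`down`/`none`
#'   — is carried onto the nodes, e.g. the differential subset of
#'   [call_differential()] output).
#' @param edges Edge tibble (`protein_a`, `protein_b`, `combined_score` on
#'   \[0,1\]), e.g. from [read_edge_table()] or [simulate_network()].
#' @param min_score Strict lower bound on retained edge scores.
#' @return An object of class `functional_network`: list with `graph`
#'   (undirected igraph), `nodes` (tibble: accession, direction, degree,
#'   cluster), `unmapped` (accessions absent from the edge vocabulary) and
#'   `min_score`.
#' @export
build_network <- function(query, edges, min_score = 0.4) {
  directions <- as_directions(query)
  query <- as_accessions(query)
  if (length(query) == 0) abort("empty query set")
  edges <- normalize_edges(tibble::as_tibble(edges), "unit")
  vocab <- union(edges$protein_a, edges$protein_b)
  mapped <- sort(intersect(query, vocab))
  unmapped <- sort(setdiff(query, vocab))
  sub <- edges[edges$combined_score > min_score &
                 edges$protein_a %in% mapped &
                 edges$protein_b %in% mapped, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    sub, directed = FALSE,
    vertices = data.frame(name = mapped, stringsAsFactors = FALSE))
  deg <- igraph::degree(g)
  dir <- rep("none", length(mapped))
  if (!is.null(directions)) {
    hit <- mapped %in% names(directions)
    dir[hit] <- unname(directions[mapped[hit]])
  }
  nodes <- tibble::tibble(accession = mapped, direction = dir,
                          degree = as.integer(deg[mapped]),
                          cluster = NA_integer_)
  structure(list(graph = g, nodes = nodes, unmapped = unmapped,
                 min_score = min_score),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf(
    "Functional network: %d mapped node(s) (%d unmapped), %d edge(s) with score > %.2f\n",
    nrow(x$nodes), length(x$unmapped), igraph::ecount(x$graph), x$min_score))
  if (any(!is.na(x$nodes$cluster))) {
    cat(sprintf("  %d cluster(s) of size >= %d\n",
                attr(x, "n_clusters"), attr(x, "min_cluster_size")))
  }
  invisible(x)
}

#' Connectivity summary of a functional network
#'
#' Reports how interconnected the query set is: the number of mapped nodes,
#' the number with at least one connection, and the mean degree
#' `2 |E| / |mapped nodes|`.  Because it is ambiguous whether "average
#' neighbors" should average over all mapped nodes or only the connected
#' ones, both denominators are reported.
#'
#' @param net A `functional_network`.
#' @return One-row tibble: `n_nodes`, `n_connected`, `n_edges`,
#'   `mean_degree`, `mean_degree_connected`.
#' @export
connectivity_summary <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  n_nodes <- nrow(net$nodes)
  n_edges <- igraph::ecount(net$graph)
  n_connected <- sum(net$nodes$degree >= 1)
  tibble::tibble(
    n_nodes = n_nodes,
    n_connected = n_connected,
    n_edges = as.integer(n_edges),
    mean_degree = if (n_nodes > 0) 2 * n_edges / n_nodes else 0,
    mean_degree_connected = if (n_connected > 0) 2 * n_edges / n_connected else 0
  )
}

#' Cluster a functional network by greedy modularity maximization
#'
#' Detects communities on the unweighted thresholded graph (nodes
#' pre-sorted lexicographically, multi-edges and self-loops removed) with
#' deterministic greedy modularity maximization.  Communities reaching
#' `min_cluster_size` are reported as clusters, renumbered by decreasing
#' size (ties by first member); smaller communities and isolated nodes are
#' left unclustered (`NA`).
#'
#' @param net A `functional_network`.
#' @param min_cluster_size Minimum community size reported as a cluster.
#' @return The network with `nodes$cluster` filled in and attributes
#'   `n_clusters` (count of clusters meeting the size floor) and
#'   `cluster_sizes`.
#' @export
cluster_network <- function(net, min_cluster_size = 3) {
  stopifnot(inherits(net, "functional_network"))
  g <- igraph::simplify(net$graph)
  membership <- rep(NA_integer_, nrow(net$nodes))
  names(membership) <- net$nodes$accession
  if (igraph::ecount(g) > 0) {
    comm <- igraph::cluster_fast_greedy(g, weights = NA)
    mem <- igraph::membership(comm)
    sizes <- table(mem)
    keep <- names(sizes)[sizes >= min_cluster_size]
    # renumber: decreasing size, ties by lexicographically first member
    first_member <- vapply(keep, function(k) min(names(mem)[mem == k]), "")
    ord <- keep[order(-as.integer(sizes[keep]), first_member)]
    for (i in seq_along(ord)) {
      membership[names(mem)[mem == ord[i]]] <- i
    }
  }
  net$nodes$cluster <- unname(membership[net$nodes$accession])
  attr(net, "n_clusters") <- length(unique(stats::na.omit(net$nodes$cluster)))
  attr(net, "min_cluster_size") <- min_cluster_size
  attr(net, "cluster_sizes") <-
    as.integer(table(net$nodes$cluster))
  net
}

#' @exportS3Method generics::tidy
tidy.functional_network <- function(x, ...) x$nodes

#' @exportS3Method generics::glance
glance.functional_network <- function(x, ...) {
  dplyr::bind_cols(
    connectivity_summary(x),
    tibble::tibble(n_unmapped = length(x$unmapped),
                   n_clusters = attr(x, "n_clusters") %||% NA_integer_)
  )
}
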
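#' Graph-construction parameters
#'
#' Parameters for building one tissue graph: the affinity-propagation
#' (AP) preference \code{P} controlling exemplar granularity (more
#' negative values yield fewer exemplars and a coarser spatial
#' representation) and the KNN neighbourhood size \code{K} controlling
#' local connectivity. Defaults \code{K = 4}, \code{P = -50} are the
#' configuration the sensitivity grid identifies as most stable.
#'
#' @param K Integer KNN neighbourhood size.
#' @param P AP preference (self-similarity); negative in all regimes
#'   used here since similarities are negative squared distances.
#' @param damping AP damping factor in (0.5, 1).
#' @param max_iter Maximum AP message-passing iterations.
#' @param conv_iter Iterations the exemplar set must stay unchanged to
#'   declare convergence.
#' @param seed Seed for the symmetry-breaking similarity jitter.
#' @return Object of class \code{graph_params}.
#' @export
graph_params <- function(K = 4L, P = -50, damping = 0.9, max_iter = 1000L,
                         conv_iter = 50L, seed = 1L) {
  stopifnot(K >= 1L, damping > 0.5, damping < 1, max_iter >= 1L,
            conv_iter >= 1L)
  structure(list(K = as.integer(K), P = P, damping = damping,
                 max_iter = as.integer(max_iter),
                 conv_iter = as.integer(conv_iter),
                 seed = as.integer(seed)),
            class = "graph_params")
}

#' Affinity-propagation clustering of 2-D points
#'
#' Exemplar-based clustering by responsibility/availability message
#' passing. Similarity is the negative squared Euclidean distance in
#' the input units; the shared preference sits on the diagonal. A tiny
#' seeded jitter (magnitude 1e-6) is added to off-diagonal similarities
#' to break exact symmetry degeneracies, so results are deterministic
#' given \code{(points, preference, seed)}. Points are used in the
#' order given; callers wanting order invariance should sort first (as
#' \code{\link{build_tissue_graph}} does).
#'
#' @param points Numeric matrix with 2 columns (row, col coordinates).
#' @param preference Shared diagonal preference (typically negative).
#' @param damping,max_iter,conv_iter Message-passing controls.
#' @param seed Jitter seed.
#' @return List with \code{exemplars} (1-based indices into
#'   \code{points}), \code{assignments} (1-based exemplar index per
#'   point) and \code{converged}. Warns (and returns the current state)
#'   on non-convergence.
#' @export
ap_cluster <- function(points, preference = -50, damping = 0.9,
                       max_iter = 1000L, conv_iter = 50L, seed = 1L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  stopifnot(n >= 1L, ncol(points) == 2L)
  if (n == 1L) {
    return(list(exemplars = 1L, assignments = 1L, converged = TRUE))
  }
  d2 <- as.matrix(stats::dist(points))^2
  S <- -d2
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(seed)
  jit <- matrix(stats::runif(n * n, -1e-6, 1e-6), n, n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  S <- S + jit
  diag(S) <- preference
  res <- .ap_message_passing(S, damping, as.integer(max_iter),
                             as.integer(conv_iter))
  if (!res$converged) {
    warning("affinity propagation did not converge within ", max_iter,
            " iterations; returning current exemplar set")
  }
  ref <- .refine_exemplars(S, res$exemplars)
  list(exemplars = ref$exemplars, assignments = ref$assignments,
       converged = res$converged)
}

# medoid refinement of the converged exemplar set: alternately reassign
# points to their most similar exemplar and re-pick each cluster's
# exemplar as the member maximizing the within-cluster similarity sum
# (diagonal = preference), until stable
.refine_exemplars <- function(S, exemplars) {
  E <- sort(exemplars)
  repeat {
    assign <- E[max.col(S[, E, drop = FALSE], ties.method = "first")]
    assign[E] <- E
    newE <- sort(unique(vapply(unique(assign), function(e) {
      mem <- which(assign == e)
      mem[which.max(colSums(S[mem, mem, drop = FALSE]))]
    }, integer(1))))
    if (identical(newE, E)) break
    E <- newE
  }
  assign <- E[max.col(S[, E, drop = FALSE], ties.method = "first")]
  assign[E] <- E
  list(exemplars = E, assignments = assign)
}

#' KNN edges over node positions
#'
#' Each node is linked to its \code{K} nearest other nodes by Euclidean
#' distance (all others when fewer than \code{K} exist); distance ties
#' are broken by the lower node index. The directed KNN relation is
#' symmetrized by union, which preserves connectivity of boundary
#' nodes.
#'
#' @param node_positions Numeric matrix of node coordinates (2 cols).
#' @param K Neighbourhood size.
#' @return Integer matrix of undirected edges (2 columns, 1-based,
#'   \code{from < to}), zero rows for a single node.
#' @export
knn_edges <- function(node_positions, K = 4L) {
  node_positions <- as.matrix(node_positions)
  n <- nrow(node_positions)
  stopifnot(n >= 1L, K >= 1L)
  if (n == 1L) return(matrix(integer(0), 0L, 2L,
                             dimnames = list(NULL, c("from", "to"))))
  D <- as.matrix(stats::dist(node_positions))
  kk <- min(K, n - 1L)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(kk)]  # ties -> lower index
    pairs[[i]] <- cbind(pmin(i, nb), pmax(i, nb))
  }
  e <- unique(do.call(rbind, pairs))
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  colnames(e) <- c("from", "to")
  storage.mode(e) <- "integer"
  e
}

#' Build the spatial graph of one tissue compartment
#'
#' Composes \code{\link{extract_compartment}},
#' \code{\link{ap_cluster}} and \code{\link{knn_edges}}: compartment
#' tiles are clustered by affinity propagation in tile-index
#' coordinates, the exemplar tiles become graph nodes, and nodes are
#' connected to their K nearest neighbours. Tiles are sorted
#' canonically (row-major) before clustering so the graph is invariant
#' to input tile ordering. An empty compartment yields a valid graph
#' with zero nodes, flagged empty.
#'
#' @param tta A \code{\link{tta_image}}.
#' @param compartment Compartment name (see \code{TTA_COMPARTMENTS}).
#' @param params A \code{\link{graph_params}}.
#' @return Object of class \code{tissue_graph}: \code{node_positions}
#'   (exemplar tile coordinates, tile units), \code{edges},
#'   \code{assignments} (tile -> node index), \code{n_tiles},
#'   \code{compartment}, \code{params}, \code{empty}.
#' @export
build_tissue_graph <- function(tta, compartment, params = graph_params()) {
  pts <- extract_compartment(tta, compartment)
  if (nrow(pts) == 0L) {
    g <- list(compartment = compartment,
              node_positions = matrix(numeric(0), 0L, 2L,
                                      dimnames = list(NULL, c("row", "col"))),
              edges = matrix(integer(0), 0L, 2L,
                             dimnames = list(NULL, c("from", "to"))),
              assignments = integer(0), n_tiles = 0L, params = params,
              empty = TRUE)
    return(structure(g, class = "tissue_graph"))
  }
  # extract_compartment already returns canonical row-major order
  cl <- ap_cluster(pts, preference = params$P, damping = params$damping,
                   max_iter = params$max_iter, conv_iter = params$conv_iter,
                   seed = params$seed)
  node_pos <- pts[cl$exemplars, , drop = FALSE]
  colnames(node_pos) <- c("row", "col")
  edges <- knn_edges(node_pos, params$K)
  assignments <- match(cl$assignments, cl$exemplars)
  structure(list(compartment = compartment, node_positions = node_pos,
                 edges = edges, assignments = assignments,
                 n_tiles = nrow(pts), params = params, empty = FALSE),
            class = "tissue_graph")
}

#' @export
print.tissue_graph <- function(x, ...) {
  cat(sprintf("tissue_graph [%s]: %d nodes, %d edges (from %d tiles; K=%d, P=%g)\n",
              x$compartment, nrow(x$node_positions), nrow(x$edges),
              x$n_tiles, x$params$K, x$params$P))
  invisible(x)
}

#' Number of nodes of a tissue graph
#' @param graph A \code{tissue_graph}.
#' @return Integer node count.
#' @export
n_nodes <- function(graph) nrow(graph$node_positions)

#' Convert a tissue graph to an igraph object
#'
#' @param graph A \code{tissue_graph}.
#' @return An undirected \code{igraph} graph with \code{row}/\code{col}
#'   vertex attributes.
#' @export
as_igraph <- function(graph) {
  n <- n_nodes(graph)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, t(graph$edges))
  }
  if (n > 0L) {
    g <- igraph::set_vertex_attr(g, "row", value = graph$node_positions[, 1L])
    g <- igraph::set_vertex_attr(g, "col", value = graph$node_positions[, 2L])
  }
  g
}

#' Export a tissue graph to GraphML
#'
#' Node attributes \code{row}/\code{col} and graph attributes
#' \code{compartment}, \code{K}, \code{P}, \code{n_tiles} are written.
#'
#' @param graph A \code{tissue_graph}.
#' @param path Output GraphML path.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  g <- igraph::set_graph_attr(g, "compartment", graph$compartment)
  g <- igraph::set_graph_attr(g, "K", graph$params$K)
  g <- igraph::set_graph_attr(g, "P", graph$params$P)
  g <- igraph::set_graph_attr(g, "n_tiles", graph$n_tiles)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a tissue graph edge list as CSV
#'
#' @param graph A \code{tissue_graph}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_edge_csv <- function(graph, path) {
  utils::write.csv(as.data.frame(graph$edges), path, row.names = FALSE)
  invisible(path)
}
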
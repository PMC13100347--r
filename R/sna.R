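#' SNA summarization parameters
#'
#' @param n_bins Histogram bins per node-level metric.
#' @param katz_alpha Katz attenuation; \code{NULL} selects
#'   \code{min(0.1, 0.85 / lambda_max)} per graph, where
#'   \code{lambda_max} is the largest adjacency eigenvalue, which
#'   guarantees the Katz series converges.
#' @param katz_beta Katz baseline weight.
#' @param community_method Community detection method; only greedy
#'   modularity maximization is implemented.
#' @return Object of class \code{sna_params}.
#' @export
sna_params <- function(n_bins = 10L, katz_alpha = NULL, katz_beta = 1,
                       community_method = "greedy_modularity") {
  stopifnot(n_bins >= 1L,
            community_method == "greedy_modularity")
  structure(list(n_bins = as.integer(n_bins), katz_alpha = katz_alpha,
                 katz_beta = katz_beta, community_method = community_method),
            class = "sna_params")
}

.metric_order <- c("ND", "CL", "CC", "DC", "KC", "CS")
.summary_names <- c(paste0("hist_", 0:9), "mean", "sd", "max", "min", "median")

#' Names of the 91 SNA feature slots, in order
#'
#' For each node-level metric in the fixed order ND (node degree), CL
#' (clustering coefficient), CC (closeness centrality), DC (degree
#' centrality), KC (Katz centrality), CS (community structure): 10
#' histogram frequencies then mean, standard deviation, maximum,
#' minimum, median. The final slot is the graph-level network density
#' NED.
#'
#' @return Character vector of length 91.
#' @export
sna_feature_names <- function() {
  c(as.vector(t(outer(.metric_order, .summary_names, paste, sep = "_"))),
    "NED")
}

.adjacency <- function(graph) {
  n <- n_nodes(graph)
  A <- matrix(0, n, n)
  if (nrow(graph$edges) > 0L) {
    A[graph$edges] <- 1
    A[graph$edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Node degrees
#'
#' @param graph A \code{tissue_graph}.
#' @return Numeric vector, one value per node.
#' @export
node_degrees <- function(graph) {
  n <- n_nodes(graph)
  stopifnot(n >= 1L)
  as.numeric(tabulate(c(graph$edges), nbins = n))
}

#' Degree centralities (degree / (n - 1); 0 for a single node)
#'
#' @param graph A \code{tissue_graph}.
#' @return Numeric vector in \code{[0, 1]}.
#' @export
degree_centralities <- function(graph) {
  n <- n_nodes(graph)
  if (n <= 1L) return(rep(0, n))
  node_degrees(graph) / (n - 1)
}

#' Local clustering coefficients
#'
#' \code{CL(v) = 2 T(v) / (deg(v) (deg(v) - 1))} with \code{T(v)} the
#' number of triangles through \code{v}; 0 when \code{deg(v) < 2}.
#'
#' @param graph A \code{tissue_graph}.
#' @return Numeric vector in \code{[0, 1]}.
#' @export
clustering_coefficients <- function(graph) {
  n <- n_nodes(graph)
  stopifnot(n >= 1L)
  cl <- igraph::transitivity(as_igraph(graph), type = "localundirected",
                             isolates = "zero")
  cl[!is.finite(cl)] <- 0  # degree-1 nodes
  cl
}

#' Closeness centralities (component-size scaled)
#'
#' KNN graphs can be disconnected, so closeness is computed per
#' connected component and scaled by component size:
#' \code{CC(v) = ((n_c - 1)/(n - 1)) * ((n_c - 1) / sum of distances
#' within the component)}. Isolated nodes and single-node graphs score
#' 0. Distances are unweighted shortest-path lengths.
#'
#' @param graph A \code{tissue_graph}.
#' @return Numeric vector, non-negative.
#' @export
closeness_centralities <- function(graph) {
  n <- n_nodes(graph)
  stopifnot(n >= 1L)
  if (n == 1L) return(0)
  D <- igraph::distances(as_igraph(graph))
  cc <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    n_c <- length(reach) + 1L
    if (n_c > 1L) {
      cc[v] <- ((n_c - 1) / (n - 1)) * ((n_c - 1) / sum(D[v, reach]))
    }
  }
  cc
}

#' Katz centralities
#'
#' Solves \code{(I - alpha A) x = beta 1} for the symmetric adjacency
#' matrix \code{A}, then scales \code{x} to unit Euclidean norm.
#' Requires \code{alpha * lambda_max < 1}.
#'
#' @param graph A \code{tissue_graph}.
#' @param katz_alpha Attenuation; \code{NULL} for the per-graph default
#'   \code{min(0.1, 0.85/lambda_max)}.
#' @param katz_beta Baseline weight.
#' @return Numeric vector of unit Euclidean norm.
#' @export
katz_centralities <- function(graph, katz_alpha = NULL, katz_beta = 1) {
  n <- n_nodes(graph)
  stopifnot(n >= 1L)
  A <- .adjacency(graph)
  lam <- if (n == 1L || all(A == 0)) 0 else {
    max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  }
  alpha <- if (is.null(katz_alpha)) {
    if (lam > 0) min(0.1, 0.85 / lam) else 0.1
  } else katz_alpha
  if (lam > 0 && alpha * lam >= 1) {
    stop("katz_alpha too large for this graph (alpha * lambda_max >= 1); ",
         "lower alpha below ", format(1 / lam))
  }
  x <- solve(diag(n) - alpha * A, rep(katz_beta, n))
  x / sqrt(sum(x^2))
}

#' Network density
#'
#' \code{NED = 2 m / (n (n - 1))}; 0 for a single-node graph.
#'
#' @param graph A \code{tissue_graph}.
#' @return Scalar in \code{[0, 1]}.
#' @export
network_density <- function(graph) {
  n <- n_nodes(graph)
  stopifnot(n >= 1L)
  if (n == 1L) return(0)
  2 * nrow(graph$edges) / (n * (n - 1))
}

#' Normalized community sizes
#'
#' Partitions nodes by greedy modularity maximization and assigns each
#' node the size of its community divided by the node count, so values
#' lie in \code{(0, 1]}.
#'
#' @param graph A \code{tissue_graph}.
#' @param community_method Only \code{"greedy_modularity"}.
#' @return Numeric vector in \code{(0, 1]}.
#' @export
community_sizes <- function(graph, community_method = "greedy_modularity") {
  stopifnot(community_method == "greedy_modularity")
  n <- n_nodes(graph)
  stopifnot(n >= 1L)
  if (n == 1L) return(1)
  memb <- .greedy_modularity(n, graph$edges)
  sz <- tabulate(memb)
  sz[memb] / n
}

# CNM greedy modularity maximization over the merge dendrogram:
# repeatedly merge the connected community pair with the largest
# modularity gain (ties broken by the smallest member indices), and
# return the partition of maximal modularity along the sequence
# (coarsest on ties)
.greedy_modularity <- function(n, edges) {
  m <- nrow(edges)
  if (m == 0L) return(seq_len(n))
  # E[i, j]: fraction of edge ends between communities i and j
  E <- matrix(0, n, n)
  for (r in seq_len(m)) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    E[i, j] <- E[i, j] + 1
    E[j, i] <- E[j, i] + 1
  }
  E <- E / (2 * m)
  comm <- seq_len(n)          # current community of each node
  alive <- rep(TRUE, n)
  minmem <- seq_len(n)        # smallest member index per community
  a <- rowSums(E)
  Q <- sum(diag(E)) - sum(a^2)
  best_Q <- Q
  best_comm <- comm
  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    dQ <- 2 * (E[idx, idx, drop = FALSE] - outer(a[idx], a[idx]))
    conn <- E[idx, idx, drop = FALSE] > 0
    diag(conn) <- FALSE
    if (!any(conn)) break
    dQ[!conn] <- -Inf
    mx <- max(dQ)
    cand <- which(dQ >= mx - 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ord <- order(minmem[idx[cand[, 1L]]], minmem[idx[cand[, 2L]]])
    ci <- idx[cand[ord[1L], 1L]]; cj <- idx[cand[ord[1L], 2L]]
    # merge cj into ci
    E[ci, ] <- E[ci, ] + E[cj, ]
    E[, ci] <- E[, ci] + E[, cj]
    alive[cj] <- FALSE
    a[ci] <- a[ci] + a[cj]
    comm[comm == cj] <- ci
    minmem[ci] <- min(minmem[ci], minmem[cj])
    Q <- Q + mx
    if (Q >= best_Q - 1e-12) {  # coarser partition preferred on ties
      best_Q <- max(best_Q, Q)
      best_comm <- comm
    }
  }
  match(best_comm, sort(unique(best_comm)))
}

#' Summarize one node-level metric into 15 values
#'
#' A histogram with \code{n_bins} equal-width bins over the observed
#' \code{[min, max]} range (last bin right-closed), emitted as
#' frequencies (counts / n), followed by mean, population standard
#' deviation, maximum, minimum and median. An all-equal input collapses
#' to frequency 1 in bin 0 with zero standard deviation.
#'
#' @param values Numeric vector (at least one value).
#' @param n_bins Number of histogram bins.
#' @return Numeric vector of length \code{n_bins + 5}.
#' @export
summarize_metric <- function(values, n_bins = 10L) {
  if (length(values) == 0L) stop("cannot summarize an empty metric vector")
  n <- length(values)
  lo <- min(values); hi <- max(values)
  counts <- numeric(n_bins)
  if (hi > lo) {
    idx <- pmin(floor((values - lo) / (hi - lo) * n_bins) + 1L, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
  } else {
    counts[1L] <- n
  }
  pop_sd <- sqrt(sum((values - mean(values))^2) / n)
  c(counts / n, mean(values), pop_sd, hi, lo, stats::median(values))
}

#' Extract the 91-dimensional SNA feature vector of a tissue graph
#'
#' Six node-level metrics (ND, CL, CC, DC, KC, CS), each summarized
#' into 10 histogram frequencies plus mean, population standard
#' deviation, maximum, minimum and median (15 values), followed by the
#' graph-level network density NED: 6 x 15 + 1 = 91 values in a fixed,
#' named order. An empty graph yields an all-zero vector with attribute
#' \code{valid = FALSE}.
#'
#' @param graph A \code{tissue_graph}.
#' @param params An \code{\link{sna_params}}.
#' @return Named numeric vector of length 91 with attribute
#'   \code{valid}.
#' @export
extract_sna_features <- function(graph, params = sna_params()) {
  nms <- sna_feature_names()
  if (isTRUE(graph$empty) || n_nodes(graph) == 0L) {
    return(structure(stats::setNames(rep(0, 91L), nms), valid = FALSE))
  }
  metrics <- list(
    ND = node_degrees(graph),
    CL = clustering_coefficients(graph),
    CC = closeness_centralities(graph),
    DC = degree_centralities(graph),
    KC = katz_centralities(graph, params$katz_alpha, params$katz_beta),
    CS = community_sizes(graph, params$community_method)
  )
  vals <- unlist(lapply(metrics[.metric_order], summarize_metric,
                        n_bins = params$n_bins), use.names = FALSE)
  structure(stats::setNames(c(vals, network_density(graph)), nms),
            valid = TRUE)
}

#' Tabulate SNA feature vectors as a data frame
#'
#' One row per (patient, compartment) with the 91 named feature
#' columns, suitable for CSV export.
#'
#' @param feature_list Named list: for each patient id, a named list of
#'   compartment -> SNA feature vector.
#' @return Data frame with \code{patient_id}, \code{compartment},
#'   \code{valid} and 91 feature columns.
#' @export
sna_feature_table <- function(feature_list) {
  rows <- list()
  for (pid in names(feature_list)) {
    for (comp in names(feature_list[[pid]])) {
      v <- feature_list[[pid]][[comp]]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, compartment = comp,
        valid = isTRUE(attr(v, "valid")),
        as.list(v), check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}
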
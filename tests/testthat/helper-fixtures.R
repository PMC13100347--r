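# shared fixtures and independent oracles used across the suite

# build a tissue_graph directly from an edge list (positions are dummy)
toy_graph <- function(n, edge_pairs = NULL) {
  e <- if (is.null(edge_pairs) || length(edge_pairs) == 0L) {
    matrix(integer(0), 0L, 2L)
  } else {
    matrix(as.integer(edge_pairs), ncol = 2L, byrow = TRUE)
  }
  colnames(e) <- c("from", "to")
  structure(list(compartment = "TUMOR",
                 node_positions = cbind(row = seq_len(n), col = 0),
                 edges = e, assignments = seq_len(n), n_tiles = n,
                 params = graph_params(), empty = FALSE),
            class = "tissue_graph")
}

random_toy_graph <- function(n, p = 0.35) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  e <- which(A == 1L, arr.ind = TRUE)
  colnames(e) <- c("from", "to")
  storage.mode(e) <- "integer"
  toy_graph_from_edges(n, e)
}

toy_graph_from_edges <- function(n, e) {
  g <- toy_graph(n)
  g$edges <- e
  g
}

adjacency_of <- function(graph) {
  n <- n_nodes(graph)
  A <- matrix(0L, n, n)
  if (nrow(graph$edges) > 0L) {
    A[graph$edges] <- 1L
    A[graph$edges[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

# --- independent oracles ---------------------------------------------------

# triangles through each vertex by brute-force triple enumeration
oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1L)
    d <- length(nb)
    if (d < 2L) return(0)
    tri <- 0L
    for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
      if (A[nb[i], nb[j]] == 1L) tri <- tri + 1L
    }
    2 * tri / (d * (d - 1))
  })
}

# BFS shortest-path distances from one source
oracle_bfs <- function(A, src) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in which(A[v, ] == 1L)) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# component-size-scaled closeness from BFS distances
oracle_closeness <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(0)
  sapply(seq_len(n), function(v) {
    d <- oracle_bfs(A, v)
    reach <- which(is.finite(d) & seq_len(n) != v)
    nc <- length(reach) + 1L
    if (nc == 1L) return(0)
    ((nc - 1) / (n - 1)) * ((nc - 1) / sum(d[reach]))
  })
}

# Katz centrality by truncated power series (independent of solve())
oracle_katz <- function(A, alpha, beta = 1, terms = 400L) {
  n <- nrow(A)
  x <- rep(0, n)
  term <- rep(beta, n)
  for (k in seq_len(terms)) {
    x <- x + term
    term <- alpha * (A %*% term)
  }
  x <- as.numeric(x)
  x / sqrt(sum(x^2))
}

# net similarity of an exemplar set (clean similarities, shared preference)
oracle_net_similarity <- function(S, pref, E) {
  rest <- setdiff(seq_len(nrow(S)), E)
  v <- length(E) * pref
  if (length(rest) > 0L) {
    v <- v + sum(apply(S[rest, E, drop = FALSE], 1L, max))
  }
  v
}

# exhaustive search over all non-empty exemplar subsets
oracle_best_subset <- function(S, pref, max_size = nrow(S)) {
  n <- nrow(S)
  best <- -Inf
  for (m in seq_len(min(max_size, n))) {
    for (E in utils::combn(n, m, simplify = FALSE)) {
      v <- oracle_net_similarity(S, pref, E)
      if (v > best) best <- v
    }
  }
  best
}

# tiny clustered point set: k well-separated blobs of 2-3 points
clustered_points <- function(k = 2L) {
  repeat {
    ctr <- cbind(stats::runif(k, 0, 40), stats::runif(k, 0, 40))
    if (k == 1L || min(stats::dist(ctr)) >= 15) break
  }
  npb <- sample(2:3, k, replace = TRUE)
  do.call(rbind, lapply(seq_len(k), function(j) {
    cbind(ctr[j, 1L] + stats::runif(npb[j], -1, 1),
          ctr[j, 2L] + stats::runif(npb[j], -1, 1))
  }))
}

# paired-bootstrap comparison of two correlated AUCs (stratified resampling)
oracle_bootstrap_delong <- function(a, b, y, B = 10000L, seed = 1L) {
  set.seed(seed)
  auc <- function(s, yy) {
    r <- rank(s)
    n1 <- sum(yy == 1); n0 <- sum(yy == 0)
    (sum(r[yy == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pos <- which(y == 1); neg <- which(y == 0)
  d_obs <- auc(a, y) - auc(b, y)
  d <- numeric(B)
  for (i in seq_len(B)) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    d[i] <- auc(a[idx], y[idx]) - auc(b[idx], y[idx])
  }
  2 * stats::pnorm(-abs(d_obs) / stats::sd(d))
}

# --- cohort fixtures -------------------------------------------------------

# scaled-down study conditions: same planted effects as sim_config()
# defaults, smaller grids for test runtime
recovery_config <- function(...) {
  sim_config(grid_rows = 36L, grid_cols = 36L, tumor_seed_count = 1L,
             tumor_disc_radius = 7, stroma_band = 5, ...)
}

# matched null: no group differences anywhere
null_config <- function() {
  recovery_config(itil_rate = c(0.08, 0.08), stil_rate = c(0.12, 0.12),
                  cluster_scale = c(4, 4), embedding_effect = 0,
                  clinical_effects = list(
                    er_prev = c(0.80, 0.80), pr_prev = c(0.76, 0.76),
                    ratio_meanlog = log(4), ratio_sdlog = 0.5,
                    ratio_shift = 0,
                    cep17_meanlog = log(2.2), cep17_sdlog = 0.3))
}

split_cohort <- function(cohort, test_fraction = 0.2, seed = 1L) {
  y <- cohort_labels(cohort)
  set.seed(seed)
  test_idx <- unlist(lapply(split(seq_along(y), y), function(i)
    sample(i, round(test_fraction * length(i)))))
  tr <- cohort; tr$patients <- tr$patients[-test_idx]
  te <- cohort; te$patients <- te$patients[test_idx]
  list(train = tr, test = te)
}

# single-configuration classifier grid used by the heavier harness tests
light_config <- function(seed = 1L) {
  model_config(mlp_grid = list(hidden = list(64L), l2 = 1e-3), seed = seed)
}

# held-out AUC of the stroma pipeline on one simulated cohort
stroma_holdout_auc <- function(cfg, seed, feature_set = c("sna", "clinical")) {
  coh <- simulate_cohort(200L, cfg, seed = seed)
  sp <- split_cohort(coh, 0.2, seed + 5000L)
  fit <- suppressWarnings(fit_response_model(
    sp$train, "STROMA", feature_set, config = light_config(seed)))
  evaluate(predict(fit, sp$test), cohort_labels(sp$test))$auc
}
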
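#' Binarize a connectivity matrix at a fixed edge density
#'
#' Implements the percentile-threshold rule used for wPLI matrices: keep the
#' top `density` fraction of pair weights (95th percentile at the default
#' `density = 0.05`), i.e. exactly `k = ceiling(density * n_pairs)` edges.
#' Ties at the threshold are broken by lexicographic pair order, which makes
#' the rule deterministic.
#'
#' @param w symmetric numeric matrix of pair weights (e.g. one band of a
#'   `netsig_connectivity`), or a `netsig_connectivity` (binarizes each band)
#' @param density fraction of pairs to keep, in (0, 1)
#' @return binary symmetric adjacency matrix with zero diagonal (or a named
#'   list of them, one per band)
#' @export
binarize_top_edges <- function(w, density = 0.05) {
  if (inherits(w, "netsig_connectivity")) {
    return(lapply(w$bands, binarize_top_edges, density = density))
  }
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (density <= 0 || density >= 1) {
    abort_netsig("`density` must lie in (0, 1).", "netsig_parameter_error")
  }
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  if (length(unique(wt)) == 1) {
    warn_netsig("All pair weights are equal; edge selection falls back to lexicographic order.",
                "netsig_degenerate_weights")
  }
  k <- ceiling(density * length(wt))
  ord <- order(-wt, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  A <- matrix(0L, n, n, dimnames = dimnames(w))
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  A
}

as_graph <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (!isTRUE(all.equal(unname(A), unname(t(A)))) || any(diag(A) != 0)) {
    abort_netsig("Adjacency must be symmetric with zero diagonal.",
                 "netsig_parameter_error")
  }
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

#' Clustering coefficient
#'
#' Local clustering (triangles over possible neighbor pairs), 0 for nodes of
#' degree < 2; network segregation.
#'
#' @param A binary symmetric adjacency matrix
#' @return list with `per_node` and the mean `C`
#' @export
clustering_coefficient <- function(A) {
  g <- as_graph(A)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(per_node = cc, C = mean(cc))
}

#' Characteristic path length
#'
#' Mean shortest-path length over mutually reachable node pairs; unreachable
#' pairs are excluded from the mean (the convention for graphs that
#' disconnect at sparse densities). Edgeless graphs are undefined.
#'
#' @param A binary symmetric adjacency matrix
#' @return scalar lambda (>= 1)
#' @export
characteristic_path_length <- function(A) {
  g <- as_graph(A)
  d <- igraph::distances(g)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0) {
    abort_netsig("No mutually reachable pair: path length is undefined.",
                 "netsig_undefined_metric")
  }
  mean(v)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all unordered pairs, with
#' `1/Inf = 0` for unreachable pairs; parallel information-transfer capacity.
#'
#' @param A binary symmetric adjacency matrix
#' @return scalar gE in `[0, 1]`
#' @export
global_efficiency <- function(A) {
  g <- as_graph(A)
  d <- igraph::distances(g)
  v <- d[upper.tri(d)]
  mean(ifelse(is.finite(v) & v > 0, 1 / v, 0))
}

#' Betweenness centrality
#'
#' Shortest-path betweenness with equal splitting across equal-length
#' geodesics, normalized by `(n-1)(n-2)/2` so node values lie in `[0, 1]`.
#'
#' @param A binary symmetric adjacency matrix
#' @return list with `per_node` and the mean `BtwC`
#' @export
betweenness_centrality <- function(A) {
  g <- as_graph(A)
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  list(per_node = unname(b), BtwC = mean(b))
}

#' Modularity of the best greedy partition
#'
#' Community structure by greedy agglomerative modularity optimization
#' (deterministic given the graph); returns the modularity
#' `Q = sum_c (e_c/m - (d_c/2m)^2)` of the partition found. Global
#' optimality is not claimed.
#'
#' @param A binary symmetric adjacency matrix with at least one edge
#' @param seed retained for interface stability; the greedy optimizer is
#'   deterministic
#' @return list with `Q` and the community `membership`
#' @export
modularity_graph <- function(A, seed = 1L) {
  g <- as_graph(A)
  if (igraph::ecount(g) < 1) {
    abort_netsig("Modularity is undefined on an edgeless graph.",
                 "netsig_undefined_metric")
  }
  cl <- with_seed(seed, igraph::cluster_fast_greedy(g))
  list(Q = igraph::modularity(g, igraph::membership(cl)),
       membership = as.integer(igraph::membership(cl)))
}

#' Evaluate modularity Q for a given partition
#'
#' Direct evaluation of `Q = sum_c (e_c/m - (d_c/2m)^2)` for an arbitrary
#' membership vector (used to score known partitions).
#'
#' @param A binary symmetric adjacency matrix
#' @param membership integer community labels, one per node
#' @return scalar Q
#' @export
modularity_eval <- function(A, membership) {
  g <- as_graph(A)
  igraph::modularity(g, membership)
}

#' Degree-preserving random reference graph
#'
#' Double-edge-swap randomization that preserves the degree sequence exactly
#' (self-loops and multi-edges rejected); the null model for the small-world
#' index. Connectedness is not enforced.
#'
#' @param A binary symmetric adjacency matrix
#' @param n_swaps number of swap attempts (default `10 * |E|`)
#' @param seed RNG seed for the swap sequence
#' @return a randomized adjacency matrix with the same degree sequence
#' @export
random_reference <- function(A, n_swaps = NULL, seed = 1L) {
  g <- as_graph(A)
  m <- igraph::ecount(g)
  if (m < 2) {
    warn_netsig("Fewer than 2 edges: no degree-preserving swap is possible.",
                "netsig_degenerate_graph")
    return(A)
  }
  n_swaps <- n_swaps %||% (10 * m)
  gr <- with_seed(seed, igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                                 niter = n_swaps)))
  B <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
  dimnames(B) <- dimnames(A)
  storage.mode(B) <- "integer"
  B
}

largest_component <- function(A) {
  g <- as_graph(A)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  A[keep, keep, drop = FALSE]
}

#' Small-world index
#'
#' `SWI = (C / <C_rand>) / (lambda / <lambda_rand>)`, where the angle
#' brackets average `n_null` degree-preserving random references. Computed on
#' the largest connected component, which must have at least 4 nodes; path
#' lengths use the reachable-pairs convention on observed and null graphs
#' alike. Values > 1 indicate small-world organization; lower values a more
#' regular (lattice-like) or less integrated topology.
#'
#' @param A binary symmetric adjacency matrix
#' @param n_null number of random reference graphs
#' @param seed RNG seed (one sub-seed per null)
#' @return scalar SWI
#' @export
small_world_index <- function(A, n_null = 20, seed = 1L) {
  Ac <- largest_component(A)
  if (nrow(Ac) < 4) {
    abort_netsig("Largest component has fewer than 4 nodes: SWI undefined.",
                 "netsig_undefined_metric")
  }
  C_obs <- clustering_coefficient(Ac)$C
  l_obs <- characteristic_path_length(Ac)
  C_r <- numeric(n_null)
  l_r <- numeric(n_null)
  for (i in seq_len(n_null)) {
    R <- random_reference(Ac, seed = derive_seed(seed, i))
    C_r[i] <- clustering_coefficient(R)$C
    l_r[i] <- characteristic_path_length(R)
  }
  if (mean(C_r) <= 0 || !is.finite(mean(l_r)) || mean(l_r) <= 0) {
    abort_netsig("Null model yields zero clustering or undefined path length: SWI undefined.",
                 "netsig_undefined_metric")
  }
  (C_obs / mean(C_r)) / (l_obs / mean(l_r))
}

#' All graph-theory metrics for a binarized connectivity matrix
#'
#' Binarizes each band's wPLI matrix at the given density and computes the
#' six topology metrics. SWI (and modularity) are NA when undefined for a
#' band (e.g. too-small largest component), with the condition recorded in
#' the `note` column.
#'
#' @param cm a `netsig_connectivity` or a named list of weight matrices
#' @param density binarization edge density
#' @param n_null nulls for the small-world index
#' @param seed RNG seed
#' @return tibble with columns `band`, `Q`, `swi`, `btwc`, `ge`,
#'   `clustering`, `lambda`, `note`
#' @export
graph_metrics <- function(cm, density = 0.05, n_null = 20, seed = 1L) {
  mats <- if (inherits(cm, "netsig_connectivity")) cm$bands else cm
  purrr::imap_dfr(mats, function(w, band) {
    A <- suppressWarnings(binarize_top_edges(w, density))
    note <- ""
    Q <- tryCatch(modularity_graph(A, seed = derive_seed(seed, 1))$Q,
                  netsig_error = function(e) NA_real_)
    swi <- tryCatch(small_world_index(A, n_null = n_null, seed = derive_seed(seed, 2)),
                    netsig_error = function(e) {
                      note <<- conditionMessage(e)
                      NA_real_
                    })
    lam <- tryCatch(characteristic_path_length(A),
                    netsig_error = function(e) NA_real_)
    tibble::tibble(
      band = band, Q = Q, swi = swi,
      btwc = betweenness_centrality(A)$BtwC,
      ge = global_efficiency(A),
      clustering = clustering_coefficient(A)$C,
      lambda = lam, note = note
    )
  })
}
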